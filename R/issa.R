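#' Resample a duty-cycled track to a regular step interval
#'
#' Greedy forward selection: from the current fix, the next retained fix is
#' the one whose spacing is closest to `target_dt` among those within
#' `target_dt * (1 +/- tolerance)`. Where no fix falls inside the window the
#' burst is split and a new burst starts at the following fix, so no step ever
#' spans a data hole. With the default tolerance of 0.5 the 1-h daytime
#' spacing thins to 2 h and the 3-h nocturnal spacing is accepted as is,
#' keeping the median interval at the 2-h target.
#'
#' @param track An `io_track` (cleaned).
#' @param target_dt Target step interval in hours (default 2).
#' @param tolerance Accepted fractional deviation from `target_dt`
#'   (default 0.5).
#' @return Data frame of retained fixes with columns `timestamp`, `easting`,
#'   `northing`, `burst` (integer id), `fix_index` (index into the track).
#' @export
resample_track <- function(track, target_dt = 2, tolerance = 0.5) {
  t_h <- as.numeric(track_times(track)) / 3600
  n <- length(t_h)
  lo <- target_dt * (1 - tolerance); hi <- target_dt * (1 + tolerance)
  keep <- integer(0); burst <- integer(0)
  b <- 1L; cur <- 1L
  keep <- cur; burst <- b
  while (cur < n) {
    dts <- t_h[(cur + 1L):n] - t_h[cur]
    win <- which(dts >= lo & dts <= hi)
    if (length(win) > 0) {
      nxt <- cur + win[which.min(abs(dts[win] - target_dt))]
      keep <- c(keep, nxt); burst <- c(burst, b)
      cur <- nxt
    } else {
      nxt_all <- which(dts > hi)
      if (length(nxt_all) == 0) break
      # also handles fixes closer than the lower bound with nothing beyond:
      cand <- cur + nxt_all[1L]
      b <- b + 1L
      keep <- c(keep, cand); burst <- c(burst, b)
      cur <- cand
    }
  }
  if (length(keep) < 3) stop("fewer than 3 fixes retained by resampling")
  data.frame(
    timestamp = track_times(track)[keep],
    easting = track$fixes$easting[keep],
    northing = track$fixes$northing[keep],
    burst = burst, fix_index = keep
  )
}

#' Observed steps from resampled fixes
#'
#' Steps join consecutive retained fixes within a burst. A turn angle needs
#' the previous heading, so the first step of each burst has `turn_angle` NA.
#'
#' @param fixes Data frame from [resample_track()].
#' @return Data frame of observed steps: start/end coordinates, `step_length`
#'   (m), `heading` and `turn_angle` (radians in `(-pi, pi]`), `dt_hours`.
#' @export
steps_from_fixes <- function(fixes) {
  out <- NULL
  for (b in unique(fixes$burst)) {
    f <- fixes[fixes$burst == b, , drop = FALSE]
    if (nrow(f) < 2) next
    dx <- diff(f$easting); dy <- diff(f$northing)
    heading <- atan2(dy, dx)
    ta <- c(NA, .wrap_angle(diff(heading)))
    out <- rbind(out, data.frame(
      burst = b,
      start_easting = f$easting[-nrow(f)], start_northing = f$northing[-nrow(f)],
      end_easting = f$easting[-1], end_northing = f$northing[-1],
      step_length = sqrt(dx^2 + dy^2),
      heading = heading, turn_angle = ta,
      dt_hours = as.numeric(diff(f$timestamp), units = "hours"),
      start_time = f$timestamp[-nrow(f)]
    ))
  }
  if (is.null(out)) stop("no steps could be built")
  out
}

.wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Fit the observed movement kernel (gamma step lengths, von Mises turns)
#'
#' Step lengths are fitted by gamma maximum likelihood (Newton iteration on
#' the shape via the digamma equation); zero/near-zero lengths are floored at
#' `epsilon` metres before taking logs. Turn angles are fitted by a von Mises
#' distribution with mean fixed at zero, solving `I1(k)/I0(k) = mean(cos a)`;
#' a non-positive mean cosine gives `kappa = 0` and a mean cosine beyond the
#' resolvable range caps `kappa` at `kappa_max` with a warning.
#'
#' @param steps Data frame with `step_length` and `turn_angle` columns
#'   (NA turn angles are dropped).
#' @param epsilon Floor for step lengths in metres (default 1).
#' @param kappa_max Cap for the von Mises concentration (default 500).
#' @return Object of class `io_movement_kernel`: `gamma_shape`, `gamma_scale`
#'   (m), `vonmises_kappa`, `vonmises_mu` (0), `n_steps`,
#'   `mean_step_length` (= shape * scale).
#' @export
fit_kernel <- function(steps, epsilon = 1, kappa_max = 500) {
  len <- pmax(steps$step_length, epsilon)
  if (length(len) < 20) stop("need at least 20 observed steps to fit a kernel")
  shape <- .gamma_shape_mle(len)
  scale <- mean(len) / shape
  ta <- steps$turn_angle[!is.na(steps$turn_angle)]
  rbar <- mean(cos(ta))
  kappa <- if (rbar <= 0) 0 else {
    a_max <- besselI(kappa_max, 1, expon.scaled = TRUE) /
      besselI(kappa_max, 0, expon.scaled = TRUE)
    if (rbar >= a_max) {
      warning("turn angles nearly degenerate; kappa capped at ", kappa_max)
      kappa_max
    } else {
      stats::uniroot(function(k) {
        besselI(k, 1, expon.scaled = TRUE) /
          besselI(k, 0, expon.scaled = TRUE) - rbar
      }, c(1e-8, kappa_max), tol = 1e-10)$root
    }
  }
  movement_kernel(shape, scale, kappa)
}

.gamma_shape_mle <- function(x) {
  s <- log(mean(x)) - mean(log(x))
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)   # standard init
  for (i in 1:50) {
    step <- (log(shape) - digamma(shape) - s) /
      (1 / shape - trigamma(shape))
    shape_new <- shape - step
    if (shape_new <= 0) shape_new <- shape / 2
    if (abs(shape_new - shape) < 1e-12 * shape) {
      shape <- shape_new
      break
    }
    shape <- shape_new
  }
  shape
}

#' Construct a movement kernel object
#' @param gamma_shape,gamma_scale Gamma step-length parameters (scale in m).
#' @param vonmises_kappa Von Mises turn-angle concentration (mu fixed at 0).
#' @param n_steps Number of steps the kernel was fitted on (optional).
#' @return Object of class `io_movement_kernel`.
#' @export
movement_kernel <- function(gamma_shape, gamma_scale, vonmises_kappa,
                            n_steps = NA_integer_) {
  stopifnot(gamma_shape > 0, gamma_scale > 0, vonmises_kappa >= 0)
  structure(
    list(gamma_shape = gamma_shape, gamma_scale = gamma_scale,
         vonmises_kappa = vonmises_kappa, vonmises_mu = 0,
         n_steps = n_steps,
         mean_step_length = gamma_shape * gamma_scale),
    class = "io_movement_kernel"
  )
}

#' @export
print.io_movement_kernel <- function(x, ...) {
  cat(sprintf(
    "<io_movement_kernel> gamma(shape %.3f, scale %.1f m), von Mises kappa %.3f; mean step %.1f m\n",
    x$gamma_shape, x$gamma_scale, x$vonmises_kappa, x$mean_step_length
  ))
  invisible(x)
}

#' Draw from a von Mises distribution with mean 0
#'
#' Best-Fisher rejection sampler; `kappa = 0` is the circular uniform.
#'
#' @param n Number of draws.
#' @param kappa Concentration (>= 0).
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 1e-9) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    val <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    nk <- sum(ok)
    if (nk > 0) {
      out[(got + 1):(got + nk)] <- val[ok][seq_len(nk)]
      got <- got + nk
    }
  }
  .wrap_angle(out)
}

#' Build observed/available step strata with habitat covariates
#'
#' Each observed step (needing a previous heading) is matched with
#' `n_available` available steps: lengths drawn from the fitted gamma, turn
#' angles from the fitted von Mises, applied at the observed start point to
#' the previous heading. Available steps landing on water/barren pixels or
#' outside the raster are redrawn (up to `max_redraw` times, then the stratum
#' is dropped); strata whose observed endpoint is on water/barren or outside
#' the raster are dropped and logged. Habitat covariates (forest and disturbed
#' percent cover at the local and landscape radii, plus the landcover class at
#' the endpoint) are extracted at every endpoint; percent-cover covariates are
#' standardized to mean 0, SD 1 over the whole individual-state dataset
#' (standardization constants are stored so effects can be reported per SD or
#' per natural unit). Movement covariates (`step_length`, `log_step_length`,
#' `cos_turn_angle`) stay in natural units so the fitted coefficients can
#' adjust the kernel parameters directly.
#'
#' @param steps Observed steps from [steps_from_fixes()].
#' @param kernel_obs Fitted `io_movement_kernel` for this individual-state.
#' @param raster An `io_landcover`.
#' @param n_available Available steps per stratum (default 30).
#' @param local_radius,landscape_radius Buffer radii in metres (defaults 40
#'   and 500).
#' @param standardize Standardize habitat covariates (default TRUE).
#' @param max_redraw Redraw budget per available step (default 100).
#' @param seed Optional RNG seed.
#' @return Object of class `io_strata`: `data` (one row per step, columns
#'   `stratum`, `case`, coordinates, movement and habitat covariates,
#'   `landcover_class`), `scaling` (data frame of centre/scale per habitat
#'   covariate), `kernel_obs`, `n_dropped`, `drop_log`.
#' @export
build_strata <- function(steps, kernel_obs, raster, n_available = 30,
                         local_radius = 40, landscape_radius = 500,
                         standardize = TRUE, max_redraw = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- steps[!is.na(steps$turn_angle), , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed steps with a defined turn angle")
  drop_classes <- c("water", "barren")
  rows <- vector("list", nrow(obs))
  drop_log <- character(0)
  stratum_id <- 0L
  for (i in seq_len(nrow(obs))) {
    st <- obs[i, ]
    end_obs <- c(st$end_easting, st$end_northing)
    cls_obs <- class_code_at(raster, end_obs)
    cls_name <- names(raster$class_map)[match(cls_obs, raster$class_map)]
    if (is.na(cls_obs) || cls_name %in% drop_classes) {
      drop_log <- c(drop_log, sprintf(
        "stratum at step %d dropped: observed endpoint %s", i,
        if (is.na(cls_obs)) "outside raster" else cls_name))
      next
    }
    prev_head <- st$heading - st$turn_angle
    av_x <- numeric(n_available); av_y <- numeric(n_available)
    av_len <- numeric(n_available); av_ta <- numeric(n_available)
    failed <- FALSE
    for (j in seq_len(n_available)) {
      ok <- FALSE
      for (attempt in seq_len(max_redraw)) {
        L <- stats::rgamma(1, shape = kernel_obs$gamma_shape,
                           scale = kernel_obs$gamma_scale)
        ta <- rvonmises(1, kernel_obs$vonmises_kappa)
        hx <- prev_head + ta
        ex <- st$start_easting + L * cos(hx)
        ey <- st$start_northing + L * sin(hx)
        code <- class_code_at(raster, c(ex, ey))
        cname <- names(raster$class_map)[match(code, raster$class_map)]
        if (!is.na(code) && !(cname %in% drop_classes)) {
          av_x[j] <- ex; av_y[j] <- ey; av_len[j] <- L; av_ta[j] <- ta
          ok <- TRUE
          break
        }
      }
      if (!ok) { failed <- TRUE; break }
    }
    if (failed) {
      drop_log <- c(drop_log, sprintf(
        "stratum at step %d dropped: available-step redraw budget exhausted", i))
      next
    }
    stratum_id <- stratum_id + 1L
    rows[[i]] <- data.frame(
      stratum = stratum_id,
      case = c(1L, rep(0L, n_available)),
      start_easting = st$start_easting, start_northing = st$start_northing,
      end_easting = c(st$end_easting, av_x),
      end_northing = c(st$end_northing, av_y),
      step_length = c(st$step_length, av_len),
      turn_angle = c(st$turn_angle, av_ta)
    )
  }
  dat <- do.call(rbind, rows)
  if (is.null(dat)) stop("all strata dropped during construction")
  if (length(drop_log) > nrow(obs) / 2) {
    stop("more than half of the strata dropped; check raster extent/config")
  }
  ends <- cbind(dat$end_easting, dat$end_northing)
  dat$forest_local <- percent_cover(raster, ends, local_radius, "forest")
  dat$forest_landscape <- percent_cover(raster, ends, landscape_radius, "forest")
  dat$disturbed_local <- percent_cover(raster, ends, local_radius,
                                       c("agriculture", "developed"))
  dat$disturbed_landscape <- percent_cover(raster, ends, landscape_radius,
                                           c("agriculture", "developed"))
  dat$landcover_class <- class_at(raster, ends)
  dat$log_step_length <- log(pmax(dat$step_length, 1))
  dat$cos_turn_angle <- cos(dat$turn_angle)
  hab <- c("forest_local", "forest_landscape",
           "disturbed_local", "disturbed_landscape")
  scaling <- data.frame(covariate = hab, center = 0, scale = 1)
  if (standardize) {
    for (k in seq_along(hab)) {
      v <- dat[[hab[k]]]
      mu <- mean(v); sg <- stats::sd(v)
      if (sg == 0) sg <- 1
      dat[[hab[k]]] <- (v - mu) / sg
      scaling$center[k] <- mu; scaling$scale[k] <- sg
    }
  }
  structure(
    list(data = dat, scaling = scaling, kernel_obs = kernel_obs,
         n_strata = stratum_id, n_available = n_available,
         n_dropped = length(drop_log), drop_log = drop_log),
    class = "io_strata"
  )
}

#' @export
print.io_strata <- function(x, ...) {
  cat(sprintf("<io_strata> %d strata x (1 observed + %d available); %d dropped\n",
              x$n_strata, x$n_available, x$n_dropped))
  invisible(x)
}

#' Fit a step-selection function by conditional logistic regression
#'
#' Maximizes the stratified conditional log-likelihood
#' `sum_s [eta_obs(s) - log sum_j exp(eta_j(s))]` by Newton-Raphson with
#' step halving; standard errors come from the observed information matrix.
#' Movement adjusters (`step_length`, `log_step_length`, `cos_turn_angle`) are
#' always included so the selection-free kernel can be recovered; landcover
#' class enters as indicator contrasts with forest as the reference level when
#' requested and all four habitat classes are present. A covariate whose
#' estimate runs away (separation) is reported with an infinite-CI warning
#' flag rather than an error.
#'
#' @param strata An `io_strata` object (or a compatible data frame).
#' @param covariates Habitat covariate names to include (default the four
#'   percent-cover covariates).
#' @param include_class Include landcover-class indicators vs forest
#'   (default FALSE; the paper's rule is to include them only for individuals
#'   observed in all four habitat classes).
#' @param include_raw_turn Include the raw turn angle as an extra movement
#'   adjuster (default FALSE; it is aliased with the von Mises mean under the
#'   symmetric kernel).
#' @param include_movement Include the movement adjusters (default TRUE; set
#'   FALSE only for pure habitat-covariate fits, e.g. calibration studies on
#'   exchangeable strata).
#' @param min_strata Minimum strata required (default 50).
#' @param max_iter,tol Newton-Raphson controls.
#' @return Object of class `io_ssf_fit`: `coefficients`, `std_errors`, `ci95`
#'   (matrix with `lower`/`upper`), `log_likelihood`, `n_strata`, `scaling`,
#'   `kernel_obs`, `separation` (logical per coefficient), `converged`.
#' @export
fit_conditional_logit <- function(strata,
                                  covariates = c("forest_local",
                                                 "forest_landscape",
                                                 "disturbed_local",
                                                 "disturbed_landscape"),
                                  include_class = FALSE,
                                  include_raw_turn = FALSE,
                                  include_movement = TRUE,
                                  min_strata = 50,
                                  max_iter = 100, tol = 1e-10) {
  dat <- if (inherits(strata, "io_strata")) strata$data else strata
  n_strata <- length(unique(dat$stratum))
  if (n_strata <= min_strata) {
    stop(sprintf("only %d strata; need more than %d", n_strata, min_strata))
  }
  movement <- if (include_movement) {
    c("step_length", "log_step_length", "cos_turn_angle",
      if (include_raw_turn) "turn_angle")
  } else {
    character(0)
  }
  terms <- c(covariates, movement)
  X <- as.matrix(dat[, terms, drop = FALSE])
  if (include_class) {
    present <- unique(dat$landcover_class)
    wanted <- c("shrub_grassland", "agriculture", "developed")
    if (all(c("forest", wanted) %in% present)) {
      for (cl in wanted) {
        X <- cbind(X, as.numeric(dat$landcover_class == cl))
        colnames(X)[ncol(X)] <- paste0("class_", cl)
      }
    } else {
      warning("not all four habitat classes present; class indicators omitted")
    }
  }
  # scale columns for numerical conditioning; coefficients mapped back
  col_scale <- apply(X, 2, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) 1 else s
  })
  Xs <- sweep(X, 2, col_scale, "/")
  sid <- as.integer(factor(dat$stratum))
  y <- dat$case
  # a covariate with no within-stratum variation carries no conditional
  # information: freeze its coefficient at 0 and report an infinite SE
  within_ss <- vapply(seq_len(ncol(Xs)), function(j) {
    mbar <- as.vector(rowsum(Xs[, j], sid)) / tabulate(sid)
    sum((Xs[, j] - mbar[sid])^2)
  }, numeric(1))
  informative <- within_ss > 1e-8 * nrow(Xs)
  all_names <- colnames(X)
  all_scale <- col_scale
  if (!all(informative)) {
    Xs <- Xs[, informative, drop = FALSE]
    col_scale <- col_scale[informative]
  }
  p <- ncol(Xs)
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xs %*% beta)
    mx <- as.vector(tapply(eta, sid, max))[sid]
    w_un <- exp(eta - mx)
    denom <- rowsum(w_un, sid)[sid]
    w <- w_un / denom
    ll <- sum((eta - mx - log(denom))[y == 1])
    xbar <- rowsum(Xs * w, sid)              # per-stratum weighted means
    grad <- colSums(Xs[y == 1, , drop = FALSE]) - colSums(xbar)
    H <- -(crossprod(Xs, Xs * w) - crossprod(xbar))
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    # Newton direction: beta - H^{-1} grad
    halve <- 1
    repeat {
      beta_new <- beta - halve * step
      eta_n <- drop(Xs %*% beta_new)
      mx_n <- as.vector(tapply(eta_n, sid, max))[sid]
      ll_new <- sum((eta_n - mx_n -
                       log(rowsum(exp(eta_n - mx_n), sid)[sid]))[y == 1])
      if (is.finite(ll_new) && (ll_new >= ll - 1e-12)) break
      halve <- halve / 2
      if (halve < 1e-6) break
    }
    beta <- beta_new
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  # observed information at the optimum
  eta <- drop(Xs %*% beta)
  mx <- as.vector(tapply(eta, sid, max))[sid]
  w <- exp(eta - mx) / rowsum(exp(eta - mx), sid)[sid]
  xbar <- rowsum(Xs * w, sid)
  info <- crossprod(Xs, Xs * w) - crossprod(xbar)
  cov_s <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se_s <- sqrt(pmax(diag(cov_s), 0))
  coef <- se <- rep(0, length(all_names))
  names(coef) <- names(se) <- all_names
  coef[informative] <- beta / col_scale
  se[informative] <- se_s / col_scale
  se[!informative] <- Inf
  separation <- rep(FALSE, length(all_names))
  names(separation) <- all_names
  separation[informative] <- abs(beta) > 15 | !is.finite(se_s) | se_s > 1e3
  if (!all(informative)) {
    warning("no within-stratum variation for: ",
            paste(all_names[!informative], collapse = ", "),
            " (coefficient fixed at 0, SE infinite)")
  }
  if (any(separation)) {
    warning("possible separation: ", paste(names(coef)[separation],
                                           collapse = ", "),
            " (treat CI as infinite)")
  }
  ci <- cbind(lower = coef - 1.96 * se, upper = coef + 1.96 * se)
  scaling <- if (inherits(strata, "io_strata")) strata$scaling else NULL
  kernel_obs <- if (inherits(strata, "io_strata")) strata$kernel_obs else NULL
  structure(
    list(coefficients = coef, std_errors = se, ci95 = ci,
         log_likelihood = ll_old, n_strata = n_strata,
         scaling = scaling, kernel_obs = kernel_obs,
         separation = separation, converged = converged),
    class = "io_ssf_fit"
  )
}

#' @export
print.io_ssf_fit <- function(x, ...) {
  cat(sprintf("<io_ssf_fit> %d strata, logLik %.2f%s\n", x$n_strata,
              x$log_likelihood, if (!x$converged) " (not converged)" else ""))
  print(data.frame(estimate = x$coefficients, se = x$std_errors,
                   lower = x$ci95[, 1], upper = x$ci95[, 2]))
  invisible(x)
}

#' Selection-free movement kernel and mean movement rate
#'
#' Removes the tilt that habitat selection imposes on the availability kernel:
#' the fitted `log_step_length` coefficient shifts the gamma shape, the
#' `step_length` coefficient tilts the gamma rate, and the `cos_turn_angle`
#' coefficient shifts the von Mises concentration (exponential-family
#' conjugacy makes these adjustments exact):
#' `shape' = shape + b_log_sl`, `1/scale' = 1/scale - b_sl`,
#' `kappa' = max(kappa + b_cos_ta, 0)`. The mean movement rate is
#' `shape' * scale'` metres per step interval.
#'
#' @param fit An `io_ssf_fit` containing the three movement coefficients.
#' @param kernel_obs The observed (availability) `io_movement_kernel`;
#'   defaults to the one stored in `fit`.
#' @return List with `kernel` (adjusted `io_movement_kernel`) and
#'   `mean_movement_rate` (m per step interval).
#' @export
adjust_kernel <- function(fit, kernel_obs = NULL) {
  if (is.null(kernel_obs)) kernel_obs <- fit$kernel_obs
  if (is.null(kernel_obs)) stop("no observed kernel available")
  b <- fit$coefficients
  need <- c("step_length", "log_step_length", "cos_turn_angle")
  if (!all(need %in% names(b))) {
    stop("fit lacks movement coefficients: ",
         paste(setdiff(need, names(b)), collapse = ", "))
  }
  shape_new <- kernel_obs$gamma_shape + b[["log_step_length"]]
  inv_scale_new <- 1 / kernel_obs$gamma_scale - b[["step_length"]]
  if (inv_scale_new <= 0 || shape_new <= 0) {
    stop(sprintf(
      "invalid kernel adjustment: shape' = %.4f, 1/scale' = %.6f (require both > 0)",
      shape_new, inv_scale_new))
  }
  kappa_new <- max(kernel_obs$vonmises_kappa + b[["cos_turn_angle"]], 0)
  kern <- movement_kernel(shape_new, 1 / inv_scale_new, kappa_new)
  list(kernel = kern, mean_movement_rate = kern$mean_step_length)
}

#' Pool individual selection coefficients to the population level
#'
#' Inverse-variance weighted mean of the per-individual coefficients,
#' `sum(b_i / s_i^2) / sum(1 / s_i^2)`, with a percentile bootstrap CI that
#' accounts for both between-individual variation (resampling individuals
#' with replacement) and within-individual uncertainty (redrawing each
#' resampled coefficient from `Normal(b_i, s_i^2)`).
#'
#' @param fits List of `io_ssf_fit` objects (>= 2 with finite SEs).
#' @param covariate Coefficient name to pool.
#' @param bootstrap_reps Bootstrap replicates (default 2000).
#' @param seed Optional RNG seed.
#' @return Object of class `io_population_estimate`: `covariate`,
#'   `pooled_log_rss`, `ci95`, `n_individuals`, `bootstrap_reps`,
#'   `interpretation` (`"selection"`, `"avoidance"` or `"indifference"` from
#'   the CI against zero).
#' @export
pool_population <- function(fits, covariate, bootstrap_reps = 2000,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- vapply(fits, function(f) f$coefficients[[covariate]], numeric(1))
  s <- vapply(fits, function(f) f$std_errors[[covariate]], numeric(1))
  keep <- is.finite(b) & is.finite(s)
  b <- b[keep]; s <- s[keep]
  if (length(b) < 2) stop("need at least 2 individuals with finite SEs")
  if (any(s == 0)) stop("degenerate (zero) standard error in pooled input")
  wsum <- function(bb) sum(bb / s^2) / sum(1 / s^2)
  pooled <- wsum(b)
  m <- length(b)
  boots <- vapply(seq_len(bootstrap_reps), function(r) {
    ix <- sample.int(m, m, replace = TRUE)
    bb <- stats::rnorm(m, b[ix], s[ix])
    sum(bb / s[ix]^2) / sum(1 / s[ix]^2)
  }, numeric(1))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  interp <- if (ci[1] > 0) "selection" else if (ci[2] < 0) "avoidance" else
    "indifference"
  structure(
    list(covariate = covariate, pooled_log_rss = pooled, ci95 = ci,
         n_individuals = m, bootstrap_reps = bootstrap_reps,
         interpretation = interp),
    class = "io_population_estimate"
  )
}

#' @export
print.io_population_estimate <- function(x, ...) {
  cat(sprintf(
    "<io_population_estimate> %s: pooled log-RSS %.3f (95%% CI %.3f, %.3f) over %d birds -> %s\n",
    x$covariate, x$pooled_log_rss, x$ci95[1], x$ci95[2], x$n_individuals,
    x$interpretation
  ))
  invisible(x)
}
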