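#' Exact log-likelihood of a continuous-time movement process
#'
#' Evaluates the Gaussian log-likelihood of projected positions under a
#' stationary continuous-time stochastic process plus independent Gaussian
#' measurement error, exactly, via the Markov (Kalman) recursion per axis.
#' The two axes are independent and share the isotropic process parameters.
#'
#' Process autocovariance of each axis at lag `dt` (hours):
#' * `IID`: `sigma2 * 1(dt == 0)` (no autocorrelation),
#' * `OU`:  `sigma2 * exp(-dt / tau_position)`,
#' * `OUF`: `sigma2 / (tau_position - tau_velocity) *
#'           (tau_position * exp(-dt / tau_position) -
#'            tau_velocity * exp(-dt / tau_velocity))`.
#'
#' Measurement error adds `error_rms^2 / 2` variance per axis (`error_rms` is
#' the 2-D distance RMS from tag calibration).
#'
#' @param kind `"IID"`, `"OU"` or `"OUF"`.
#' @param t_hours Numeric vector of fix times in hours (strictly increasing).
#' @param xy Two-column coordinate matrix (metres).
#' @param mu Length-2 stationary mean (metres).
#' @param sigma2 Per-axis position variance (m^2).
#' @param tau_position Position autocorrelation timescale (hours; OU/OUF).
#' @param tau_velocity Velocity timescale (hours; OUF only, `< tau_position`).
#' @param error_rms Horizontal error RMS (metres, 2-D distance convention).
#' @return Log-likelihood (scalar).
#' @export
movement_loglik <- function(kind, t_hours, xy, mu, sigma2,
                            tau_position = NULL, tau_velocity = NULL,
                            error_rms = 0) {
  kind <- match.arg(kind, c("IID", "OU", "OUF"))
  R <- error_rms^2 / 2
  ll <- 0
  for (axis in 1:2) {
    z <- xy[, axis] - mu[axis]
    ll <- ll + switch(kind,
      IID = .iid_ll(z, sigma2, R),
      OU  = .ou_ll(t_hours, z, sigma2, tau_position, R),
      OUF = .ouf_ll(t_hours, z, sigma2, tau_position, tau_velocity, R)
    )
  }
  ll
}

.iid_ll <- function(z, sigma2, R) {
  v <- sigma2 + R
  -0.5 * sum(log(2 * pi * v) + z^2 / v)
}

# 1-D state Kalman filter for a centred OU process observed with noise
.ou_ll <- function(t, z, sigma2, tau, R) {
  n <- length(z)
  phi <- exp(-diff(t) / tau)
  a <- 0; P <- sigma2
  ll <- 0
  for (i in seq_len(n)) {
    if (i == 1L) {
      pa <- 0; pP <- sigma2
    } else {
      f <- phi[i - 1L]
      pa <- f * a
      pP <- f * f * P + sigma2 * (1 - f * f)
    }
    S <- pP + R
    v <- z[i] - pa
    ll <- ll - 0.5 * (log(2 * pi * S) + v * v / S)
    K <- pP / S
    a <- pa + K * v
    P <- pP * (1 - K)
  }
  ll
}

# 2-D state (position, velocity) Kalman filter for the centred OUF process.
# The process solves (d/dt + 1/tau_p)(d/dt + 1/tau_v) x = noise; its exact
# discrete transition has eigenvalues -1/tau_p and -1/tau_v, stationary
# position variance sigma2, stationary velocity variance sigma2/(tau_p*tau_v),
# and zero stationary position-velocity covariance.
.ouf_ll <- function(t, z, sigma2, tau_p, tau_v, R) {
  if (tau_v >= tau_p) return(-Inf)
  n <- length(z)
  a_c <- 1 / (tau_p * tau_v)
  b_c <- 1 / tau_p + 1 / tau_v
  l1 <- -1 / tau_p; l2 <- -1 / tau_v
  p22_inf <- sigma2 * a_c
  dts <- diff(t)
  # per-step transition matrices (2x2), vectorized over steps
  e1 <- exp(l1 * dts); e2 <- exp(l2 * dts)
  den <- l1 - l2
  f11 <- (e1 * (0 - l2) - e2 * (0 - l1)) / den
  f12 <- (e1 - e2) / den
  f21 <- (e1 * (-a_c) - e2 * (-a_c)) / den
  f22 <- (e1 * (-b_c - l2) - e2 * (-b_c - l1)) / den

  a1 <- 0; a2 <- 0
  P11 <- sigma2; P12 <- 0; P22 <- p22_inf
  ll <- 0
  for (i in seq_len(n)) {
    if (i == 1L) {
      pa1 <- 0; pa2 <- 0
      pP11 <- sigma2; pP12 <- 0; pP22 <- p22_inf
    } else {
      k <- i - 1L
      F11 <- f11[k]; F12 <- f12[k]; F21 <- f21[k]; F22 <- f22[k]
      pa1 <- F11 * a1 + F12 * a2
      pa2 <- F21 * a1 + F22 * a2
      # FPF'
      t11 <- F11 * P11 + F12 * P12; t12 <- F11 * P12 + F12 * P22
      t21 <- F21 * P11 + F22 * P12; t22 <- F21 * P12 + F22 * P22
      fpf11 <- t11 * F11 + t12 * F12
      fpf12 <- t11 * F21 + t12 * F22
      fpf22 <- t21 * F21 + t22 * F22
      # Q = Pinf - F Pinf F'
      q11 <- sigma2 - (F11 * F11 * sigma2 + F12 * F12 * p22_inf)
      q12 <- -(F11 * F21 * sigma2 + F12 * F22 * p22_inf)
      q22 <- p22_inf - (F21 * F21 * sigma2 + F22 * F22 * p22_inf)
      pP11 <- fpf11 + q11; pP12 <- fpf12 + q12; pP22 <- fpf22 + q22
    }
    S <- pP11 + R
    v <- z[i] - pa1
    ll <- ll - 0.5 * (log(2 * pi * S) + v * v / S)
    K1 <- pP11 / S; K2 <- pP12 / S
    a1 <- pa1 + K1 * v
    a2 <- pa2 + K2 * v
    P11 <- pP11 - K1 * pP11
    P12 <- pP12 - K1 * pP12
    P22 <- pP22 - K2 * pP12
  }
  ll
}

#' Fit a continuous-time movement model to a track
#'
#' Maximum-likelihood fit of a stationary IID, OU (Ornstein-Uhlenbeck) or OUF
#' (OU position + OU velocity) process with known measurement-error RMS.
#' The stationary mean is estimated jointly with the covariance parameters.
#'
#' @param track An `io_track` (typically restricted to one movement state).
#' @param kind `"IID"`, `"OU"` or `"OUF"`.
#' @param error_rms Horizontal error RMS in metres (from [calibrate_error()]).
#' @return Object of class `io_movement_model` with fields `kind`, `mu`,
#'   `sigma2`, `tau_position`, `tau_velocity`, `error_rms`, `log_likelihood`,
#'   `n_params`, `aicc`, `n`, `duration_hours`, `convergence`.
#' @export
fit_movement_model <- function(track, kind = c("IID", "OU", "OUF"),
                               error_rms = 0) {
  kind <- match.arg(kind)
  xy <- track_coords(track)
  n <- nrow(xy)
  if (n < 30) stop("need at least 30 fixes to fit a movement model")
  t_hours <- as.numeric(track$fixes$timestamp) / 3600
  t_hours <- t_hours - t_hours[1]
  duration <- t_hours[n]
  R <- error_rms^2 / 2
  mu0 <- colMeans(xy)
  v0 <- max(mean(apply(xy, 2, stats::var)) - R, 1)

  if (kind == "IID") {
    vm <- mean(apply(xy, 2, function(z) mean((z - mean(z))^2)))
    sigma2 <- max(vm - R, 1e-6)
    ll <- movement_loglik("IID", t_hours, xy, mu0, sigma2, error_rms = error_rms)
    return(.finish_model(kind, mu0, sigma2, NULL, NULL, error_rms, ll,
                         n_params = 3L, n = n, duration = duration,
                         convergence = 0L))
  }

  med_dt <- stats::median(diff(t_hours))
  r1 <- mean(vapply(1:2, function(a) {
    z <- xy[, a] - mu0[a]
    suppressWarnings(stats::cor(z[-n], z[-1]))
  }, numeric(1)))
  tau0 <- if (is.finite(r1) && r1 > 0.05 && r1 < 0.99) {
    -med_dt / log(r1)
  } else {
    duration / 10
  }
  tau0 <- min(max(tau0, med_dt / 2), duration)

  if (kind == "OU") {
    obj <- function(p) {
      -movement_loglik("OU", t_hours, xy, c(p[1], p[2]), exp(p[3]),
                       tau_position = exp(p[4]), error_rms = error_rms)
    }
    init <- c(mu0, log(v0), log(tau0))
    fit <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    p <- fit$par
    tau_p <- exp(p[4])
    if (tau_p > 10 * duration || tau_p < med_dt / 100) {
      warning("OU fit: tau_position hit an effective boundary (",
              signif(tau_p, 3), " h)")
    }
    return(.finish_model("OU", c(p[1], p[2]), exp(p[3]), tau_p, NULL,
                         error_rms, -fit$value, n_params = 4L, n = n,
                         duration = duration, convergence = fit$convergence))
  }

  # OUF: tau_velocity parameterized as a fraction of tau_position
  obj <- function(p) {
    tp <- exp(p[4]); tv <- tp * stats::plogis(p[5])
    -movement_loglik("OUF", t_hours, xy, c(p[1], p[2]), exp(p[3]),
                     tau_position = tp, tau_velocity = tv,
                     error_rms = error_rms)
  }
  init <- c(mu0, log(v0), log(tau0), stats::qlogis(0.2))
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-10))
  p <- fit$par
  tau_p <- exp(p[4]); tau_v <- tau_p * stats::plogis(p[5])
  if (tau_p > 10 * duration || stats::plogis(p[5]) > 0.99) {
    warning("OUF fit: a timescale hit an effective boundary")
  }
  .finish_model("OUF", c(p[1], p[2]), exp(p[3]), tau_p, tau_v,
                error_rms, -fit$value, n_params = 5L, n = n,
                duration = duration, convergence = fit$convergence)
}

.finish_model <- function(kind, mu, sigma2, tau_p, tau_v, error_rms, ll,
                          n_params, n, duration, convergence) {
  structure(
    list(kind = kind, mu = mu, sigma2 = sigma2,
         tau_position = tau_p, tau_velocity = tau_v,
         error_rms = error_rms, log_likelihood = ll,
         n_params = n_params, aicc = aicc(ll, n_params, n),
         n = n, duration_hours = duration, convergence = convergence),
    class = "io_movement_model"
  )
}

#' AICc (small-sample corrected Akaike Information Criterion)
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size (number of fixes).
#' @return `-2*loglik + 2k + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
print.io_movement_model <- function(x, ...) {
  cat(sprintf("<io_movement_model> %s: sigma2 = %.1f m^2", x$kind, x$sigma2))
  if (!is.null(x$tau_position)) cat(sprintf(", tau_p = %.2f h", x$tau_position))
  if (!is.null(x$tau_velocity)) cat(sprintf(", tau_v = %.2f h", x$tau_velocity))
  cat(sprintf(", logLik = %.2f, AICc = %.2f (n = %d)\n",
              x$log_likelihood, x$aicc, x$n))
  invisible(x)
}

#' Select among fitted movement models by AICc
#'
#' @param fits List of `io_movement_model` objects fitted to identical data.
#' @return The minimum-AICc fit; exact ties break toward fewer parameters.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0L) stop("no fitted models supplied")
  if (inherits(fits, "io_movement_model")) return(fits)
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  ks <- vapply(fits, function(f) f$n_params, numeric(1))
  fits[[order(aiccs, ks)[1L]]]
}
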