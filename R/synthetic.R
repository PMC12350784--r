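#' Configuration for the dual-state track simulator
#'
#' Defaults emulate the study system: a duty cycle of one fix per hour by day
#' (0600-1800) and every 3 h by night (16 fixes/day), ~2% missingness, 5.9 m
#' horizontal error RMS, Ornstein-Uhlenbeck residency movement (sigma 300 m
#' per axis, tau 6 h), and episodic commuting to a disjunct satellite area
#' 13 km away at 8 km/h, with lognormal trip durations (median 17 h) and
#' inter-trip residency (median 28.3 h). A 60-day track with one commuting
#' session spanning days 25-55 keeps simulations fast while preserving the
#' dual-state structure.
#'
#' @param rng_seed Integer seed; every simulation is exactly reproducible.
#' @param bird_id Identifier for the emitted track.
#' @param start Track start (POSIXct, UTC).
#' @param n_days Days of tracking.
#' @param residency_center Length-2 (easting, northing) in metres.
#' @param residency_sigma Per-axis OU standard deviation (m).
#' @param residency_tau OU position timescale (hours).
#' @param satellite_centers List of length-2 centres of commuting
#'   destinations; each must be more than `5 * residency_sigma` from the
#'   residency centre (geographically disjunct).
#' @param commute_speed Transit speed (m/h).
#' @param commute_heading_kappa Heading concentration of the transit leg;
#'   larger values make transit more ballistic (fewer fixes off the straight
#'   line).
#' @param trip_duration_meanlog,trip_duration_sdlog Lognormal parameters of
#'   trip duration in hours.
#' @param inter_trip_meanlog,inter_trip_sdlog Lognormal parameters of the
#'   residency time between trips in hours.
#' @param session_windows Data frame with `start_day`, `end_day` (days from
#'   track start) delimiting commuting sessions; NULL or empty for a purely
#'   stationary bird.
#' @param error_rms Horizontal GPS error RMS (m, 2-D distance convention).
#' @param duty An [duty_cycle()].
#' @param missingness Fraction of scheduled fixes dropped at random.
#' @param local_offset_hours Local clock offset from UTC.
#' @param min_dwell_hours Minimum dwell at the satellite per trip.
#' @return List of class `io_sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       bird_id = "sim",
                       start = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                       n_days = 60,
                       residency_center = c(0, 0),
                       residency_sigma = 300,
                       residency_tau = 6,
                       satellite_centers = list(c(12000, 5000)),
                       commute_speed = 8000,
                       commute_heading_kappa = 20,
                       trip_duration_meanlog = log(17),
                       trip_duration_sdlog = 0.8,
                       inter_trip_meanlog = log(28.3),
                       inter_trip_sdlog = 0.5,
                       session_windows = data.frame(start_day = 25,
                                                    end_day = 55),
                       error_rms = 5.9,
                       duty = duty_cycle(),
                       missingness = 0.02,
                       local_offset_hours = -10,
                       min_dwell_hours = 1) {
  stopifnot(missingness >= 0, missingness < 1, residency_sigma > 0,
            residency_tau > 0, commute_speed > 0, n_days >= 1)
  for (s in satellite_centers) {
    d <- sqrt(sum((s - residency_center)^2))
    if (d <= 5 * residency_sigma) {
      stop("satellite centre must be disjunct: > 5 * residency_sigma from the residency centre")
    }
    transit <- d / commute_speed
    if (2 * transit > stats::qlnorm(0.05, trip_duration_meanlog,
                                    trip_duration_sdlog)) {
      stop("satellite unreachable: round-trip transit exceeds plausible trip durations")
    }
  }
  structure(
    list(rng_seed = rng_seed, bird_id = bird_id, start = start,
         n_days = n_days, residency_center = residency_center,
         residency_sigma = residency_sigma, residency_tau = residency_tau,
         satellite_centers = satellite_centers, commute_speed = commute_speed,
         commute_heading_kappa = commute_heading_kappa,
         trip_duration_meanlog = trip_duration_meanlog,
         trip_duration_sdlog = trip_duration_sdlog,
         inter_trip_meanlog = inter_trip_meanlog,
         inter_trip_sdlog = inter_trip_sdlog,
         session_windows = session_windows, error_rms = error_rms,
         duty = duty, missingness = missingness,
         local_offset_hours = local_offset_hours,
         min_dwell_hours = min_dwell_hours),
    class = "io_sim_config"
  )
}

# sampled fix times after duty cycle + missingness: exactly n_days complete
# duty-cycle days, starting with the first day window at/after `start`
.sim_times <- function(config) {
  per_day <- length(schedule_fixes(config$duty, config$start, 1,
                                   config$local_offset_hours))
  ts <- schedule_fixes(config$duty, config$start, config$n_days + 1,
                       config$local_offset_hours)
  ts <- ts[ts >= config$start]
  ts <- ts[seq_len(min(length(ts), config$n_days * per_day))]
  if (config$missingness > 0) {
    keep <- stats::runif(length(ts)) >= config$missingness
    ts <- ts[keep]
  }
  ts
}

# exact discrete-time OU transition along a sequence of times; positions are
# conditioned on the previous fix of the same bout (no Euler discretization)
.ou_chain <- function(t_h, center, sigma, tau, prev = NULL, prev_t = NULL) {
  n <- length(t_h)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    if (is.null(prev)) {
      out[i, ] <- center + stats::rnorm(2, 0, sigma)
    } else {
      phi <- exp(-(t_h[i] - prev_t) / tau)
      out[i, ] <- center + phi * (prev - center) +
        stats::rnorm(2, 0, sigma * sqrt(1 - phi^2))
    }
    prev <- out[i, ]; prev_t <- t_h[i]
  }
  out
}

#' Simulate a dual-state (stationary + commuting) track with ground truth
#'
#' Outside commuting sessions the bird moves as an exact Ornstein-Uhlenbeck
#' process around its residency centre. Within a session, trips alternate
#' with inter-trip residency: a near-ballistic transit to a satellite centre,
#' an OU dwell there, and a direct return. Positions are sampled at the
#' duty-cycle times, thinned by missingness, and perturbed by isotropic GPS
#' error. The exact ground truth (per-fix state, change-point indices, trip
#' times) is emitted alongside.
#'
#' @param config An [sim_config()].
#' @return List with `track` (an `io_track`) and `truth` (list:
#'   `state_per_fix`, `changepoints` — fix indices of session boundaries,
#'   `trips` — data frame of `exit_time`, `reentry_time`, `destination`,
#'   `session_windows` as POSIXct, `nest_location = NULL`).
#' @export
simulate_dual_state_track <- function(config) {
  set.seed(config$rng_seed)
  ts <- .sim_times(config)
  t_h <- as.numeric(ts - as.numeric(config$start)) / 3600
  n <- length(t_h)
  res_c <- config$residency_center

  # schedule trips within each session window
  trips <- NULL
  wins <- config$session_windows
  if (!is.null(wins) && nrow(wins) > 0) {
    sat_i <- 0L
    for (w in seq_len(nrow(wins))) {
      tcur <- wins$start_day[w] * 24
      wend <- wins$end_day[w] * 24
      repeat {
        gap <- stats::rlnorm(1, config$inter_trip_meanlog,
                             config$inter_trip_sdlog)
        exit <- tcur + gap
        dur <- stats::rlnorm(1, config$trip_duration_meanlog,
                             config$trip_duration_sdlog)
        sat_i <- sat_i %% length(config$satellite_centers) + 1L
        sat <- config$satellite_centers[[sat_i]]
        transit <- sqrt(sum((sat - res_c)^2)) / config$commute_speed
        dwell <- max(dur - 2 * transit, config$min_dwell_hours)
        dur <- dwell + 2 * transit
        if (exit + dur > wend) break
        trips <- rbind(trips, data.frame(exit_h = exit, reentry_h = exit + dur,
                                         transit_h = transit,
                                         destination = sat_i))
        tcur <- exit + dur
      }
    }
  }

  # per-fix mode and bout id
  mode <- rep("res", n)       # res | out | dwell | back
  bout <- integer(n)          # OU bout identity (changes reset the chain)
  trip_of <- rep(NA_integer_, n)
  if (!is.null(trips)) {
    for (k in seq_len(nrow(trips))) {
      tr <- trips[k, ]
      io <- t_h >= tr$exit_h & t_h < tr$exit_h + tr$transit_h
      id <- t_h >= tr$exit_h + tr$transit_h & t_h < tr$reentry_h - tr$transit_h
      ib <- t_h >= tr$reentry_h - tr$transit_h & t_h < tr$reentry_h
      mode[io] <- "out"; mode[id] <- "dwell"; mode[ib] <- "back"
      trip_of[io | id | ib] <- k
    }
  }
  bout <- cumsum(c(TRUE, mode[-1] != mode[-n] | c(diff(trip_of) != 0 &
                                                    !is.na(trip_of[-n]) &
                                                    !is.na(trip_of[-1]))[seq_len(n - 1)]))

  pos <- matrix(NA_real_, n, 2)
  for (b in unique(bout)) {
    ix <- which(bout == b)
    md <- mode[ix[1]]
    if (md %in% c("res", "dwell")) {
      center <- if (md == "res") res_c else
        config$satellite_centers[[trips$destination[trip_of[ix[1]]]]]
      pos[ix, ] <- .ou_chain(t_h[ix], center, config$residency_sigma,
                             config$residency_tau)
    } else {
      tr <- trips[trip_of[ix[1]], ]
      sat <- config$satellite_centers[[tr$destination]]
      leg <- sat - res_c
      leg_len <- sqrt(sum(leg^2))
      u <- leg / leg_len
      perp <- c(-u[2], u[1])
      sd_lat <- leg_len / (4 * sqrt(config$commute_heading_kappa))
      for (i in ix) {
        frac <- if (mode[i] == "out") {
          (t_h[i] - tr$exit_h) / tr$transit_h
        } else {
          (tr$reentry_h - t_h[i]) / tr$transit_h
        }
        lat <- stats::rnorm(1, 0, sd_lat * sin(pi * min(max(frac, 0), 1)))
        pos[i, ] <- res_c + frac * leg + lat * perp
      }
    }
  }
  pos <- pos + matrix(stats::rnorm(2 * n, 0, config$error_rms / sqrt(2)), n, 2)

  state <- rep("stationary", n)
  changepoints <- integer(0)
  win_t <- NULL
  if (!is.null(wins) && nrow(wins) > 0) {
    for (w in seq_len(nrow(wins))) {
      ws <- wins$start_day[w] * 24; we <- wins$end_day[w] * 24
      state[t_h >= ws & t_h < we] <- "commuting"
      for (boundary in c(ws, we)) {
        i <- which(t_h >= boundary)[1]
        if (!is.na(i) && i > 1 && i <= n) changepoints <- c(changepoints, i)
      }
    }
    win_t <- data.frame(
      start = config$start + wins$start_day * 86400,
      end = config$start + wins$end_day * 86400
    )
  }
  fixes <- data.frame(
    timestamp = ts, easting = pos[, 1], northing = pos[, 2],
    n_satellites = 8L, fix_dimension = "3D", source_row = seq_len(n)
  )
  truth <- list(
    state_per_fix = state,
    changepoints = unique(changepoints),
    trips = if (is.null(trips)) {
      data.frame(exit_time = as.POSIXct(character(), tz = "UTC"),
                 reentry_time = as.POSIXct(character(), tz = "UTC"),
                 destination = integer(0))
    } else {
      data.frame(exit_time = config$start + trips$exit_h * 3600,
                 reentry_time = config$start + trips$reentry_h * 3600,
                 destination = trips$destination)
    },
    session_windows = win_t,
    nest_location = NULL
  )
  list(track = io_track(config$bird_id, fixes, "synthetic-utm"), truth = truth)
}

#' Simulate nest attendance with a continuous brooding bout
#'
#' Builds a purely stationary track in which, before brooding onset, each
#' scheduled fix is at the nest with a probability that ramps linearly from
#' `incubation_share[1]` at track start to `incubation_share[2]` just before
#' onset (little attendance before laying, near-continuous sitting late in
#' incubation; a single value gives a flat share); from onset the female sits
#' continuously within GPS error of the nest for at least `brooding_hours`
#' (females brood day and night after hatching), then resumes the late-share
#' pattern.
#'
#' @param config An [sim_config()] (session windows are ignored).
#' @param nest_location Length-2 nest coordinates; default 150 m east, 100 m
#'   south of the residency centre.
#' @param incubation_share Probability a pre-onset fix is at the nest; either
#'   a single flat value or `c(start, end)` for the linear ramp (default
#'   `c(0.2, 0.85)`).
#' @param brooding_onset_day Days from track start at which brooding begins
#'   (default 40; NULL for no brooding bout).
#' @param brooding_hours Length of the continuous bout (default 96, >= 90).
#' @return List with `track` and `truth` (`nest_location`, `hatch_window`
#'   POSIXct start/end, `state_per_fix` all stationary).
#' @export
simulate_nest_attendance <- function(config, nest_location = NULL,
                                     incubation_share = c(0.2, 0.85),
                                     brooding_onset_day = 40,
                                     brooding_hours = 96) {
  set.seed(config$rng_seed)
  if (is.null(nest_location)) {
    nest_location <- config$residency_center + c(150, -100)
  }
  ts <- .sim_times(config)
  t_h <- as.numeric(ts - as.numeric(config$start)) / 3600
  n <- length(t_h)
  share <- if (length(incubation_share) == 1) {
    rep(incubation_share, n)
  } else {
    onset_h <- if (is.null(brooding_onset_day)) max(t_h) else
      brooding_onset_day * 24
    frac <- pmin(pmax(t_h / max(onset_h, 1e-9), 0), 1)
    incubation_share[1] + frac * diff(incubation_share)
  }
  at_nest <- stats::runif(n) < share
  if (!is.null(brooding_onset_day)) {
    onset <- brooding_onset_day * 24
    at_nest[t_h >= onset & t_h < onset + brooding_hours] <- TRUE
  }
  pos <- matrix(NA_real_, n, 2)
  pos[at_nest, 1] <- nest_location[1]
  pos[at_nest, 2] <- nest_location[2]
  away <- which(!at_nest)
  if (length(away) > 0) {
    pos[away, ] <- .ou_chain(t_h[away], config$residency_center,
                             config$residency_sigma, config$residency_tau)
  }
  pos <- pos + matrix(stats::rnorm(2 * n, 0, config$error_rms / sqrt(2)), n, 2)
  fixes <- data.frame(
    timestamp = ts, easting = pos[, 1], northing = pos[, 2],
    n_satellites = 8L, fix_dimension = "3D", source_row = seq_len(n)
  )
  truth <- list(
    nest_location = nest_location,
    hatch_window = if (is.null(brooding_onset_day)) NULL else
      c(config$start + brooding_onset_day * 86400,
        config$start + (brooding_onset_day * 24 + brooding_hours) * 3600),
    state_per_fix = rep("stationary", n)
  )
  list(track = io_track(config$bird_id, fixes, "synthetic-utm"), truth = truth)
}

#' Simulate a patchy categorical landcover raster
#'
#' A Gaussian white-noise field is smoothed at `patch_scale` and thresholded
#' at the quantiles of the target class fractions, producing contiguous
#' patches whose realized fractions match the targets to within quantile ties.
#' Deterministic per seed.
#'
#' @param extent Length-2 (width, height) in metres.
#' @param resolution Pixel size in metres (default 30).
#' @param class_fractions Named fractions over classes (must sum to 1 within
#'   1e-9); names must be landcover classes.
#' @param patch_scale Smoothing length in metres (default 300).
#' @param rng_seed Integer seed.
#' @param origin Top-left corner (default `c(0, extent[2])`).
#' @return An `io_landcover`.
#' @export
simulate_landcover <- function(extent, resolution = 30,
                               class_fractions = c(forest = 0.4,
                                                   shrub_grassland = 0.25,
                                                   agriculture = 0.2,
                                                   developed = 0.15),
                               patch_scale = 300, rng_seed = 1,
                               origin = NULL) {
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1")
  }
  class_map <- c(forest = 1L, shrub_grassland = 2L, agriculture = 3L,
                 developed = 4L, barren = 5L, water = 6L)
  if (!all(names(class_fractions) %in% names(class_map))) {
    stop("unknown class name(s) in class_fractions")
  }
  set.seed(rng_seed)
  nc <- max(2L, ceiling(extent[1] / resolution))
  nr <- max(2L, ceiling(extent[2] / resolution))
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  s <- max(patch_scale / resolution, 0.5)
  off <- seq(-ceiling(3 * s), ceiling(3 * s))
  kv <- stats::dnorm(off / s)
  bandmat <- function(m) {
    K <- matrix(0, m, m)
    for (d in seq_along(off)) {
      i <- seq_len(m)
      j <- i + off[d]
      ok <- j >= 1 & j <= m
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + kv[d]
    }
    K / rowSums(K)
  }
  sm <- bandmat(nr) %*% z %*% t(bandmat(nc))
  qs <- stats::quantile(sm, probs = cumsum(class_fractions), type = 7)
  grid <- matrix(class_map[names(class_fractions)[1]], nr, nc)
  brk <- c(-Inf, qs)
  for (k in seq_along(class_fractions)) {
    sel <- sm > brk[k] & sm <= brk[k + 1]
    grid[sel] <- class_map[[names(class_fractions)[k]]]
  }
  if (is.null(origin)) origin <- c(0, nr * resolution)
  landcover_raster(grid, resolution = resolution, origin = origin,
                   class_map = class_map)
}

#' Simulate a habitat-selecting walker (SSF ground truth)
#'
#' Each step draws `n_candidates` proposals from the true movement kernel and
#' selects one with probability proportional to `exp(beta' x)` evaluated at
#' the candidate endpoints; candidates outside the raster (or on water/barren)
#' get zero weight. If every candidate is unavailable the walker stays put for
#' that step and the event is flagged.
#'
#' @param raster An `io_landcover`.
#' @param kernel_true The true `io_movement_kernel`.
#' @param beta_true Named numeric of selection coefficients on the natural
#'   covariate scale; names among `forest_local`, `forest_landscape`,
#'   `disturbed_local`, `disturbed_landscape`.
#' @param n_steps Number of steps.
#' @param rng_seed Integer seed.
#' @param start Start position (default raster centre).
#' @param dt_hours Step interval in hours (default 2).
#' @param n_candidates Proposals per step (default 200).
#' @param local_radius,landscape_radius Buffer radii (defaults 40, 500).
#' @return List with `track` (an `io_track`), `kernel_true`, `beta_true`,
#'   `n_reflected` (steps where all candidates were unavailable).
#' @export
simulate_ssf_walker <- function(raster, kernel_true, beta_true, n_steps,
                                rng_seed = 1, start = NULL, dt_hours = 2,
                                n_candidates = 200,
                                local_radius = 40, landscape_radius = 500) {
  set.seed(rng_seed)
  res <- raster$resolution
  if (is.null(start)) {
    start <- c(raster$origin[1] + ncol(raster$grid) * res / 2,
               raster$origin[2] - nrow(raster$grid) * res / 2)
  }
  cov_names <- names(beta_true)
  cover_of <- function(pts) {
    out <- matrix(0, nrow(pts), length(cov_names),
                  dimnames = list(NULL, cov_names))
    for (nm in cov_names) {
      r <- if (grepl("landscape", nm)) landscape_radius else local_radius
      cls <- if (grepl("^forest", nm)) "forest" else
        c("agriculture", "developed")
      out[, nm] <- percent_cover(raster, pts, r, cls)
    }
    out
  }
  pos <- matrix(NA_real_, n_steps + 1, 2)
  pos[1, ] <- start
  heading <- stats::runif(1, -pi, pi)
  n_reflected <- 0L
  drop_classes <- c("water", "barren")
  for (i in seq_len(n_steps)) {
    L <- stats::rgamma(n_candidates, shape = kernel_true$gamma_shape,
                       scale = kernel_true$gamma_scale)
    ta <- rvonmises(n_candidates, kernel_true$vonmises_kappa)
    hx <- heading + ta
    ex <- pos[i, 1] + L * cos(hx)
    ey <- pos[i, 2] + L * sin(hx)
    code <- class_code_at(raster, cbind(ex, ey))
    cname <- names(raster$class_map)[match(code, raster$class_map)]
    ok <- !is.na(code) & !(cname %in% drop_classes)
    if (!any(ok)) {
      n_reflected <- n_reflected + 1L
      pos[i + 1, ] <- pos[i, ]
      next
    }
    w <- numeric(n_candidates)
    xc <- cover_of(cbind(ex, ey)[ok, , drop = FALSE])
    w[ok] <- exp(drop(xc %*% beta_true))
    pick <- sample.int(n_candidates, 1, prob = w)
    pos[i + 1, ] <- c(ex[pick], ey[pick])
    heading <- hx[pick]
  }
  ts <- as.POSIXct("2020-01-01 16:00:00", tz = "UTC") +
    (0:n_steps) * dt_hours * 3600
  fixes <- data.frame(
    timestamp = ts, easting = pos[, 1], northing = pos[, 2],
    n_satellites = 8L, fix_dimension = "3D", source_row = seq_len(n_steps + 1)
  )
  list(track = io_track("walker", fixes, "synthetic-utm"),
       kernel_true = kernel_true, beta_true = beta_true,
       n_reflected = n_reflected)
}

#' Simulate stationary calibration tags
#'
#' Fixes from `n_tags` tags at fixed (distinct) points with isotropic
#' per-axis Gaussian error `error_sigma`; feeds [calibrate_error()], whose
#' distance-RMS convention then reports about `sqrt(2) * error_sigma`.
#'
#' @param n_tags Number of tags (default 5).
#' @param n_fixes Total fixes across tags (default 122).
#' @param error_sigma Per-axis error SD in metres.
#' @param rng_seed Integer seed.
#' @return Data frame with `tag_id`, `easting`, `northing`.
#' @export
simulate_stationary_tags <- function(n_tags = 5, n_fixes = 122,
                                     error_sigma = 4.2, rng_seed = 1) {
  set.seed(rng_seed)
  per <- rep(n_fixes %/% n_tags, n_tags)
  extra <- n_fixes %% n_tags
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  rows <- lapply(seq_len(n_tags), function(k) {
    center <- c(k * 1000, -k * 500)
    data.frame(
      tag_id = sprintf("tag%02d", k),
      easting = center[1] + stats::rnorm(per[k], 0, error_sigma),
      northing = center[2] + stats::rnorm(per[k], 0, error_sigma)
    )
  })
  do.call(rbind, rows)
}
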