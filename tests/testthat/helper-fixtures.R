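# in-code fixtures shared across test files

# track from a coordinate matrix at a fixed hourly (or custom) spacing
make_track <- function(xy, dt_hours = 1,
                       start = as.POSIXct("2020-03-01 16:00:00", tz = "UTC"),
                       id = "t1") {
  xy <- as.matrix(xy)
  io_track(id, data.frame(
    timestamp = start + (seq_len(nrow(xy)) - 1) * dt_hours * 3600,
    easting = xy[, 1], northing = xy[, 2],
    n_satellites = 8L, fix_dimension = "3D"
  ))
}

# track with explicit times (hours from start)
make_track_t <- function(xy, t_hours,
                         start = as.POSIXct("2020-03-01 16:00:00", tz = "UTC"),
                         id = "t1") {
  xy <- as.matrix(xy)
  io_track(id, data.frame(
    timestamp = start + t_hours * 3600,
    easting = xy[, 1], northing = xy[, 2],
    n_satellites = 8L, fix_dimension = "3D"
  ))
}

# dense 1-second resampling oracle for visits: linear interpolation of the
# trajectory, point-in-region test at every second, visit intervals from runs
dense_visit_oracle <- function(track, region) {
  tsec <- as.numeric(iomove::track_times(track))
  xy <- iomove::track_coords(track)
  grid <- seq(tsec[1], tsec[length(tsec)], by = 1)
  gx <- stats::approx(tsec, xy[, 1], xout = grid)$y
  gy <- stats::approx(tsec, xy[, 2], xout = grid)$y
  inside <- iomove::point_in_region(cbind(gx, gy), region)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  keep <- r$values
  data.frame(entry = grid[starts[keep]], exit = grid[ends[keep]])
}

# brute-force outlier recomputation, one fix at a time
brute_outliers <- function(track, max_speed, max_core_distance) {
  xy <- iomove::track_coords(track)
  t_h <- as.numeric(iomove::track_times(track)) / 3600
  n <- nrow(xy)
  med <- c(stats::median(xy[, 1]), stats::median(xy[, 2]))
  flagged <- integer(0)
  for (i in seq_len(n)) {
    sp <- c()
    if (i > 1) {
      sp <- c(sp, sqrt(sum((xy[i, ] - xy[i - 1, ])^2)) / (t_h[i] - t_h[i - 1]))
    }
    if (i < n) {
      sp <- c(sp, sqrt(sum((xy[i + 1, ] - xy[i, ])^2)) / (t_h[i + 1] - t_h[i]))
    }
    fast <- all(sp > max_speed)
    far <- sqrt(sum((xy[i, ] - med)^2)) > max_core_distance
    if (fast || far) flagged <- c(flagged, i)
  }
  flagged
}

# exhaustive change-point search: best unpenalized NLL over all placements of
# K segments with a minimum length, using an independently written cost
brute_segment_nll <- function(xy, K, min_len) {
  n <- nrow(xy)
  seg_nll <- function(i, j) {   # fixes i..j inclusive, 1-based
    s <- xy[i:j, , drop = FALSE]
    len <- j - i + 1
    v <- pmax(colMeans(s^2) - colMeans(s)^2, 1e-9)
    sum(0.5 * len * (log(2 * pi * v) + 1))
  }
  if (K == 1) return(seg_nll(1, n))
  best <- Inf
  if (K == 2) {
    for (c1 in min_len:(n - min_len)) {
      v <- seg_nll(1, c1) + seg_nll(c1 + 1, n)
      if (v < best) best <- v
    }
  } else if (K == 3) {
    for (c1 in min_len:(n - 2 * min_len)) {
      a <- seg_nll(1, c1)
      for (c2 in (c1 + min_len):(n - min_len)) {
        v <- a + seg_nll(c1 + 1, c2) + seg_nll(c2 + 1, n)
        if (v < best) best <- v
      }
    }
  } else {
    stop("brute force supports K <= 3")
  }
  best
}

# dense multivariate-normal log-likelihood oracle for the movement processes,
# built from the closed-form autocovariance (full covariance matrix + Cholesky)
mvn_movement_loglik <- function(kind, t_hours, xy, mu, sigma2,
                                tau_p = NULL, tau_v = NULL, error_rms = 0) {
  n <- length(t_hours)
  lag <- abs(outer(t_hours, t_hours, "-"))
  cov_m <- switch(kind,
    IID = diag(sigma2, n),
    OU = sigma2 * exp(-lag / tau_p),
    OUF = sigma2 / (tau_p - tau_v) *
      (tau_p * exp(-lag / tau_p) - tau_v * exp(-lag / tau_v))
  )
  cov_m <- cov_m + diag(error_rms^2 / 2, n)
  L <- chol(cov_m)
  ll <- 0
  for (axis in 1:2) {
    z <- xy[, axis] - mu[axis]
    u <- backsolve(L, z, transpose = TRUE)
    ll <- ll - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(u^2))
  }
  ll
}

# small uniform-forest raster helper
uniform_raster <- function(class = "forest", n = 50, res = 30) {
  cm <- c(forest = 1L, shrub_grassland = 2L, agriculture = 3L,
          developed = 4L, barren = 5L, water = 6L)
  landcover_raster(matrix(cm[[class]], n, n), resolution = res,
                   origin = c(0, n * res))
}

# exchangeable-strata simulator for conditional-logit calibration: one
# stratum = 1 observed + n_avail available rows; the observed row is chosen
# with probability proportional to exp(beta * x)
simulate_clogit_strata <- function(n_strata, n_avail = 30, beta = 0,
                                   n_cov = 1) {
  rows <- vector("list", n_strata)
  for (s in seq_len(n_strata)) {
    x <- matrix(stats::rnorm((n_avail + 1) * n_cov), ncol = n_cov)
    w <- exp(drop(x %*% rep(beta, length.out = n_cov)))
    pick <- sample.int(n_avail + 1, 1, prob = w)
    case <- integer(n_avail + 1); case[pick] <- 1L
    df <- data.frame(stratum = s, case = case)
    for (k in seq_len(n_cov)) df[[paste0("x", k)]] <- x[, k]
    rows[[s]] <- df
  }
  do.call(rbind, rows)
}
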