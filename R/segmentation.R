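#' Penalized change-point segmentation of a coordinate time series
#'
#' Partitions a track's (easting, northing) series into homogeneous segments.
#' Each segment is modelled as independent Gaussian per axis with its own mean
#' and variance, so change points react to shifts in either the mean location
#' or the dispersion of locations. For each candidate number of segments
#' `K = 1..max_segments` the optimal change-point placement is found exactly
#' by dynamic programming under the minimum-segment-length constraint, and `K`
#' is then chosen by minimizing
#' `NLL(K) + penalty * K * log(n)` (a BIC-like penalty on the negative
#' log-likelihood scale).
#'
#' Segmentation operates on fix index, not clock time: the duty cycle makes
#' sampling near-regular, and irregular gaps are ignored at this stage.
#'
#' @param track An `io_track`.
#' @param min_segment_length Minimum fixes per segment (default 225,
#'   approximately two weeks at 16 fixes/day).
#' @param max_segments Maximum number of segments considered (default 10).
#' @param penalty Penalty multiplier `beta` in `beta * K * log(n)` (default 2.5:
#'   each extra segment adds two means, two variances and a break location,
#'   so a unit multiplier under-penalizes and splits pure noise).
#' @return Object of class `io_segmentation`: a list with `segments` (data
#'   frame: `start_index` inclusive, `end_index` exclusive, per-axis mean and
#'   SD, `state`, `duration_days`, `start_time`, `end_time`), `n_changepoints`,
#'   `penalized_score`, `nll_by_k`, `min_segment_length`.
#' @export
segment_track <- function(track, min_segment_length = 225,
                          max_segments = 10, penalty = 2.5) {
  if (max_segments < 1) stop("max_segments must be at least 1")
  if (min_segment_length < 2) stop("min_segment_length must be at least 2")
  xy <- track_coords(track)
  n <- nrow(xy)
  if (n < 2 * min_segment_length) {
    if (n < min_segment_length) {
      warning(sprintf(
        "track %s has %d fixes (< min_segment_length = %d); returning a single segment",
        track$bird_id, n, min_segment_length))
    }
    return(.make_segmentation(track, breaks = c(0L, n),
                              min_segment_length = min_segment_length,
                              penalized_score = .seg_cost_range(xy, 0L, n) +
                                penalty * log(n)))
  }
  L <- as.integer(min_segment_length)
  kmax <- min(max_segments, n %/% L)

  sx <- c(0, cumsum(xy[, 1])); sx2 <- c(0, cumsum(xy[, 1]^2))
  sy <- c(0, cumsum(xy[, 2])); sy2 <- c(0, cumsum(xy[, 2]^2))
  cost_to <- function(i, j) {
    # cost of segment covering fixes (i, j] in 0-based half-open [i, j) terms;
    # i may be a vector
    len <- j - i
    mx <- (sx[j + 1] - sx[i + 1]) / len
    vx <- pmax((sx2[j + 1] - sx2[i + 1]) / len - mx^2, 1e-9)
    my <- (sy[j + 1] - sy[i + 1]) / len
    vy <- pmax((sy2[j + 1] - sy2[i + 1]) / len - my^2, 1e-9)
    0.5 * len * (log(2 * pi * vx) + 1) + 0.5 * len * (log(2 * pi * vy) + 1)
  }

  C <- matrix(Inf, nrow = kmax, ncol = n + 1)       # C[k, j+1]: best k-segment cost of [0, j)
  B <- matrix(NA_integer_, nrow = kmax, ncol = n + 1)
  js <- L:n
  C[1, js + 1] <- cost_to(0L, js)
  if (kmax >= 2) {
    for (k in 2:kmax) {
      for (j in (k * L):n) {
        ts_cand <- ((k - 1) * L):(j - L)
        tot <- C[k - 1, ts_cand + 1] + cost_to(ts_cand, j)
        best <- which.min(tot)
        C[k, j + 1] <- tot[best]
        B[k, j + 1] <- ts_cand[best]
      }
    }
  }
  nll_by_k <- C[, n + 1]
  scores <- nll_by_k + penalty * seq_len(kmax) * log(n)
  k_star <- which.min(scores)
  breaks <- n
  k <- k_star; j <- n
  while (k >= 2) {
    j <- B[k, j + 1]
    breaks <- c(j, breaks)
    k <- k - 1
  }
  breaks <- c(0L, as.integer(breaks))
  .make_segmentation(track, breaks, min_segment_length,
                     penalized_score = scores[k_star], nll_by_k = nll_by_k)
}

.seg_cost_range <- function(xy, i, j) {
  seg <- xy[(i + 1):j, , drop = FALSE]
  len <- nrow(seg)
  v <- pmax(apply(seg, 2, function(z) mean(z^2) - mean(z)^2), 1e-9)
  sum(0.5 * len * (log(2 * pi * v) + 1))
}

.make_segmentation <- function(track, breaks, min_segment_length,
                               penalized_score, nll_by_k = NULL) {
  xy <- track_coords(track)
  ts <- track_times(track)
  n <- nrow(xy)
  k <- length(breaks) - 1L
  seg <- data.frame(
    start_index = breaks[-length(breaks)] + 1L,  # 1-based inclusive
    end_index = breaks[-1] + 1L                  # 1-based exclusive
  )
  seg$mean_easting <- NA_real_; seg$mean_northing <- NA_real_
  seg$sd_easting <- NA_real_; seg$sd_northing <- NA_real_
  for (i in seq_len(k)) {
    rows <- seg$start_index[i]:(seg$end_index[i] - 1L)
    seg$mean_easting[i] <- mean(xy[rows, 1])
    seg$mean_northing[i] <- mean(xy[rows, 2])
    seg$sd_easting[i] <- stats::sd(xy[rows, 1])
    seg$sd_northing[i] <- stats::sd(xy[rows, 2])
  }
  seg$state <- "unassigned"
  seg$start_time <- ts[seg$start_index]
  # a segment's time span runs to the first fix of the next segment
  # (last segment: to the final fix), so tiling segments tile the track span
  end_fix <- pmin(seg$end_index, n)
  seg$end_time <- ts[end_fix]
  seg$duration_days <- as.numeric(difftime(seg$end_time, seg$start_time,
                                           units = "days"))
  structure(
    list(segments = seg, n_changepoints = k - 1L,
         penalized_score = penalized_score, nll_by_k = nll_by_k,
         min_segment_length = min_segment_length,
         bird_id = track$bird_id),
    class = "io_segmentation"
  )
}

#' @export
print.io_segmentation <- function(x, ...) {
  cat(sprintf("<io_segmentation> bird %s: %d segment(s), %d change point(s)\n",
              x$bird_id, nrow(x$segments), x$n_changepoints))
  print(x$segments[, c("start_index", "end_index", "sd_easting",
                       "sd_northing", "state", "duration_days")])
  invisible(x)
}

#' Classify segments into stationary vs commuting states
#'
#' Segments are clustered on the log geometric-mean coordinate SD,
#' `log(sqrt(sd_easting * sd_northing))`, by deterministic 1-D k-means
#' (centers initialized at quantiles, Lloyd iterations to convergence). The
#' higher-SD cluster is labelled `commuting`. When the two cluster centres
#' differ by less than `min_log_separation` (default `log(2)`, i.e. an SD
#' ratio below 2) the separation is judged spurious and every segment is
#' labelled `stationary`: genuinely dual-state birds separate by an order of
#' magnitude, so a factor-2 split is noise.
#'
#' @param result An `io_segmentation`.
#' @param k_states Number of states (fixed at 2).
#' @param min_log_separation Minimum between-centre distance on the log-SD
#'   axis for a two-state classification (default `log(2)`).
#' @return The `io_segmentation` with `segments$state` filled in.
#' @export
classify_states <- function(result, k_states = 2, min_log_separation = log(2)) {
  stopifnot(inherits(result, "io_segmentation"))
  if (k_states != 2) stop("only k_states = 2 is supported")
  seg <- result$segments
  if (nrow(seg) == 1L) {
    seg$state <- "stationary"
    result$segments <- seg
    return(result)
  }
  f <- 0.5 * (log(pmax(seg$sd_easting, 1e-6)) + log(pmax(seg$sd_northing, 1e-6)))
  km <- .kmeans_1d(f, k = 2)
  if (diff(range(km$centers)) < min_log_separation) {
    seg$state <- "stationary"
  } else {
    hi <- which.max(km$centers)
    seg$state <- ifelse(km$cluster == hi, "commuting", "stationary")
  }
  result$segments <- seg
  result
}

# deterministic 1-D k-means: quantile initialization + Lloyd iterations
.kmeans_1d <- function(x, k, max_iter = 100) {
  centers <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k,
                                        type = 7))
  cluster <- rep(1L, length(x))
  for (iter in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    new_cluster <- max.col(-d, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      if (any(new_cluster == j)) new_centers[j] <- mean(x[new_cluster == j])
    }
    if (identical(new_cluster, cluster) && all(new_centers == centers)) break
    cluster <- new_cluster
    centers <- new_centers
  }
  list(cluster = cluster, centers = centers)
}

#' Per-fix state labels from a classified segmentation
#' @param result A classified `io_segmentation`.
#' @return Character vector, one state per fix.
#' @export
state_per_fix <- function(result) {
  seg <- result$segments
  rep(seg$state, seg$end_index - seg$start_index)
}

#' Summarize time spent per movement state
#'
#' @param result A classified `io_segmentation`.
#' @param track The `io_track` the segmentation was computed on.
#' @return List with `by_state` (data frame: state, n_segments, total duration
#'   in days, mean within-segment SD per axis), `proportion_time_commuting`
#'   (commuting duration over total segment duration), and `segments` (per
#'   segment SD bands for timeline plots).
#' @export
summarize_states <- function(result, track) {
  seg <- result$segments
  if (any(seg$state == "unassigned")) {
    stop("states are unassigned; run classify_states() first")
  }
  agg <- lapply(split(seg, seg$state), function(s) {
    data.frame(
      state = s$state[1],
      n_segments = nrow(s),
      total_duration_days = sum(s$duration_days),
      mean_sd_easting = mean(s$sd_easting),
      mean_sd_northing = mean(s$sd_northing)
    )
  })
  by_state <- do.call(rbind, agg)
  rownames(by_state) <- NULL
  total <- sum(seg$duration_days)
  commuting <- sum(seg$duration_days[seg$state == "commuting"])
  list(
    by_state = by_state,
    proportion_time_commuting = if (total > 0) commuting / total else 0,
    segments = seg[, c("start_time", "end_time", "state",
                       "sd_easting", "sd_northing")]
  )
}

#' Write a segments table to CSV
#' @param result A classified `io_segmentation`.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_segments_csv <- function(result, path) {
  seg <- result$segments
  out <- data.frame(
    bird_id = result$bird_id,
    start_ts = format(seg$start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    end_ts = format(seg$end_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    state = seg$state,
    sd_e = seg$sd_easting, sd_n = seg$sd_northing
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
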