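#' @title GPS track objects
#'
#' @description
#' An `io_track` holds the time-ordered, projected GPS fixes of one tagged
#' bird. Coordinates are planar (projected, metres); timestamps are stored in
#' UTC and interpreted in a configurable local clock offset wherever the duty
#' cycle matters (Hawai`i standard time, UTC-10, by default).
#'
#' @param bird_id Character scalar identifying the animal.
#' @param fixes Data frame with columns `timestamp` (POSIXct, UTC),
#'   `easting`, `northing` (metres), `n_satellites` (integer count),
#'   `fix_dimension` (`"2D"` or `"3D"`) and optionally `source_row`
#'   (provenance index into the input file).
#' @param crs_label Character label for the projected CRS (not interpreted;
#'   carried through to all outputs).
#'
#' @return An object of class `io_track`.
#' @export
io_track <- function(bird_id, fixes, crs_label = "unknown") {
  stopifnot(is.character(bird_id), length(bird_id) == 1L)
  fixes <- as.data.frame(fixes)
  required <- c("timestamp", "easting", "northing")
  missing_cols <- setdiff(required, names(fixes))
  if (length(missing_cols) > 0L) {
    stop("fixes is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!inherits(fixes$timestamp, "POSIXct")) {
    stop("fixes$timestamp must be POSIXct")
  }
  attr(fixes$timestamp, "tzone") <- "UTC"
  if (is.null(fixes$n_satellites)) fixes$n_satellites <- NA_integer_
  if (is.null(fixes$fix_dimension)) fixes$fix_dimension <- "3D"
  if (is.null(fixes$source_row)) fixes$source_row <- seq_len(nrow(fixes))
  if (nrow(fixes) < 2L) stop("a track needs at least 2 fixes")
  if (any(!is.finite(fixes$easting)) || any(!is.finite(fixes$northing))) {
    stop("easting/northing must be finite")
  }
  o <- order(fixes$timestamp)
  fixes <- fixes[o, , drop = FALSE]
  rownames(fixes) <- NULL
  dt <- diff(as.numeric(fixes$timestamp))
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L]
    stop(sprintf(
      "timestamps must be strictly increasing; duplicate/non-increasing at source rows %d and %d",
      fixes$source_row[bad], fixes$source_row[bad + 1L]
    ))
  }
  structure(
    list(bird_id = bird_id, fixes = fixes, crs_label = crs_label),
    class = "io_track"
  )
}

#' @export
print.io_track <- function(x, ...) {
  n <- nrow(x$fixes)
  span <- diff(range(as.numeric(x$fixes$timestamp))) / 86400
  cat(sprintf(
    "<io_track> bird %s: %d fixes over %.1f days [%s]\n",
    x$bird_id, n, span, x$crs_label
  ))
  invisible(x)
}

#' Number of fixes in a track
#' @param track An `io_track`.
#' @return Integer fix count.
#' @export
n_fixes <- function(track) nrow(track$fixes)

#' Timestamps of a track's fixes
#' @param track An `io_track`.
#' @return POSIXct vector (UTC).
#' @export
track_times <- function(track) track$fixes$timestamp

#' Coordinate matrix of a track
#' @param track An `io_track`.
#' @return Two-column matrix (easting, northing) in metres.
#' @export
track_coords <- function(track) {
  cbind(easting = track$fixes$easting, northing = track$fixes$northing)
}

#' Restrict a track to a subset of fixes
#' @param track An `io_track`.
#' @param idx Integer indices (kept in time order) .
#' @return An `io_track` with the selected fixes.
#' @export
subset_track <- function(track, idx) {
  io_track(track$bird_id, track$fixes[sort(unique(idx)), , drop = FALSE],
           track$crs_label)
}

#' Read GPS tracking data from CSV
#'
#' Expects columns `id`, `timestamp` (ISO-8601, UTC), `easting`, `northing`,
#' `n_satellites`, `fix_dimension`. One `io_track` is returned per unique id.
#' Duplicate `(id, timestamp)` pairs are rejected, naming the offending source
#' rows. Fixes recorded within `trim_hours` of an individual's first fix are
#' dropped (post-release acclimation trim; set to 0 to disable).
#'
#' @param path CSV file path.
#' @param crs_label Projected CRS label attached to each track.
#' @param trim_hours Hours to trim after the first fix (default 48).
#' @return Named list of `io_track` objects.
#' @export
read_tracks <- function(path, crs_label = "unknown", trim_hours = 48) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "timestamp", "easting", "northing",
                "n_satellites", "fix_dimension")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("input CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw$source_row <- seq_len(nrow(raw))
  ts <- .parse_iso_times(raw$timestamp)
  if (anyNA(ts)) {
    bad <- raw$source_row[is.na(ts)]
    stop("unparseable timestamp(s) at source row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  raw$timestamp <- ts
  out <- list()
  for (id in unique(raw$id)) {
    sub <- raw[raw$id == id, , drop = FALSE]
    dup <- duplicated(sub$timestamp) | duplicated(sub$timestamp, fromLast = TRUE)
    if (any(dup)) {
      stop(sprintf("duplicate timestamps for id %s at source rows: %s",
                   id, paste(sub$source_row[dup], collapse = ", ")))
    }
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    if (trim_hours > 0) {
      keep <- as.numeric(sub$timestamp) >=
        as.numeric(sub$timestamp[1L]) + trim_hours * 3600
      if (sum(keep) < 2L) {
        stop(sprintf("id %s: fewer than 2 fixes remain after the %g-h trim",
                     id, trim_hours))
      }
      sub <- sub[keep, , drop = FALSE]
    }
    out[[as.character(id)]] <- io_track(
      as.character(id),
      sub[, c("timestamp", "easting", "northing",
              "n_satellites", "fix_dimension", "source_row")],
      crs_label
    )
  }
  out
}

# lenient ISO-8601 parser: tries each format, leaves NA where none matches
.parse_iso_times <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (f in fmts) {
    nas <- is.na(out)
    if (!any(nas)) break
    out[nas] <- as.POSIXct(strptime(x[nas], f, tz = "UTC"))
  }
  out
}

#' Write cleaned tracks to CSV
#'
#' @param tracks A single `io_track` or list of them.
#' @param path Output CSV path.
#' @param outlier_flags Optional list (parallel to `tracks`) of integer fix
#'   indices flagged by [flag_outliers()]; written as a 0/1 `outlier_flag`
#'   column.
#' @return Invisibly, the written data frame.
#' @export
write_tracks_csv <- function(tracks, path, outlier_flags = NULL) {
  if (inherits(tracks, "io_track")) tracks <- list(tracks)
  rows <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    df <- tr$fixes
    flag <- integer(nrow(df))
    if (!is.null(outlier_flags) && length(outlier_flags) >= i) {
      flag[outlier_flags[[i]]] <- 1L
    }
    data.frame(
      id = tr$bird_id,
      timestamp = format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      easting = df$easting, northing = df$northing,
      n_satellites = df$n_satellites, fix_dimension = df$fix_dimension,
      outlier_flag = flag
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Screen fixes by GPS solution quality
#'
#' Retains only fixes computed from at least three satellites with a
#' three-dimensional solution; fixes failing either rule are the classic
#' low-quality GPS solutions that dominate gross position error.
#'
#' @param track An `io_track`.
#' @param min_satellites Minimum satellite count (default 3).
#' @return List with `track` (filtered, order preserved) and `removed`
#'   (number of fixes dropped).
#' @export
filter_fix_quality <- function(track, min_satellites = 3) {
  f <- track$fixes
  sat <- f$n_satellites
  sat[is.na(sat)] <- 0L
  keep <- sat >= min_satellites & f$fix_dimension == "3D"
  if (sum(keep) < 2L) {
    stop(sprintf("bird %s: quality filter removed all (or all but one) fixes",
                 track$bird_id))
  }
  list(
    track = io_track(track$bird_id, f[keep, , drop = FALSE], track$crs_label),
    removed = sum(!keep)
  )
}

#' Flag improbable fixes by speed and core displacement
#'
#' A fix is flagged when the minimum straight-line speed required to reach it
#' from *both* temporal neighbours exceeds `max_speed` (requiring both sides
#' makes the rule robust to a single bad neighbour), or when its distance from
#' the track's coordinate-wise median exceeds `max_core_distance`. Endpoint
#' fixes have a single neighbour, which is then decisive. Flags are returned;
#' removal is the caller's choice.
#'
#' @param track An `io_track` (already quality-filtered).
#' @param max_speed Maximum plausible speed, m/h (default 30000).
#' @param max_core_distance Maximum displacement from the median location,
#'   metres (default 50000).
#' @return Integer vector of flagged fix indices (possibly empty).
#' @export
flag_outliers <- function(track, max_speed = 30000, max_core_distance = 50000) {
  if (max_speed <= 0 || max_core_distance <= 0) {
    stop("max_speed and max_core_distance must be positive")
  }
  xy <- track_coords(track)
  t_h <- as.numeric(track$fixes$timestamp) / 3600
  n <- nrow(xy)
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  v <- d / diff(t_h)                      # speed on each inter-fix leg
  sp_prev <- c(Inf, v)                    # speed needed from previous neighbour
  sp_next <- c(v, Inf)                    # speed needed from next neighbour
  both_fast <- pmin(sp_prev, sp_next) > max_speed
  med <- c(stats::median(xy[, 1]), stats::median(xy[, 2]))
  core_d <- sqrt((xy[, 1] - med[1])^2 + (xy[, 2] - med[2])^2)
  which(both_fast | core_d > max_core_distance)
}

#' Calibrate horizontal GPS error from stationary reference tags
#'
#' Each tag sat at a fixed (unknown) point; deviations are the 2-D distances
#' of its fixes from that tag's centroid. The reported statistic is the RMS of
#' these distances pooled over tags, so an isotropic per-axis error sigma maps
#' to `sqrt(2) * sigma`. The 95% CI comes from the chi-squared distribution of
#' the pooled sum of squared deviations on `2 * (n - n_tags)` degrees of
#' freedom (two coordinates per fix, one estimated centroid per tag per axis).
#'
#' @param stationary_fixes Data frame with columns `tag_id`, `easting`,
#'   `northing` (metres).
#' @return List of class `io_error_calibration` with `horizontal_rms`,
#'   `horizontal_ci` (95%), `n_fixes`, `n_tags`, `df`.
#' @export
calibrate_error <- function(stationary_fixes) {
  f <- as.data.frame(stationary_fixes)
  stopifnot(all(c("tag_id", "easting", "northing") %in% names(f)))
  n <- nrow(f)
  if (n < 10L) stop("need at least 10 stationary fixes to calibrate error")
  ss <- 0
  for (tag in unique(f$tag_id)) {
    sub <- f[f$tag_id == tag, , drop = FALSE]
    cx <- mean(sub$easting); cy <- mean(sub$northing)
    ss <- ss + sum((sub$easting - cx)^2 + (sub$northing - cy)^2)
  }
  n_tags <- length(unique(f$tag_id))
  df <- 2 * (n - n_tags)
  if (df <= 0) stop("not enough fixes per tag to estimate error")
  # point estimate: plain RMS of the distances; CI: SS / sigma_axis^2 ~
  # chi^2_df for the per-axis variance, mapped to the distance-RMS scale
  # (population distance-RMS = sqrt(2) * sigma_axis). The CI is widened to
  # include the point estimate when the centroid-df correction would nudge it
  # past the lower bound at very small per-tag sample sizes.
  rms <- sqrt(ss / n)
  ci <- if (ss == 0) c(0, 0) else {
    ci0 <- sqrt(2 * ss / stats::qchisq(c(0.975, 0.025), df))
    c(min(ci0[1], rms), max(ci0[2], rms))
  }
  structure(
    list(horizontal_rms = rms, horizontal_ci = ci,
         n_fixes = n, n_tags = n_tags, df = df),
    class = "io_error_calibration"
  )
}

#' @export
print.io_error_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> horizontal RMS %.2f m (95%% CI %.2f-%.2f), n = %d fixes, %d tags\n",
    x$horizontal_rms, x$horizontal_ci[1], x$horizontal_ci[2], x$n_fixes, x$n_tags
  ))
  invisible(x)
}

#' Write a calibration report as JSON
#' @param calibration Result of [calibrate_error()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_calibration_json <- function(calibration, path) {
  jsonlite::write_json(
    list(
      horizontal_rms_m = calibration$horizontal_rms,
      horizontal_ci95_m = calibration$horizontal_ci,
      n_fixes = calibration$n_fixes,
      n_tags = calibration$n_tags
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Duty cycle definition
#'
#' The programmed fix schedule: one fix every `day_interval` hours through the
#' local day window `[day_start, day_end)` and every `night_interval` hours
#' from `day_end` until the next `day_start`. The half-open day window puts the
#' `day_end` fix in the night block, which is what yields 16 fixes per day for
#' the default 1-h/3-h programme.
#'
#' @param day_start,day_end Local clock hours bounding the day window
#'   (defaults 6 and 18).
#' @param day_interval,night_interval Fix intervals in hours (defaults 1, 3).
#' @return List of class `io_duty_cycle`.
#' @export
duty_cycle <- function(day_start = 6, day_end = 18,
                       day_interval = 1, night_interval = 3) {
  stopifnot(day_interval > 0, night_interval > 0,
            day_start >= 0, day_end > day_start, day_end <= 24)
  structure(
    list(day_start = day_start, day_end = day_end,
         day_interval = day_interval, night_interval = night_interval),
    class = "io_duty_cycle"
  )
}

#' Generate scheduled fix times under a duty cycle
#'
#' @param duty An [duty_cycle()] object.
#' @param start POSIXct start (UTC); the schedule begins at the day-window
#'   start of the local date containing `start`.
#' @param n_days Number of whole schedule days to generate.
#' @param local_offset_hours Local clock offset from UTC in hours
#'   (default -10, Hawai`i standard time).
#' @return POSIXct vector (UTC) of scheduled fix times.
#' @export
schedule_fixes <- function(duty, start, n_days, local_offset_hours = -10) {
  stopifnot(inherits(duty, "io_duty_cycle"), n_days >= 1)
  start_local <- as.numeric(start) + local_offset_hours * 3600
  day0 <- floor(start_local / 86400) * 86400    # local midnight
  day_hours <- seq(duty$day_start, duty$day_end - 1e-9, by = duty$day_interval)
  night_hours <- seq(duty$day_end, duty$day_start + 24 - 1e-9,
                     by = duty$night_interval)
  one_day <- c(day_hours, night_hours) * 3600
  local_times <- rep(day0 + (seq_len(n_days) - 1) * 86400, each = length(one_day)) +
    rep(one_day, times = n_days)
  as.POSIXct(local_times - local_offset_hours * 3600,
             origin = "1970-01-01", tz = "UTC")
}

#' Local clock hours of a track's fixes
#' @param times POSIXct (UTC).
#' @param local_offset_hours Offset from UTC in hours (default -10).
#' @return Numeric local clock hour in `[0, 24)`.
#' @export
local_hour <- function(times, local_offset_hours = -10) {
  ((as.numeric(times) + local_offset_hours * 3600) / 3600) %% 24
}
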