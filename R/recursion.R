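#' Regions for recursion (revisitation) analysis
#'
#' A region is either a closed disc (`region_circle`) or a simple polygon
#' (`region_polygon`), in the same projected metre coordinates as the tracks.
#' Membership is boundary-inclusive.
#'
#' @param center Length-2 numeric (easting, northing) of the disc centre.
#' @param radius Disc radius in metres (> 0).
#' @return An `io_region` object.
#' @export
region_circle <- function(center, radius) {
  stopifnot(length(center) == 2, is.finite(center), radius > 0)
  structure(list(type = "circle", center = as.numeric(center),
                 radius = radius), class = "io_region")
}

#' @rdname region_circle
#' @param coords Two-column matrix of polygon vertices (metres); the ring is
#'   closed implicitly and must have at least 3 distinct vertices.
#' @export
region_polygon <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, all(is.finite(coords)))
  if (nrow(coords) < 3) stop("polygon needs at least 3 distinct vertices")
  # drop an explicitly repeated closing vertex
  n <- nrow(coords)
  if (all(coords[1, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
  if (nrow(coords) < 3) stop("polygon needs at least 3 distinct vertices")
  structure(list(type = "polygon", coords = coords), class = "io_region")
}

#' Test points for membership in a region (boundary inclusive)
#' @param pts Two-column coordinate matrix.
#' @param region An `io_region`.
#' @return Logical vector.
#' @export
point_in_region <- function(pts, region) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (region$type == "circle") {
    d2 <- (pts[, 1] - region$center[1])^2 + (pts[, 2] - region$center[2])^2
    return(d2 <= region$radius^2 * (1 + 1e-12) + 1e-9)
  }
  .pip_evenodd(pts, region$coords)
}

# even-odd ray casting with boundary points counted as inside
.pip_evenodd <- function(pts, poly) {
  n <- nrow(poly); m <- nrow(pts)
  inside <- logical(m)
  on_edge <- logical(m)
  px <- pts[, 1]; py <- pts[, 2]
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # boundary check: distance from point to segment (xi,yi)-(xj,yj)
    ex <- xj - xi; ey <- yj - yi
    len2 <- ex^2 + ey^2
    tproj <- if (len2 > 0) pmin(pmax(((px - xi) * ex + (py - yi) * ey) / len2, 0), 1) else 0
    dx <- px - (xi + tproj * ex); dy <- py - (yi + tproj * ey)
    on_edge <- on_edge | (dx * dx + dy * dy <= 1e-12)
    j <- i
  }
  inside | on_edge
}

# Inside time-intervals of a piecewise-linear trajectory w.r.t. a region.
# Returns a 2-column matrix of (entry, exit) times in seconds, maximal and
# non-overlapping. Crossing times are linear interpolations along each chord.
.inside_intervals <- function(xy, tsec, region) {
  n <- nrow(xy)
  if (region$type == "circle") {
    ints <- .circle_chord_intervals(xy, tsec, region$center, region$radius)
  } else {
    ints <- .polygon_chord_intervals(xy, tsec, region)
  }
  .merge_touching(ints)
}

# vectorized over chords: the inside part of chord i is [s1, s2] /\ [0, 1]
# where s1 <= s2 are the roots of |p1 + s d - c|^2 = r^2
.circle_chord_intervals <- function(xy, tsec, center, r) {
  n <- nrow(xy)
  if (n < 2) {
    inside <- point_in_region(xy, region_circle(center, r))
    if (n == 1 && inside) return(cbind(tsec, tsec))
    return(matrix(numeric(0), ncol = 2))
  }
  p1x <- xy[-n, 1]; p1y <- xy[-n, 2]
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  fx <- p1x - center[1]; fy <- p1y - center[2]
  a <- dx * dx + dy * dy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  t1 <- tsec[-n]; t2 <- tsec[-1]
  out_lo <- rep(NA_real_, n - 1); out_hi <- rep(NA_real_, n - 1)

  deg <- a <= 0                       # stationary chord: inside iff endpoint is
  if (any(deg)) {
    ins <- cc[deg] <= 1e-9
    out_lo[deg][ins] <- t1[deg][ins]
    out_hi[deg][ins] <- t2[deg][ins]
  }
  nd <- !deg
  if (any(nd)) {
    disc <- b[nd]^2 - 4 * a[nd] * cc[nd]
    hit <- disc > 0
    idx <- which(nd)[hit]
    if (length(idx)) {
      sq <- sqrt(disc[hit])
      s1 <- (-b[idx] - sq) / (2 * a[idx])
      s2 <- (-b[idx] + sq) / (2 * a[idx])
      lo <- pmax(s1, 0); hi <- pmin(s2, 1)
      ok <- lo < hi | (lo == hi & lo >= 0 & hi <= 1)
      idx <- idx[ok]; lo <- lo[ok]; hi <- hi[ok]
      out_lo[idx] <- t1[idx] + lo * (t2[idx] - t1[idx])
      out_hi[idx] <- t1[idx] + hi * (t2[idx] - t1[idx])
    }
  }
  keep <- !is.na(out_lo)
  cbind(out_lo[keep], out_hi[keep])
}

.polygon_chord_intervals <- function(xy, tsec, region) {
  n <- nrow(xy)
  poly <- region$coords
  m <- nrow(poly)
  p1x <- xy[-n, 1]; p1y <- xy[-n, 2]
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  cross_s <- vector("list", n - 1)
  j <- m
  for (i in seq_len(m)) {
    qx <- poly[j, 1]; qy <- poly[j, 2]
    ex <- poly[i, 1] - qx; ey <- poly[i, 2] - qy
    den <- dx * ey - dy * ex
    s <- ((qx - p1x) * ey - (qy - p1y) * ex) / den
    u <- ((qx - p1x) * dy - (qy - p1y) * dx) / den
    hit <- is.finite(s) & s > 1e-12 & s < 1 - 1e-12 & u >= -1e-12 & u <= 1 + 1e-12
    for (kk in which(hit)) cross_s[[kk]] <- c(cross_s[[kk]], s[kk])
    j <- i
  }
  ints <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    sv <- sort(unique(c(0, cross_s[[k]], 1)))
    mids <- (sv[-length(sv)] + sv[-1]) / 2
    midpts <- cbind(p1x[k] + mids * dx[k], p1y[k] + mids * dy[k])
    ins <- point_in_region(midpts, region)
    if (any(ins)) {
      lo <- sv[-length(sv)][ins]; hi <- sv[-1][ins]
      ints[[k]] <- cbind(tsec[k] + lo * (tsec[k + 1] - tsec[k]),
                         tsec[k] + hi * (tsec[k + 1] - tsec[k]))
    }
  }
  do.call(rbind, c(list(matrix(numeric(0), ncol = 2)), ints))
}

# merge intervals that touch or overlap (tolerance 1 ms)
.merge_touching <- function(ints, tol = 1e-3) {
  if (nrow(ints) == 0) return(ints)
  ints <- ints[order(ints[, 1]), , drop = FALSE]
  lo <- ints[1, 1]; hi <- ints[1, 2]
  out <- NULL
  for (k in seq_len(nrow(ints))[-1]) {
    if (ints[k, 1] <= hi + tol) {
      hi <- max(hi, ints[k, 2])
    } else {
      out <- rbind(out, c(lo, hi))
      lo <- ints[k, 1]; hi <- ints[k, 2]
    }
  }
  rbind(out, c(lo, hi))
}

#' Visits of a track to a region
#'
#' The trajectory is treated as piecewise linear between fixes; entry and exit
#' times are found by linear interpolation along each chord (for circles the
#' chord-disc intersection is solved exactly). Consecutive visits separated by
#' less than `time_threshold` hours outside the region are merged into one
#' visit; a threshold of 0 means no merging. Entries/exits that interpolate
#' across a sampling gap longer than `gap_flag_hours` are flagged
#' low-confidence (nocturnal 3-h gaps make such crossings common).
#'
#' @param track An `io_track`.
#' @param region An `io_region` from [region_circle()] or [region_polygon()].
#' @param time_threshold Merge threshold in hours (default 0 = none).
#' @param gap_flag_hours Sampling-gap length above which an interpolated
#'   crossing is flagged (default 12).
#' @return Object of class `io_recursion`: `visits` (data frame: `entry`,
#'   `exit` POSIXct, `duration_hours`, `first_fix_index`, `low_confidence`,
#'   `ongoing`), `n_revisits`, `return_times` (hours between consecutive
#'   visits), `time_threshold`.
#' @export
visits_to_region <- function(track, region, time_threshold = 0,
                             gap_flag_hours = 12) {
  stopifnot(inherits(region, "io_region"))
  xy <- track_coords(track)
  tsec <- as.numeric(track_times(track))
  ints <- .inside_intervals(xy, tsec, region)
  if (time_threshold > 0 && nrow(ints) > 1) {
    gaps <- ints[-1, 1] - ints[-nrow(ints), 2]
    keep_break <- gaps >= time_threshold * 3600
    ints <- .regroup_intervals(ints, keep_break)
  }
  .recursion_result(track, region, ints, tsec, time_threshold, gap_flag_hours)
}

.regroup_intervals <- function(ints, keep_break) {
  grp <- cumsum(c(TRUE, keep_break))
  t(vapply(split(seq_len(nrow(ints)), grp), function(ix) {
    c(min(ints[ix, 1]), max(ints[ix, 2]))
  }, numeric(2)))
}

.recursion_result <- function(track, region, ints, tsec, time_threshold,
                              gap_flag_hours) {
  n <- length(tsec)
  if (nrow(ints) == 0) {
    visits <- data.frame(
      entry = as.POSIXct(character(), tz = "UTC"),
      exit = as.POSIXct(character(), tz = "UTC"),
      duration_hours = numeric(0), first_fix_index = integer(0),
      low_confidence = logical(0), ongoing = logical(0)
    )
    return(structure(list(target = region, visits = visits, n_revisits = 0L,
                          return_times = numeric(0),
                          time_threshold = time_threshold),
                     class = "io_recursion"))
  }
  entry <- ints[, 1]; exit <- ints[, 2]
  # first sampled fix falling inside the visit
  ffi <- vapply(seq_len(nrow(ints)), function(k) {
    ix <- which(tsec >= entry[k] - 1e-6 & tsec <= exit[k] + 1e-6)
    if (length(ix)) ix[1] else NA_integer_
  }, integer(1))
  gap_h <- gap_flag_hours * 3600
  gaps <- diff(tsec)
  crossing_gap <- function(tt) {
    i <- findInterval(tt - 1e-6, tsec)
    i >= 1 & i < n & gaps[pmax(i, 1)] > gap_h
  }
  low_conf <- crossing_gap(entry) | crossing_gap(exit)
  ongoing <- c(rep(FALSE, nrow(ints) - 1),
               abs(exit[nrow(ints)] - tsec[n]) < 1e-6)
  visits <- data.frame(
    entry = as.POSIXct(entry, origin = "1970-01-01", tz = "UTC"),
    exit = as.POSIXct(exit, origin = "1970-01-01", tz = "UTC"),
    duration_hours = (exit - entry) / 3600,
    first_fix_index = ffi,
    low_confidence = low_conf,
    ongoing = ongoing
  )
  structure(
    list(target = region, visits = visits, n_revisits = nrow(visits),
         return_times = if (nrow(ints) > 1) (entry[-1] - exit[-length(exit)]) / 3600
                        else numeric(0),
         time_threshold = time_threshold),
    class = "io_recursion"
  )
}

#' @export
print.io_recursion <- function(x, ...) {
  cat(sprintf("<io_recursion> %d visit(s) to %s region; threshold %g h\n",
              x$n_revisits, x$target$type, x$time_threshold))
  invisible(x)
}

#' Commuting-trip metrics relative to the place of residency
#'
#' Within the supplied commuting windows, a commuting trip is a completed
#' excursion: an exit from the residency polygon followed by a return into it.
#' Trip duration is the time outside per excursion (time to return); residency
#' bouts are the visit durations inside between excursions. Excursions still
#' open when a window ends (no observed return) are not counted as commutes
#' but reported in `open_excursions`.
#'
#' @param track An `io_track` (full cleaned track).
#' @param residency_polygon An `io_region` polygon — normally the 95% isopleth
#'   of the stationary-state home range.
#' @param commuting_windows Data frame with POSIXct columns `start`, `end`
#'   delimiting commuting segments (may be empty).
#' @return Object of class `io_commuting_summary`: `n_commutes`,
#'   `commute_durations` (h), `between_commute_residency` (h),
#'   `proportion_time_commuting` (commuting-window time over total tracked
#'   time), `open_excursions`.
#' @export
commuting_summary <- function(track, residency_polygon, commuting_windows) {
  tsec <- as.numeric(track_times(track))
  total_h <- (tsec[length(tsec)] - tsec[1]) / 3600
  out <- list(n_commutes = 0L, commute_durations = numeric(0),
              between_commute_residency = numeric(0),
              proportion_time_commuting = 0, open_excursions = 0L)
  if (is.null(commuting_windows) || nrow(commuting_windows) == 0) {
    return(structure(out, class = "io_commuting_summary"))
  }
  win_h <- 0
  for (w in seq_len(nrow(commuting_windows))) {
    ws <- as.numeric(commuting_windows$start[w])
    we <- as.numeric(commuting_windows$end[w])
    win_h <- win_h + (we - ws) / 3600
    sel <- which(tsec >= ws & tsec <= we)
    if (length(sel) < 2) next
    sub <- subset_track(track, sel)
    rec <- visits_to_region(sub, residency_polygon, time_threshold = 0)
    v <- rec$visits
    if (nrow(v) >= 2) {
      out$n_commutes <- out$n_commutes + (nrow(v) - 1L)
      out$commute_durations <- c(out$commute_durations, rec$return_times)
    }
    if (nrow(v) >= 1) {
      closed <- !v$ongoing
      out$between_commute_residency <- c(out$between_commute_residency,
                                         v$duration_hours[closed])
      # trailing outside period with no return
      sub_t <- as.numeric(track_times(sub))
      if (as.numeric(v$exit[nrow(v)]) < sub_t[length(sub_t)] - 1e-6) {
        out$open_excursions <- out$open_excursions + 1L
      }
    }
  }
  out$proportion_time_commuting <- if (total_h > 0) win_h / total_h else 0
  structure(out, class = "io_commuting_summary")
}

#' @export
print.io_commuting_summary <- function(x, ...) {
  cat(sprintf(
    "<io_commuting_summary> %d commute(s); median duration %.1f h; median residency %.1f h; prop. time commuting %.2f\n",
    x$n_commutes,
    if (length(x$commute_durations)) stats::median(x$commute_durations) else NA,
    if (length(x$between_commute_residency)) stats::median(x$between_commute_residency) else NA,
    x$proportion_time_commuting
  ))
  invisible(x)
}

# fast path used by find_nest: revisit count / total residency / mean return
# for a disc, with absences shorter than min_sep_h merged into the current
# visit (brief excursions do not end a visit), so a revisit is a return after
# an absence of at least min_sep_h
.circle_visit_stats <- function(xy, tsec, center, r, min_sep_h) {
  ints <- .merge_touching(.circle_chord_intervals(xy, tsec, center, r))
  if (nrow(ints) > 1 && min_sep_h > 0) {
    gaps <- ints[-1, 1] - ints[-nrow(ints), 2]
    ints <- .regroup_intervals(ints, gaps >= min_sep_h * 3600)
  }
  nv <- nrow(ints)
  if (nv == 0) return(c(0, 0, Inf))
  res <- sum(ints[, 2] - ints[, 1]) / 3600
  ret <- if (nv > 1) mean((ints[-1, 1] - ints[-nv, 2]) / 3600) else Inf
  c(nv, res, ret)
}

#' Locate the most probable nest site from revisitation statistics
#'
#' For every diurnal fix, visits to a `search_radius`-metre disc centred on it
#' are computed with absences shorter than `min_separation` hours merged into
#' the ongoing visit, so a revisit is a genuine return after at least
#' `min_separation` hours away (brief excursions and GPS jitter across the
#' disc boundary do not inflate the count). Candidates are ranked by the
#' composite score `n_revisits * total_residency / mean_return`, which
#' requires a candidate to do well on all three nest signatures at once —
#' many returns, long time in attendance, short absences. (A strict
#' most-revisits-first ordering is not used: continuous attendance merges
#' into few long visits, so it would systematically prefer incidentally
#' passed-through locations over a well-attended nest.) Merged return times
#' are bounded below by `min_separation`, so the ratio is well behaved; ties
#' break toward longer residency. When no candidate is revisited (all score
#' at most one visit) the result is flagged `no_nest_signal`.
#'
#' @param track An `io_track`, restricted by the caller to a breeding-season
#'   window.
#' @param search_radius Disc radius in metres (default 20, about three times
#'   the GPS error).
#' @param min_separation Minimum absence in hours for a return to count as a
#'   revisit (default 12).
#' @param diurnal_only Use only fixes with local time in the day window
#'   (default TRUE).
#' @param local_offset_hours Local clock offset from UTC (default -10).
#' @return List of class `io_nest_candidates`: `ranking` (data frame sorted
#'   best-first with candidate index, coordinates, `n_revisits`,
#'   `total_residency_hours`, `mean_return_hours`), `location` (best
#'   candidate's easting/northing), `no_nest_signal`.
#' @export
find_nest <- function(track, search_radius = 20, min_separation = 12,
                      diurnal_only = TRUE, local_offset_hours = -10) {
  xy <- track_coords(track)
  tsec <- as.numeric(track_times(track))
  if (diurnal_only) {
    lh <- local_hour(track_times(track), local_offset_hours)
    cand <- which(lh >= 6 & lh < 18)
  } else {
    cand <- seq_len(nrow(xy))
  }
  if (length(cand) == 0) stop("no diurnal fixes to use as nest candidates")
  stats_m <- matrix(NA_real_, nrow = length(cand), ncol = 3)
  for (k in seq_along(cand)) {
    stats_m[k, ] <- .circle_visit_stats(xy, tsec, xy[cand[k], ],
                                        search_radius, min_separation)
  }
  ranking <- data.frame(
    fix_index = cand,
    easting = xy[cand, 1], northing = xy[cand, 2],
    n_revisits = stats_m[, 1],
    total_residency_hours = stats_m[, 2],
    mean_return_hours = stats_m[, 3]
  )
  ranking$score <- ifelse(
    is.finite(ranking$mean_return_hours) & ranking$mean_return_hours > 0,
    ranking$n_revisits * ranking$total_residency_hours /
      ranking$mean_return_hours,
    0
  )
  o <- order(-ranking$score, -ranking$total_residency_hours,
             ranking$mean_return_hours)
  ranking <- ranking[o, , drop = FALSE]
  rownames(ranking) <- NULL
  # refine the winning candidate onto the attendance cluster by mean shift:
  # the reported location is the centroid of the fixes within the search
  # radius, iterated, which averages out the GPS error on any single fix
  loc <- c(ranking$easting[1], ranking$northing[1])
  for (it in 1:3) {
    sel <- (xy[, 1] - loc[1])^2 + (xy[, 2] - loc[2])^2 <= search_radius^2
    if (!any(sel)) break
    loc <- c(mean(xy[sel, 1]), mean(xy[sel, 2]))
  }
  structure(
    list(ranking = ranking,
         location = c(easting = loc[1], northing = loc[2]),
         no_nest_signal = max(ranking$n_revisits) <= 1),
    class = "io_nest_candidates"
  )
}

#' @export
print.io_nest_candidates <- function(x, ...) {
  cat(sprintf("<io_nest_candidates> best: (%.1f, %.1f), %g revisits%s\n",
              x$location[1], x$location[2], x$ranking$n_revisits[1],
              if (x$no_nest_signal) " [no nest signal]" else ""))
  invisible(x)
}

#' Estimate the hatch date from nest-site residency
#'
#' Visits to a `radius`-metre disc around the nest are computed with no merge
#' threshold. The hatch date is the calendar date (local time) of the start of
#' the earliest visit whose duration reaches `residency_peak` hours *and*
#' whose preceding absence (return time) is at most `return_near_zero` hours;
#' the first visit of the series, having no preceding absence, qualifies on
#' duration alone. If no visit qualifies the hatch date is absent.
#'
#' The default `return_near_zero` of 6 h is the shortest absence the 1-h/3-h
#' duty cycle can resolve reliably: a single missed nocturnal fix registers,
#' after linear interpolation, as an absence of up to about two night
#' intervals.
#'
#' @param track An `io_track`.
#' @param nest_location Length-2 numeric (easting, northing), e.g. from
#'   [find_nest()].
#' @param radius Disc radius in metres (default 50, covering perches adjacent
#'   to the nest).
#' @param residency_peak Minimum visit duration in hours (default 90,
#'   about 3-4 days of continuous brooding).
#' @param return_near_zero Maximum preceding absence in hours (default 6).
#' @param local_offset_hours Local clock offset from UTC (default -10).
#' @return Object of class `io_nest_estimate`: `location`, `hatch_date`
#'   (Date, `NA` when the rule does not fire), `peak_residency` (longest visit
#'   in hours), `n_revisits`, `visits`.
#' @export
estimate_hatch <- function(track, nest_location, radius = 50,
                           residency_peak = 90, return_near_zero = 6,
                           local_offset_hours = -10) {
  rec <- visits_to_region(track, region_circle(nest_location, radius),
                          time_threshold = 0)
  v <- rec$visits
  hatch <- as.Date(NA)
  if (nrow(v) > 0) {
    preceding <- c(NA_real_, rec$return_times)
    qual <- v$duration_hours >= residency_peak &
      (is.na(preceding) | preceding <= return_near_zero)
    if (any(qual)) {
      entry <- v$entry[which(qual)[1]]
      hatch <- as.Date(as.POSIXct(as.numeric(entry) +
                                    local_offset_hours * 3600,
                                  origin = "1970-01-01", tz = "UTC"))
    }
  }
  structure(
    list(location = nest_location, hatch_date = hatch,
         peak_residency = if (nrow(v)) max(v$duration_hours) else 0,
         n_revisits = rec$n_revisits, visits = v),
    class = "io_nest_estimate"
  )
}

#' @export
print.io_nest_estimate <- function(x, ...) {
  cat(sprintf(
    "<io_nest_estimate> nest (%.1f, %.1f); peak residency %.1f h; hatch %s\n",
    x$location[1], x$location[2], x$peak_residency,
    if (is.na(x$hatch_date)) "not detected" else format(x$hatch_date)
  ))
  invisible(x)
}

#' Write a visit table as CSV
#' @param recursion An `io_recursion` result.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_visits_csv <- function(recursion, path) {
  v <- recursion$visits
  out <- data.frame(
    entry = format(v$entry, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    exit = format(v$exit, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    duration_hours = v$duration_hours,
    return_time_hours = c(NA, recursion$return_times)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write a nest report as JSON
#' @param estimate An `io_nest_estimate`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_nest_json <- function(estimate, path) {
  jsonlite::write_json(
    list(
      easting = unname(estimate$location[1]),
      northing = unname(estimate$location[2]),
      hatch_date = if (is.na(estimate$hatch_date)) NULL else
        format(estimate$hatch_date),
      peak_residency_hours = estimate$peak_residency,
      n_revisits = estimate$n_revisits
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
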