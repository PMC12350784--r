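test_that("boundary-crossing times are linearly interpolated", {
  # outside at x = -10 (t = 0 h), inside at x = +10 (t = 1 h); the boundary
  # at x = 0 is crossed halfway in both region flavours
  tr <- make_track_t(cbind(c(-10, 10), c(0, 0)), c(0, 1))
  circ <- region_circle(c(10, 0), 10)
  rec <- visits_to_region(tr, circ)
  expect_equal(rec$n_revisits, 1)
  entry_h <- as.numeric(rec$visits$entry - track_times(tr)[1],
                        units = "hours")
  expect_equal(entry_h, 0.5, tolerance = 1e-9)

  poly <- region_polygon(rbind(c(0, -100), c(1000, -100),
                               c(1000, 100), c(0, 100)))
  rec2 <- visits_to_region(tr, poly)
  entry2 <- as.numeric(rec2$visits$entry - track_times(tr)[1],
                       units = "hours")
  expect_equal(entry2, 0.5, tolerance = 1e-9)

  expect_error(region_polygon(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("a track entirely inside is one visit spanning the full track", {
  set.seed(21)
  xy <- matrix(rnorm(40, 0, 5), ncol = 2)
  tr <- make_track(xy)
  rec <- visits_to_region(tr, region_circle(c(0, 0), 100))
  expect_equal(rec$n_revisits, 1)
  expect_equal(rec$visits$entry, track_times(tr)[1])
  expect_equal(rec$visits$exit, track_times(tr)[20])
  expect_true(rec$visits$ongoing)
})

test_that("visit counts and crossing times match the dense 1-s oracle", {
  # sawtooth crossing a circle four times
  saw <- make_track_t(cbind(c(-300, 50, -250, 40, -350, 30, -280, 60, -320),
                            c(0, 10, 5, -10, 0, 15, -5, 5, 0)),
                      seq(0, 16, by = 2))
  fixtures <- list(
    list(track = saw, region = region_circle(c(0, 0), 100)),
    list(track = saw, region = region_polygon(rbind(c(-100, -80), c(90, -90),
                                                    c(100, 95), c(-90, 85))))
  )
  set.seed(22)
  rw <- make_track_t(apply(matrix(rnorm(120, 0, 60), ncol = 2), 2, cumsum),
                     seq(0, by = 1.5, length.out = 60))
  fixtures <- c(fixtures, list(
    list(track = rw, region = region_circle(c(30, 30), 80)),
    list(track = rw, region = region_polygon(rbind(c(-60, -60), c(120, -40),
                                                   c(150, 130), c(-40, 110))))
  ))
  for (f in fixtures) {
    rec <- visits_to_region(f$track, f$region)
    oracle <- dense_visit_oracle(f$track, f$region)
    expect_equal(rec$n_revisits, nrow(oracle))
    if (nrow(oracle) > 0) {
      expect_lt(max(abs(as.numeric(rec$visits$entry) - oracle$entry)), 1.0)
      expect_lt(max(abs(as.numeric(rec$visits$exit) - oracle$exit)), 1.0)
    }
  }
})

test_that("visit durations and gaps conserve the tracked window", {
  set.seed(23)
  xy <- apply(matrix(rnorm(400, 0, 50), ncol = 2), 2, cumsum)
  tr <- make_track(xy)
  rec <- visits_to_region(tr, region_circle(c(0, 0), 120))
  tsec <- as.numeric(track_times(tr))
  window_h <- (tsec[length(tsec)] - tsec[1]) / 3600
  inside_h <- sum(rec$visits$duration_hours)
  # outside time: leading, trailing and between-visit gaps
  v <- rec$visits
  lead_h <- as.numeric(v$entry[1] - track_times(tr)[1], units = "hours")
  trail_h <- as.numeric(track_times(tr)[n_fixes(tr)] - v$exit[nrow(v)],
                        units = "hours")
  outside_h <- lead_h + trail_h + sum(rec$return_times)
  expect_equal(inside_h + outside_h, window_h, tolerance = 1 / 3600)
  expect_length(rec$return_times, rec$n_revisits - 1)
})

test_that("revisit counts are invariant to rigid motions of track and region", {
  set.seed(24)
  xy <- apply(matrix(rnorm(300, 0, 70), ncol = 2), 2, cumsum)
  tr <- make_track(xy)
  circ <- region_circle(c(20, -10), 90)
  base <- visits_to_region(tr, circ)

  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(5e5, -3e4)
  xy2 <- sweep(xy %*% R, 2, shift, "+")
  c2 <- drop(circ$center %*% R) + shift
  moved <- visits_to_region(make_track(xy2), region_circle(c2, 90))
  expect_equal(moved$n_revisits, base$n_revisits)
  expect_equal(moved$visits$duration_hours, base$visits$duration_hours,
               tolerance = 1e-6)
})

test_that("the merge threshold fuses visits separated by short absences", {
  # inside 0-2 h, outside 2-4 h, inside 4-6 h (1-h fix spacing)
  xy <- cbind(c(0, 0, 0, 500, 500, 0, 0), rep(0, 7))
  tr <- make_track(xy)
  circ <- region_circle(c(0, 0), 100)
  none <- visits_to_region(tr, circ, time_threshold = 0)
  expect_equal(none$n_revisits, 2)
  merged <- visits_to_region(tr, circ, time_threshold = 6)
  expect_equal(merged$n_revisits, 1)
})

test_that("commuting trips require both an exit and a return", {
  # residency square around origin; excursions to x = 5000
  inside <- c(0, 0)
  seqs <- c(rep(list(inside), 5), rep(list(c(5000, 0)), 10),
            rep(list(inside), 5), rep(list(c(5000, 0)), 4))
  xy <- do.call(rbind, seqs)
  tr <- make_track(xy)
  poly <- region_polygon(rbind(c(-200, -200), c(200, -200),
                               c(200, 200), c(-200, 200)))
  wins <- data.frame(start = track_times(tr)[1],
                     end = track_times(tr)[n_fixes(tr)])
  cs <- commuting_summary(tr, poly, wins)
  expect_equal(cs$n_commutes, 1)            # the final excursion never returns
  expect_equal(cs$open_excursions, 1)
  expect_equal(length(cs$commute_durations), 1)
  expect_equal(cs$commute_durations, 10, tolerance = 0.2)

  # bird that never leaves: no commutes, and no windows means empty summary
  stay <- make_track(matrix(rnorm(60, 0, 10), ncol = 2))
  expect_equal(commuting_summary(stay, poly, wins[0, ])$n_commutes, 0)
  cs2 <- commuting_summary(stay, poly,
                           data.frame(start = track_times(stay)[1],
                                      end = track_times(stay)[30]))
  expect_equal(cs2$n_commutes, 0)
})

test_that("scripted excursions are counted with their durations", {
  # 20 excursions of 10 h each from a residency polygon, 1-h fixes
  blocks <- list()
  for (k in 1:20) {
    blocks <- c(blocks, rep(list(c(0, 0)), 6), rep(list(c(8000, 0)), 9))
  }
  blocks <- c(blocks, rep(list(c(0, 0)), 6))
  xy <- do.call(rbind, blocks)
  tr <- make_track(xy)
  poly <- region_polygon(rbind(c(-300, -300), c(300, -300),
                               c(300, 300), c(-300, 300)))
  wins <- data.frame(start = track_times(tr)[1],
                     end = track_times(tr)[n_fixes(tr)])
  cs <- commuting_summary(tr, poly, wins)
  expect_equal(cs$n_commutes, 20)
  expect_equal(median(cs$commute_durations), 10, tolerance = 0.12)
  expect_equal(cs$proportion_time_commuting, 1)
})

test_that("nest candidates rank by revisits, then residency, then return time", {
  # nest visited on 30 separate nights (>= 12 h apart); decoys visited once
  start <- as.POSIXct("2020-04-01 00:00:00", tz = "UTC")
  rows <- NULL
  for (d in 0:29) {
    day0 <- d * 24
    rows <- rbind(rows,
                  cbind(day0 + 0, 0, 0),            # at nest, midnight
                  cbind(day0 + 2, 0, 0),
                  cbind(day0 + 8, 3000 + 100 * d, 4000),
                  cbind(day0 + 14, -2500 - 90 * d, 1500))
  }
  tr <- make_track_t(rows[, 2:3], rows[, 1], start = start, id = "f1")
  nest <- find_nest(tr, diurnal_only = FALSE)
  expect_false(nest$no_nest_signal)
  expect_equal(unname(nest$location), c(0, 0))
  expect_gte(nest$ranking$n_revisits[1], 28)
  expect_lte(abs(nest$ranking$n_revisits[1] - 30), 2)

  # all fixes at unique locations > 40 m apart: no nest signal
  set.seed(25)
  lone <- make_track(cbind(seq(0, by = 60, length.out = 40),
                           seq(0, by = 45, length.out = 40)))
  expect_true(find_nest(lone, diurnal_only = FALSE)$no_nest_signal)

  # revisit tie: longer total residency wins
  rows2 <- NULL
  for (d in 0:4) {
    day0 <- d * 48
    rows2 <- rbind(rows2,
                   cbind(day0 + 0, 0, 0), cbind(day0 + 6, 0, 0),  # A: 6-h stays
                   cbind(day0 + 20, 1000, 0), cbind(day0 + 22, 1000, 0))  # B: 2-h
  }
  tr2 <- make_track_t(rows2[, 2:3], rows2[, 1], id = "f2")
  nest2 <- find_nest(tr2, diurnal_only = FALSE)
  top2 <- nest2$ranking[1, ]
  second <- nest2$ranking[nest2$ranking$n_revisits == top2$n_revisits &
                            abs(nest2$ranking$easting - 1000) < 25, ][1, ]
  expect_equal(unname(nest2$location), c(0, 0))
  expect_equal(top2$n_revisits, second$n_revisits)
  expect_gt(top2$total_residency_hours, second$total_residency_hours)
})

test_that("diurnal filtering restricts nest candidates to the day window", {
  # all fixes at local night -> no candidates survive the diurnal filter
  start <- as.POSIXct("2020-04-01 08:00:00", tz = "UTC")  # 22:00 local (UTC-10)
  tr <- io_track("f", data.frame(
    timestamp = start + (0:19) * 86400,   # same local clock time nightly
    easting = rnorm(20), northing = rnorm(20),
    n_satellites = 8L, fix_dimension = "3D"
  ))
  expect_error(find_nest(tr, diurnal_only = TRUE), "no diurnal fixes")
})

test_that("hatch-date rule needs 90 h residency and a near-zero return", {
  start <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")
  nest <- c(0, 0)
  mk <- function(spec) {
    # spec rows: (t_hours, at_nest)
    xy <- cbind(ifelse(spec[, 2] == 1, 0, 4000), 0)
    make_track_t(xy, spec[, 1], start = start)
  }
  # longest visit 60 h: no hatch date
  s1 <- rbind(cbind(seq(0, 60, 2), 1), cbind(seq(62, 80, 2), 0))
  h1 <- estimate_hatch(mk(s1), nest)
  expect_true(is.na(h1$hatch_date))
  expect_gte(h1$peak_residency, 55)

  # 100-h visit preceded by a 30-h absence: rejected at threshold 1 h,
  # accepted at a threshold wider than the absence
  s2 <- rbind(cbind(seq(0, 10, 2), 1), cbind(seq(12, 40, 2), 0),
              cbind(seq(42, 142, 2), 1))
  h2 <- estimate_hatch(mk(s2), nest, return_near_zero = 1)
  expect_true(is.na(h2$hatch_date))
  h2b <- estimate_hatch(mk(s2), nest, return_near_zero = 40)
  expect_false(is.na(h2b$hatch_date))

  # qualifying 96-h bout with a short preceding absence: earliest visit wins
  s3 <- rbind(cbind(seq(0, 10, 2), 1), cbind(c(12), 0),
              cbind(seq(14, 112, 2), 1), cbind(c(116), 0),
              cbind(seq(118, 216, 2), 1))
  h3 <- estimate_hatch(mk(s3), nest, return_near_zero = 6)
  expect_false(is.na(h3$hatch_date))
  # earliest qualifying visit starts ~14 h in: 04:00 local on 1 May
  expect_equal(h3$hatch_date, as.Date("2020-05-01"))
})

test_that("visit tables and nest reports serialize", {
  set.seed(26)
  xy <- apply(matrix(rnorm(200, 0, 60), ncol = 2), 2, cumsum)
  tr <- make_track(xy)
  rec <- visits_to_region(tr, region_circle(c(0, 0), 100))
  csv <- tempfile(fileext = ".csv")
  write_visits_csv(rec, csv)
  expect_equal(nrow(read.csv(csv)), rec$n_revisits)

  est <- estimate_hatch(tr, c(0, 0))
  js <- tempfile(fileext = ".json")
  write_nest_json(est, js)
  obj <- jsonlite::read_json(js)
  expect_equal(obj$n_revisits, est$n_revisits)
})
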