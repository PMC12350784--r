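test_that("resampling thins hourly data to 2 h and splits bursts at holes", {
  # perfectly hourly: every second fix retained at dt = 2 h
  tr <- make_track(cbind(1:25, 0), dt_hours = 1)
  rs <- resample_track(tr)
  expect_true(all(diff(as.numeric(rs$timestamp)) / 3600 == 2))
  expect_equal(rs$fix_index, seq(1, 25, by = 2))
  expect_equal(unique(rs$burst), 1L)

  # 3-h night gaps are inside the 2 h +- 50% window
  t_h <- c(0, 1, 2, 3, 4, 7, 10, 13, 14, 15, 16)
  tr2 <- make_track_t(cbind(seq_along(t_h), 0), t_h)
  rs2 <- resample_track(tr2)
  dts <- diff(as.numeric(rs2$timestamp)) / 3600
  expect_true(all(dts >= 1 & dts <= 3))
  expect_equal(unique(rs2$burst), 1L)

  # a 12-h hole splits the track into two bursts; no step spans the hole
  t_h3 <- c(0, 2, 4, 6, 18, 20, 22, 24)
  tr3 <- make_track_t(cbind(seq_along(t_h3), 0), t_h3)
  rs3 <- resample_track(tr3)
  expect_equal(length(unique(rs3$burst)), 2L)
  st <- steps_from_fixes(rs3)
  expect_true(all(st$dt_hours <= 3))
})

test_that("steps carry lengths, headings and wrapped turn angles", {
  # east, then north: one +pi/2 left turn
  xy <- rbind(c(0, 0), c(100, 0), c(100, 80))
  st <- steps_from_fixes(data.frame(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (0:2) * 7200,
    easting = xy[, 1], northing = xy[, 2], burst = 1L, fix_index = 1:3
  ))
  expect_equal(st$step_length, c(100, 80))
  expect_true(is.na(st$turn_angle[1]))
  expect_equal(st$turn_angle[2], pi / 2)
})

test_that("movement kernel fitting recovers gamma and von Mises parameters", {
  set.seed(41)
  st <- data.frame(step_length = rgamma(2000, shape = 2, scale = 260),
                   turn_angle = rvonmises(2000, 1.5))
  k <- fit_kernel(st)
  expect_lt(abs(k$gamma_shape - 2) / 2, 0.1)
  expect_lt(abs(k$gamma_scale - 260) / 260, 0.1)
  expect_lt(abs(k$vonmises_kappa - 1.5) / 1.5, 0.15)
  expect_equal(k$mean_step_length, k$gamma_shape * k$gamma_scale)

  # uniform angles: concentration near zero
  st_u <- data.frame(step_length = rgamma(2000, 2, scale = 100),
                     turn_angle = runif(2000, -pi, pi))
  expect_lt(fit_kernel(st_u)$vonmises_kappa, 0.06)

  # degenerate angles: capped with a warning
  st_d <- data.frame(step_length = rgamma(50, 2, scale = 100),
                     turn_angle = rep(0, 50))
  expect_warning(kd <- fit_kernel(st_d), "capped")
  expect_equal(kd$vonmises_kappa, 500)

  expect_error(fit_kernel(st[1:10, ]), "at least 20")
})

test_that("the von Mises sampler matches its first circular moment", {
  set.seed(42)
  for (kap in c(0.5, 2, 8)) {
    draws <- rvonmises(20000, kap)
    a_k <- besselI(kap, 1, expon.scaled = TRUE) /
      besselI(kap, 0, expon.scaled = TRUE)
    expect_equal(mean(cos(draws)), a_k, tolerance = 0.02)
    expect_lt(abs(mean(sin(draws))), 0.02)
  }
  u <- rvonmises(5000, 0)
  expect_gt(suppressWarnings(ks.test(u, "punif", -pi, pi))$p.value, 0.01)
})

test_that("strata pair one observed with n_available steps from the kernel", {
  r <- uniform_raster("forest", n = 200, res = 30)
  set.seed(43)
  fix <- data.frame(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (0:80) * 7200,
    easting = 3000 + cumsum(c(0, rnorm(80, 0, 60))),
    northing = 3000 + cumsum(c(0, rnorm(80, 0, 60))),
    burst = 1L, fix_index = 1:81
  )
  st <- steps_from_fixes(fix)
  kern <- movement_kernel(2, 80, 1)
  bs <- build_strata(st, kern, r, n_available = 30, seed = 7)
  tab <- table(bs$data$stratum, bs$data$case)
  expect_true(all(tab[, "1"] == 1))
  expect_true(all(tab[, "0"] == 30))
  # habitat covariates standardized over the dataset
  expect_equal(mean(bs$data$forest_local), 0)

  # near-degenerate von Mises: available headings hug the previous heading
  bs2 <- build_strata(st, movement_kernel(2, 80, 400), r,
                      n_available = 10, seed = 8)
  av <- bs2$data[bs2$data$case == 0, ]
  expect_lt(max(abs(av$turn_angle)), 0.3)

  # empirical available lengths against the generating gamma (KS)
  lens <- bs$data$step_length[bs$data$case == 0]
  expect_gt(suppressWarnings(
    ks.test(lens, "pgamma", shape = 2, scale = 80))$p.value, 0.01)
})

test_that("conditional logit matches survival::clogit to 4 significant digits", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  set.seed(44)
  dat <- simulate_clogit_strata(150, n_avail = 10, beta = 0.7, n_cov = 2)
  fit <- fit_conditional_logit(dat, covariates = c("x1", "x2"),
                               include_movement = FALSE, min_strata = 50)
  sv <- survival::clogit(case ~ x1 + x2 + strata(stratum), data = dat)
  expect_equal(unname(fit$coefficients),
               unname(coef(sv)), tolerance = 1e-4)
  expect_equal(unname(fit$std_errors),
               unname(sqrt(diag(vcov(sv)))), tolerance = 1e-4)
})

test_that("an uninformative covariate gets a zero coefficient", {
  set.seed(45)
  dat <- simulate_clogit_strata(80, n_avail = 5, beta = 0)
  dat$flat <- 1.7   # identical across all steps in every stratum
  fit <- suppressWarnings(
    fit_conditional_logit(dat, covariates = c("x1", "flat"),
                          include_movement = FALSE, min_strata = 50))
  expect_equal(unname(fit$coefficients["flat"]), 0, tolerance = 1e-8)
  expect_true(is.na(fit$std_errors["flat"]) || fit$std_errors["flat"] > 10)

  expect_error(fit_conditional_logit(dat[dat$stratum <= 50, ],
                                     covariates = "x1",
                                     include_movement = FALSE),
               "need more than 50")
})

test_that("conditional-logit estimates are unbiased at the simulated truth", {
  set.seed(46)
  est <- vapply(1:30, function(r) {
    dat <- simulate_clogit_strata(100, n_avail = 20, beta = 0.8)
    fit_conditional_logit(dat, covariates = "x1", include_movement = FALSE,
                          min_strata = 50)$coefficients[["x1"]]
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8), 0.06)
})

test_that("kernel adjustment inverts the exponential-family tilt exactly", {
  base <- movement_kernel(2, 500, 1.2)
  # a tilt exp(b1*l + b2*log l + bc*cos a) maps gamma/von Mises parameters
  # conjugately; the adjustment must round-trip the base kernel exactly
  b1 <- -0.0004; b2 <- 0.6; bc <- 0.5
  tilted <- movement_kernel(base$gamma_shape + b2,
                            1 / (1 / base$gamma_scale - b1),
                            base$vonmises_kappa + bc)
  fit <- structure(list(coefficients = c(step_length = -b1,
                                         log_step_length = -b2,
                                         cos_turn_angle = -bc)),
                   class = "io_ssf_fit")
  adj <- adjust_kernel(fit, tilted)
  expect_equal(adj$kernel$gamma_shape, base$gamma_shape, tolerance = 1e-12)
  expect_equal(adj$kernel$gamma_scale, base$gamma_scale, tolerance = 1e-12)
  expect_equal(adj$kernel$vonmises_kappa, base$vonmises_kappa,
               tolerance = 1e-12)

  # zero coefficients leave the kernel unchanged; the rate is shape * scale
  fit0 <- structure(list(coefficients = c(step_length = 0,
                                          log_step_length = 0,
                                          cos_turn_angle = 0)),
                    class = "io_ssf_fit")
  adj0 <- adjust_kernel(fit0, movement_kernel(2, 260, 1))
  expect_equal(adj0$mean_movement_rate, 520)

  # invalid adjustments error with diagnostics
  bad <- structure(list(coefficients = c(step_length = 1,
                                         log_step_length = 0,
                                         cos_turn_angle = 0)),
                   class = "io_ssf_fit")
  expect_error(adjust_kernel(bad, movement_kernel(2, 260, 1)),
               "invalid kernel adjustment")
})

test_that("population pooling is inverse-variance weighted with bootstrap CI", {
  mk_fit <- function(b, s) {
    structure(list(coefficients = c(forest_local = b),
                   std_errors = c(forest_local = s)),
              class = "io_ssf_fit")
  }
  # hand-computed: beta {0, 2}, sigma^2 {1, 3} -> (0/1 + 2/3)/(1 + 1/3) = 0.5
  pe <- pool_population(list(mk_fit(0, 1), mk_fit(2, sqrt(3))),
                        "forest_local", bootstrap_reps = 200, seed = 1)
  expect_equal(pe$pooled_log_rss, 0.5, tolerance = 1e-12)
  expect_equal(pe$n_individuals, 2)

  # identical individuals: pooled = beta; CI width approaches 2 * 1.96 * sigma
  fits <- replicate(6, mk_fit(1.4, 0.3), simplify = FALSE)
  pe2 <- pool_population(fits, "forest_local", bootstrap_reps = 4000, seed = 2)
  expect_equal(pe2$pooled_log_rss, 1.4, tolerance = 1e-12)
  expect_equal(diff(pe2$ci95), 2 * 1.96 * 0.3 / sqrt(6), tolerance = 0.12)
  expect_equal(pe2$interpretation, "selection")

  neg <- pool_population(list(mk_fit(-2, 0.1), mk_fit(-1.5, 0.1)),
                         "forest_local", bootstrap_reps = 500, seed = 3)
  expect_equal(neg$interpretation, "avoidance")
  wide <- pool_population(list(mk_fit(-1, 2), mk_fit(1, 2), mk_fit(0, 2)),
                          "forest_local", bootstrap_reps = 500, seed = 4)
  expect_equal(wide$interpretation, "indifference")

  expect_error(pool_population(list(mk_fit(1, 0), mk_fit(1, 1)),
                               "forest_local"), "degenerate")
  expect_error(pool_population(list(mk_fit(1, 1)), "forest_local"),
               "at least 2")
})
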