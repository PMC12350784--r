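test_that("AICc arithmetic and model selection rules", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46)
  fake <- function(a, k) structure(list(aicc = a, n_params = k),
                                   class = "io_movement_model")
  fits <- list(fake(210.1, 3), fake(208.0, 4), fake(209.5, 5))
  expect_equal(select_model(fits)$aicc, 208.0)
  # exact tie: fewer parameters wins (IID over OU)
  tie <- list(fake(200, 4), fake(200, 3))
  expect_equal(select_model(tie)$n_params, 3)
  expect_equal(select_model(list(fake(123, 3)))$aicc, 123)
  expect_error(select_model(list()), "no fitted models")
})

test_that("state-space likelihood equals the dense multivariate-normal oracle", {
  set.seed(11)
  n <- 200
  t_h <- cumsum(runif(n, 0.5, 3))
  xy <- matrix(rnorm(2 * n, 100, 250), ncol = 2)
  mu <- c(90, 110)
  for (err in c(0, 6)) {
    expect_equal(
      movement_loglik("IID", t_h, xy, mu, 250^2, error_rms = err),
      mvn_movement_loglik("IID", t_h, xy, mu, 250^2, error_rms = err),
      tolerance = 1e-9)
    expect_equal(
      movement_loglik("OU", t_h, xy, mu, 300^2, tau_position = 12,
                      error_rms = err),
      mvn_movement_loglik("OU", t_h, xy, mu, 300^2, tau_p = 12,
                          error_rms = err),
      tolerance = 1e-9)
    expect_equal(
      movement_loglik("OUF", t_h, xy, mu, 300^2, tau_position = 12,
                      tau_velocity = 2, error_rms = err),
      mvn_movement_loglik("OUF", t_h, xy, mu, 300^2, tau_p = 12, tau_v = 2,
                          error_rms = err),
      tolerance = 1e-9)
  }
})

test_that("OU collapses to IID as the position timescale vanishes", {
  set.seed(12)
  t_h <- 0:99
  xy <- matrix(rnorm(200, 0, 200), ncol = 2)
  ll_ou <- movement_loglik("OU", t_h, xy, c(0, 0), 4e4,
                           tau_position = 1e-6, error_rms = 6)
  ll_iid <- movement_loglik("IID", t_h, xy, c(0, 0), 4e4, error_rms = 6)
  expect_equal(ll_ou, ll_iid, tolerance = 1e-6)
})

test_that("OU parameters are recovered from simulated tracks", {
  ok <- vapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 1000; tau <- 12; sig <- 300
    t_h <- (0:(n - 1)) * 2
    phi <- exp(-2 / tau)
    z <- matrix(0, n, 2)
    z[1, ] <- rnorm(2, 0, sig)
    for (i in 2:n) z[i, ] <- phi * z[i - 1, ] + rnorm(2, 0, sig * sqrt(1 - phi^2))
    xy <- z + matrix(rnorm(2 * n, 0, 6 / sqrt(2)), n, 2)
    tr <- make_track_t(xy, t_h)
    fit <- suppressWarnings(fit_movement_model(tr, "OU", error_rms = 6))
    abs(fit$tau_position - tau) / tau < 0.25 &&
      abs(fit$sigma2 - sig^2) / sig^2 < 0.20
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("AICc prefers IID on white noise and OU on autocorrelated data", {
  set.seed(13)
  n <- 400
  white <- make_track_t(matrix(rnorm(2 * n, 0, 150), ncol = 2), (0:(n - 1)) * 2)
  fits <- lapply(c("IID", "OU"), function(k) {
    suppressWarnings(fit_movement_model(white, k, error_rms = 6))
  })
  expect_equal(select_model(fits)$kind, "IID")

  phi <- exp(-2 / 15)
  z <- matrix(0, n, 2); z[1, ] <- rnorm(2, 0, 300)
  for (i in 2:n) z[i, ] <- phi * z[i - 1, ] + rnorm(2, 0, 300 * sqrt(1 - phi^2))
  auto <- make_track_t(z, (0:(n - 1)) * 2)
  fits2 <- lapply(c("IID", "OU"), function(k) {
    suppressWarnings(fit_movement_model(auto, k, error_rms = 6))
  })
  expect_equal(select_model(fits2)$kind, "OU")
})

test_that("AKDE area on IID Gaussian data matches the analytic isopleth", {
  set.seed(14)
  n <- 2000; sig <- 200
  xy <- matrix(rnorm(2 * n, 0, sig), ncol = 2)
  tr <- make_track_t(xy, (0:(n - 1)) * 2)
  fit <- fit_movement_model(tr, "IID", error_rms = 0)
  hr <- akde_homerange(tr, fit, 0.95)
  analytic_ha <- pi * qchisq(0.95, 2) * sig^2 / 1e4   # ~752.7 ha
  expect_lt(abs(hr$area_ha - analytic_ha) / analytic_ha, 0.15)

  # nestedness: the 50% region sits inside the 95% region of the same fit
  hr50 <- akde_homerange(tr, fit, 0.50)
  expect_lt(hr50$area_ha, hr$area_ha)
  expect_gte(hr50$threshold_density, hr$threshold_density)
  expect_true(all(hr$area_ci_ha[1] <= hr$area_ha &
                    hr$area_ha <= hr$area_ci_ha[2]))
})

test_that("AKDE area is invariant under translation and rotation", {
  set.seed(15)
  n <- 800
  xy <- matrix(rnorm(2 * n, 0, 150), ncol = 2)
  tr <- make_track_t(xy, (0:(n - 1)) * 2)
  fit <- fit_movement_model(tr, "IID", error_rms = 0)
  base <- akde_homerange(tr, fit, 0.95)$area_ha

  th <- pi / 7
  rot <- xy %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shifted <- sweep(rot, 2, c(250000, 2100000), "+")
  tr2 <- make_track_t(shifted, (0:(n - 1)) * 2)
  fit2 <- fit_movement_model(tr2, "IID", error_rms = 0)
  expect_equal(akde_homerange(tr2, fit2, 0.95)$area_ha, base,
               tolerance = 0.02)
})

test_that("autocorrelation shrinks the effective sample size and widens the CI", {
  set.seed(16)
  n <- 600; tau <- 20
  phi <- exp(-2 / tau)
  z <- matrix(0, n, 2); z[1, ] <- rnorm(2, 0, 250)
  for (i in 2:n) z[i, ] <- phi * z[i - 1, ] + rnorm(2, 0, 250 * sqrt(1 - phi^2))
  tr <- make_track_t(z, (0:(n - 1)) * 2)
  ou <- suppressWarnings(fit_movement_model(tr, "OU", error_rms = 0))
  iid <- fit_movement_model(tr, "IID", error_rms = 0)
  expect_lt(effective_sample_size(ou), n)
  expect_equal(effective_sample_size(iid), n)
  hr_ou <- akde_homerange(tr, ou, 0.95)
  hr_iid <- akde_homerange(tr, iid, 0.95)
  rel_width <- function(hr) diff(hr$area_ci_ha) / hr$area_ha
  expect_gt(rel_width(hr_ou), rel_width(hr_iid))
})

test_that("paired log-area comparison matches the closed-form hand computation", {
  same <- compare_state_areas(c(3, 5, 8), c(3, 5, 8))
  expect_equal(same$t, 0)

  # pairs {(1,2),(1,2),(1,2),(1,4)}: d = -{log2, log2, log2, log4}
  d <- c(log(2), log(2), log(2), log(4))
  t_hand <- -mean(d) / (sd(d) / sqrt(4))
  res <- compare_state_areas(rep(1, 4), c(2, 2, 2, 4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$fold_change, exp(mean(d)))

  expect_error(compare_state_areas(c(1, -1), c(2, 2)), "positive")
  expect_error(compare_state_areas(1, 2), "at least 2")

  # large commuting ranges give a strongly negative t and ~19x fold change
  set.seed(17)
  stat <- exp(rnorm(10, log(250), 0.3))
  comm <- stat * 19 * exp(rnorm(10, 0, 0.4))
  big <- compare_state_areas(stat, comm)
  expect_lt(big$t, -3)
  expect_equal(big$fold_change, 19, tolerance = 0.35 * 19)
})

test_that("isopleths round-trip through GeoJSON as polygon regions", {
  set.seed(18)
  xy <- matrix(rnorm(1200, 0, 120), ncol = 2)
  tr <- make_track_t(xy, (0:599) * 2)
  fit <- fit_movement_model(tr, "IID", error_rms = 0)
  hr <- akde_homerange(tr, fit, 0.95)
  path <- tempfile(fileext = ".geojson")
  write_isopleths_geojson(list(hr), path,
                          properties = list(list(bird = "b1")))
  reg <- read_region_geojson(path)
  expect_s3_class(reg, "io_region")
  # the recovered ring contains the bulk of the fixes
  expect_gt(mean(point_in_region(xy, reg)), 0.85)
})
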