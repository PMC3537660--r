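tgrid <- function(n, dur = 1) seq(0, dur, length.out = n)

test_that("quintic spline reproduces constants and cubics", {
  t <- tgrid(71)
  f <- fit_quintic_spline(rep(3.2, 71), time = t)
  expect_lt(max(abs(predict(f, seq(0, 1, 0.01)) - 3.2)), 1e-10)

  cubic <- function(x) 1 + 2 * x - 3 * x^2 + 0.5 * x^3
  # the interpolating fit recovers the cubic exactly (cubics lie in the space)
  f0 <- fit_quintic_spline(cubic(t), smoothing = 0, time = t)
  expect_lt(max(abs(predict(f0, seq(0, 1, 0.01)) - cubic(seq(0, 1, 0.01)))), 1e-8)
  # the GCV fit keeps it to rounding-level bias
  fg <- fit_quintic_spline(cubic(t), time = t)
  expect_lt(max(abs(predict(fg, seq(0, 1, 0.01)) - cubic(seq(0, 1, 0.01)))), 1e-5)
})

test_that("zero smoothing interpolates the data exactly", {
  t <- tgrid(31)
  set.seed(5)
  y <- sin(2 * pi * t) + rnorm(31, 0, 0.1)
  f <- fit_quintic_spline(y, smoothing = 0, time = t)
  expect_lt(max(abs(predict(f, t) - y)), 1e-10)
})

test_that("spline preconditions are enforced", {
  expect_error(fit_quintic_spline(1:7, time = tgrid(7)),
               class = "gk_insufficient_data_error")
  y <- c(1:10, NA)
  expect_error(fit_quintic_spline(y, time = tgrid(11)), class = "gk_data_error")
  expect_error(fit_quintic_spline(1:10, time = rev(tgrid(10))),
               class = "gk_data_error")
})

test_that("GCV smoothing beats the noise floor on a noisy sine", {
  t <- tgrid(71)
  truth <- sin(2 * pi * t)
  sigma <- 0.02
  set.seed(42)
  rmse <- replicate(100, {
    f <- fit_quintic_spline(truth + rnorm(71, 0, sigma), time = t)
    sqrt(mean((predict(f, t) - truth)^2))
  })
  expect_lt(mean(rmse), sigma)
})

test_that("percent-cycle resampling is linear-exact and endpoint-preserving", {
  t <- tgrid(21, dur = 0.2)
  f <- fit_quintic_spline(t / 0.2, time = t)
  prof <- resample_to_percent_cycle(f, 0, 0.2)
  expect_length(prof, 101)
  expect_equal(prof, (0:100) / 100, tolerance = 1e-8)
  expect_equal(prof[1], predict(f, 0))
  expect_equal(prof[101], predict(f, 0.2))
  expect_error(predict(f, 0.3), class = "gk_range_error")
  expect_error(resample_to_percent_cycle(f, 0.2, 0), class = "gk_usage_error")
})

test_that("profiles are invariant to cycle duration at fixed shape", {
  # same half-sine shape digitized as a fast feeding and a slow climbing cycle
  s1 <- seq(0, 1, length.out = 71)
  s2 <- seq(0, 1, length.out = 64)
  f1 <- fit_quintic_spline(sin(pi * s1), time = s1 * 0.141)
  f2 <- fit_quintic_spline(sin(pi * s2), time = s2 * 0.313)
  p1 <- resample_to_percent_cycle(f1, 0, 0.141)
  p2 <- resample_to_percent_cycle(f2, 0, 0.313)
  expect_lt(max(abs(p1 - p2)), 1e-3)
})

test_that("profile aggregation follows sampling theory", {
  one <- aggregate_profiles(list(sin(pi * (0:100) / 100)))
  expect_equal(one$mean, sin(pi * (0:100) / 100))
  expect_equal(one$sem, rep(0, 101))
  expect_equal(one$n_cycles, 1)

  two <- aggregate_profiles(list(rep(0, 101), rep(2, 101)))
  expect_equal(two$mean, rep(1, 101))
  expect_equal(two$sem, rep(1, 101))

  # 500 noisy cycles: pointwise s.e.m. ~ sigma / sqrt(500)
  set.seed(7)
  sigma <- 0.05
  base <- sin(pi * (0:100) / 100)
  mat <- sapply(1:500, function(i) base + rnorm(101, 0, sigma))
  ag <- aggregate_profiles(mat)
  expect_equal(mean(ag$sem), sigma / sqrt(500), tolerance = 0.15)

  # aggregation commutes with permutation of the cycle list
  perm <- sample(500)
  ag2 <- aggregate_profiles(mat[, perm])
  expect_equal(ag2$mean, ag$mean)
  expect_equal(ag2$sem, ag$sem)

  expect_error(aggregate_profiles(list()), class = "gk_usage_error")
  expect_error(aggregate_profiles(matrix(0, 50, 2)), class = "gk_usage_error")
})

test_that("pipeline profiles converge to the analytic profile without noise", {
  # zero phase lag makes the analytic percent-cycle profile a pure half-sine
  gt <- generate_trial(quick_feeding(seed = 3, phase_lag = 0))
  kin <- compute_all_variables(gt$trial)
  cp <- cycle_profiles(kin)
  s <- (0:100) / 100
  amps <- c(mandibular_retraction_length = 0.019, hyoid_retraction_length = 0.014)
  for (v in names(amps)) {
    prof <- cp$value[cp$variable == v]
    expect_lt(max(abs(prof - amps[v] * sin(pi * s))), 1e-3 * amps[v])
  }
  # smoothing parameters are recorded for reproducibility
  slog <- attr(cp, "smoothing_log")
  expect_true(all(c("trial_id", "variable", "lambda") %in% names(slog)))
})

test_that("group profiles carry exact cycle counts and zero sem for n = 1", {
  study <- generate_study(
    list(f = list(params = quick_feeding(noise_sd = 0.005), n_cycles = 3,
                  n_individuals = 1),
         c = list(params = quick_climbing(noise_sd = 0.005), n_cycles = 1,
                  n_individuals = 1)),
    seed = 13)
  cp <- cycle_profiles(compute_all_variables(study$trials))
  gp <- group_profiles(cp)
  expect_setequal(unique(gp$n_cycles[gp$group == "feeding"]), 3)
  expect_true(all(gp$sem[gp$group == "climbing"] == 0))
  expect_true(all(table(gp$group, gp$variable) == 101))
  # plot layout down-samples to every 5%
  expect_setequal(unique(profile_plot_table(gp)$percent), seq(0, 100, 5))
})
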