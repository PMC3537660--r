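test_that("peak_value is the profile maximum", {
  expect_equal(peak_value((0:100) / 100), 1.0)
  expect_equal(peak_value(rep(2.7, 101)), 2.7)
  expect_error(peak_value(numeric(0)), class = "gk_usage_error")
})

test_that("Mann-Whitney U matches the worked example and degenerates safely", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)

  expect_warning(mw2 <- mann_whitney_u(c(2, 2, 2), c(2, 2)),
                 class = "gk_degenerate_warning")
  expect_equal(mw2$p_value, 1)

  # identical (but non-constant) samples show no separation
  mw3 <- mann_whitney_u(c(1, 5, 9), c(1, 5, 9))
  expect_equal(mw3$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), class = "gk_usage_error")
})

test_that("Kruskal-Wallis matches the hand-ranked example and MW ordering", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 2)

  expect_warning(kw0 <- kruskal_wallis(list(c(1, 1), c(1, 1, 1))),
                 class = "gk_degenerate_warning")
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), class = "gk_usage_error")

  # rank-based: invariant under strictly monotone transformation
  set.seed(31)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(lapply(g, exp))$H,
               tolerance = 1e-12)

  # two-group H is monotone in the Mann-Whitney separation on the same data
  set.seed(32)
  seps <- t(replicate(30, {
    a <- rnorm(10); b <- rnorm(10, runif(1, 0, 3))
    c(abs(mann_whitney_u(a, b)$U - 50), kruskal_wallis(list(a, b))$H)
  }))
  ord <- order(seps[, 1])
  expect_true(all(diff(seps[ord, 2]) >= -1e-9))
})

test_that("divergence angle matches its analytic cases and invariances", {
  u <- c(1, 1, rep(0, 99))
  expect_equal(divergence_angle(u, u), 0)
  expect_equal(divergence_angle(c(1, rep(0, 100)), c(0, 1, rep(0, 99))), 90)
  expect_equal(divergence_angle(u, c(1, rep(0, 100))), 45, tolerance = 1e-12)
  expect_error(divergence_angle(rep(0, 101), u), class = "gk_degenerate_error")

  # agreement with an independent projection-based formulation; symmetry;
  # invariance to positive rescaling; amplitude-insensitivity
  set.seed(8)
  for (i in 1:50) {
    a <- rnorm(101); b <- rnorm(101)
    proj <- sum(a * b) / sum(a * a)
    resid <- b - proj * a
    oracle <- atan2(sqrt(sum(resid^2)), proj * sqrt(sum(a^2))) * 180 / pi
    expect_equal(divergence_angle(a, b), oracle, tolerance = 1e-9)
    expect_equal(divergence_angle(a, b), divergence_angle(b, a))
    expect_equal(divergence_angle(3.7 * a, 0.2 * b), divergence_angle(a, b),
                 tolerance = 1e-9)
    expect_lt(divergence_angle(a, 2.5 * a), 1e-5)
  }
})

test_that("divergence summary and percent excess reproduce published layouts", {
  ref <- reference_feeding_climbing()
  ds <- divergence_summary(ref$divergence_angle_deg, thresholds = c(5, 10))
  expect_equal(round(ds$mean, 1), 9.0)
  expect_equal(round(ds$sem, 1), 2.4)
  expect_identical(unname(ds$counts_below), c(4L, 6L))

  im <- reference_interspecific_means()
  ss <- im$mean_max[im$variable == "premaxillary_protrusion_length" &
                      im$species == "Sicyopterus stimpsoni"]
  lc <- im$mean_max[im$variable == "premaxillary_protrusion_length" &
                      im$species == "Lentipes concolor"]
  expect_equal(percent_excess(ss, lc), 29.1667, tolerance = 1e-4)
  expect_error(percent_excess(1, 0), class = "gk_usage_error")
})

test_that("comparison report assembles peak tests, angles and summaries", {
  study <- generate_study(
    list(f = list(params = quick_feeding(noise_sd = 0.005), n_cycles = 4,
                  n_individuals = 2, cv_individual = 0),
         c = list(params = quick_climbing(noise_sd = 0.005), n_cycles = 4,
                  n_individuals = 2, cv_individual = 0)),
    seed = 17)
  cp <- cycle_profiles(compute_all_variables(study$trials))
  gp <- group_profiles(cp)
  pk <- cycle_peaks(cp)
  rep <- comparison_report(
    pk, gp,
    excess = list(list(variable = "premaxillary_protrusion_length",
                       a = "climbing", b = "feeding")))
  expect_setequal(unique(rep$peak_table$variable), kin_variables())
  expect_equal(nrow(rep$divergence_table), 8)
  expect_true(all(rep$peak_table$p_value >= 0 & rep$peak_table$p_value <= 1))
  expect_equal(rep$summary_table$n_variables, 8)
  exp_excess <- 100 * (0.035 - 0.031) / 0.031
  expect_equal(rep$excess_table$excess_pct, exp_excess, tolerance = 0.5)

  # a variable present in only one group is excluded with a warning
  pk_drop <- pk[!(pk$group == "feeding" & pk$variable == "oral_sucker_area"), ]
  expect_warning(rep2 <- comparison_report(pk_drop, gp),
                 class = "gk_grouping_warning")
  expect_equal(rep2$summary_table$n_variables, 7)
})

test_that("raw and smoothed peaks agree closely for clean cycles", {
  gt <- generate_trial(quick_feeding(seed = 23))
  kin <- compute_all_variables(gt$trial)
  cp <- cycle_profiles(kin)
  ps <- cycle_peaks(cp)
  pr <- raw_cycle_peaks(kin)
  m <- merge(ps, pr, by = c("trial_id", "variable"))
  expect_equal(m$peak.x, m$peak.y, tolerance = 1e-3)
})
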