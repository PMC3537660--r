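test_that("synthetic trials round-trip through the CSV dialect", {
  study <- generate_study(
    list(f = list(params = quick_feeding(noise_sd = 0.01), n_cycles = 2,
                  n_individuals = 1),
         c = list(params = quick_climbing(noise_sd = 0.01), n_cycles = 2,
                  n_individuals = 1)),
    seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(study$trials, path)
  back <- read_landmark_table(path)
  expect_length(back, 4)
  for (id in names(study$trials)) {
    a <- study$trials[[id]]; b <- back[[id]]
    expect_equal(b$points$x, a$points$x, tolerance = 1e-10)
    expect_equal(b$points$y, a$points$y, tolerance = 1e-10)
    expect_identical(b$behavior, a$behavior)
    expect_equal(b$body_length, a$body_length)
    expect_equal(b$frame_rate, a$frame_rate)
  }
  # read -> write -> read is idempotent
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("per-view calibration scales coordinates on read", {
  gt <- generate_trial(quick_feeding(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(gt$trial, path)
  scaled <- read_landmark_table(path, calibration = c(ventral = 2, lateral = 0.5))
  p0 <- gt$trial$points
  p1 <- scaled[[1]]$points
  expect_equal(p1$x[p1$view == "ventral"], 2 * p0$x[p0$view == "ventral"])
  expect_equal(p1$y[p1$view == "lateral"], 0.5 * p0$y[p0$view == "lateral"])
})

test_that("files violating the column contract are rejected with named errors", {
  gt <- generate_trial(quick_feeding(seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(gt$trial, path)
  df <- read.csv(path)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "landmark_id")], bad, row.names = FALSE)
  expect_error(read_landmark_table(bad), "landmark_id", class = "gk_format_error")

  write.csv(rbind(df, df[1, ]), bad, row.names = FALSE)
  expect_error(read_landmark_table(bad), "duplicate", class = "gk_data_error")

  df2 <- df
  df2$time_s[df2$frame_index == 1] <- -1
  write.csv(df2, bad, row.names = FALSE)
  expect_error(read_landmark_table(bad), class = "gk_data_error")

  df3 <- df
  df3$body_length_cm <- 500
  write.csv(df3, bad, row.names = FALSE)
  expect_error(read_landmark_table(bad), "plausibility", class = "gk_data_error")

  df4 <- df
  df4$landmark_id[df4$view == "ventral"][1] <- 20
  write.csv(df4, bad, row.names = FALSE)
  expect_error(read_landmark_table(bad), class = "gk_data_error")
})

test_that("interior gaps are filled linearly; long or boundary gaps error", {
  gt <- generate_trial(quick_feeding(seed = 6))
  tr <- gt$trial
  mark_missing <- function(tr, id, frames) {
    sel <- tr$points$landmark_id == id & tr$points$frame_index %in% frames
    tr$points$missing[sel] <- 1
    tr$points$x[sel] <- NA
    tr$points$y[sel] <- NA
    tr
  }
  # single interior gap: filled with the midpoint of the flanking frames
  p8 <- tr$points[tr$points$landmark_id == 8, ]
  tr1 <- mark_missing(tr, 8, 5)
  f1 <- interpolate_missing(tr1)
  got <- f1$points[f1$points$landmark_id == 8 & f1$points$frame_index == 5, ]
  expect_equal(got$y, mean(p8$y[p8$frame_index %in% c(4, 6)]), tolerance = 1e-12)
  expect_equal(got$missing, 0)
  expect_match(qc_log(f1), "landmark=8", all = FALSE)

  # constant trajectory: fill equals the constant
  tr2 <- mark_missing(tr, 9, 10)
  f2 <- interpolate_missing(tr2)
  got2 <- f2$points[f2$points$landmark_id == 9 & f2$points$frame_index == 10, ]
  expect_equal(got2$y, tr$points$y[tr$points$landmark_id == 9][1],
               tolerance = 1e-12)

  # 4-frame gap with max_gap = 3 is unrecoverable
  tr3 <- mark_missing(tr, 8, 5:8)
  expect_error(interpolate_missing(tr3, max_gap = 3), "gap",
               class = "gk_gap_error")
  expect_silent(invisible(interpolate_missing(tr3, max_gap = 4)))

  # boundary gap is unrecoverable regardless of length
  tr4 <- mark_missing(tr, 8, 0)
  expect_error(interpolate_missing(tr4), class = "gk_gap_error")
})

test_that("registration is invariant under rigid translation of the raw data", {
  gt <- generate_trial(quick_feeding(seed = 8))
  kin0 <- compute_all_variables(gt$trial)
  for (shift in list(c(1.5, -2), c(100, 3))) {
    tr <- gt$trial
    tr$points$x <- tr$points$x + shift[1]
    tr$points$y <- tr$points$y + shift[2]
    kin <- compute_all_variables(tr)
    expect_equal(kin$value, kin0$value, tolerance = 1e-9)
  }
})

test_that("registration removes whole-body advance during climbing", {
  p0 <- quick_climbing(seed = 2)
  p1 <- quick_climbing(seed = 2, whole_body_advance = 2.0)
  k0 <- compute_all_variables(generate_trial(p0)$trial)
  k1 <- compute_all_variables(generate_trial(p1)$trial)
  expect_equal(k1$value, k0$value, tolerance = 1e-9)
  # protrusion peak is the generator amplitude, not amplitude + advance
  pk <- max(k1$value[k1$variable == "premaxillary_protrusion_length"])
  expect_equal(pk, p1$premax_length_amp, tolerance = 1e-6)
})

test_that("registration fails loudly when a reference landmark is missing", {
  gt <- generate_trial(quick_feeding(seed = 10))
  tr <- gt$trial
  sel <- tr$points$landmark_id == 12 & tr$points$frame_index == 3
  tr$points$missing[sel] <- 1
  expect_error(register_frames(tr), "12", class = "gk_registration_error")
})
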