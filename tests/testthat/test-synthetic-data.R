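walk_profile <- function() default_activity_profiles()[[1]]
fall_profile <- function(peak = 3.0, noise = 0.02)
  activity_profile(9L, "fall", is_fall = TRUE, impact_peak = peak,
                   impact_duration = 0.35, noise_std = noise,
                   gyro_peak = 5)

test_that("ADL trials have the right length and carry no fall labels", {
  rec <- generate_trial(walk_profile(), rate = 18, duration = 15, seed = 1)
  expect_equal(length(rec$time), 270)
  expect_true(all(rec$labels == 0))
  expect_equal(nrow(rec$acc), 270)
})

test_that("fall trials reach the configured impact peak within noise", {
  prof <- fall_profile(peak = 3.0, noise = 0.02)
  for (s in 1:100) {
    rec <- generate_trial(prof, rate = 18, duration = 15, seed = s)
    peak <- max(sqrt(rowSums(rec$acc^2)))
    expect_gte(peak, 3.0 - 3 * 0.02)
    expect_lte(peak, 3.0 + 3 * 0.02)
  }
})

test_that("fall trials label exactly one impact-plus-lying segment", {
  rec <- generate_trial(fall_profile(), rate = 50, duration = 15, seed = 3)
  lab <- rec$labels
  expect_gt(sum(lab), 0)
  runs <- rle(lab)
  expect_equal(sum(runs$values == 1), 1)     # one contiguous fall segment
  expect_equal(lab[length(lab)], 1L)         # lying through trial end
  # gravity present before the fall, rotated after it
  pre <- mean(sqrt(rowSums(rec$acc[1:50, ]^2)))
  post <- mean(sqrt(rowSums(rec$acc[(length(lab) - 49):length(lab), ]^2)))
  expect_equal(pre, 1, tolerance = 0.3)
  expect_equal(post, 1, tolerance = 0.3)
})

test_that("the same seed reproduces a trial exactly", {
  a <- generate_trial(fall_profile(), 20, 15, seed = 11)
  b <- generate_trial(fall_profile(), 20, 15, seed = 11)
  expect_identical(a$acc, b$acc)
  expect_identical(a$gyr, b$gyr)
  expect_identical(a$labels, b$labels)
})

test_that("invalid duration or rate is rejected", {
  expect_error(generate_trial(walk_profile(), 0, 15), "positive")
  expect_error(generate_trial(walk_profile(), 18, -1), "positive")
  expect_error(activity_profile(1, "bad", is_fall = TRUE, impact_peak = 0.5),
               "exceed")
})

test_that("generate_dataset writes one file per trial plus a manifest", {
  acts <- list(walk_profile(), fall_profile())
  src <- list(dataset_name = "Mini", sample_rate = 18, acc_units = "g",
              gyr_units = "rad/s", n_subjects = 2, activities = acts,
              trials_per_activity = 3, trial_duration = 15)
  cfg <- generator_config(list(src), seed = 5)
  dir <- withr::local_tempdir()
  man <- suppressWarnings(generate_dataset(cfg, dir))
  expect_equal(nrow(man), 12)
  expect_true(all(file.exists(file.path(dir, man$path))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # a sample labeled 1 occurs only in fall-activity trials
  for (i in seq_len(nrow(man))) {
    rec <- read_trial_csv(file.path(dir, man$path[i]))
    if (!man$is_fall_activity[i]) expect_true(all(rec$labels == 0))
  }
})

test_that("identical config and seed give byte-identical manifests", {
  cfg <- generator_config(tiny_sources(n_subjects = 2), seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressWarnings(generate_dataset(cfg, d1))
  suppressWarnings(generate_dataset(cfg, d2))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  f <- read.csv(file.path(d1, "manifest.csv"))$path[5]
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("sources declared in m/s2 store ~9.81 resting magnitude on disk", {
  man <- tiny_manifest()
  row <- man[man$acc_units == "m/s2" & !man$is_fall_activity, ][1, ]
  df <- read.csv(file.path(attr(man, "out_dir"), row$path))
  med <- median(sqrt(df$acc_x^2 + df$acc_y^2 + df$acc_z^2))
  expect_equal(med, 9.81, tolerance = 0.15 * 9.81)
  # and round-trips to ~1 g through the unit converter
  expect_equal(median(convert_units(sqrt(df$acc_x^2 + df$acc_y^2 +
                                           df$acc_z^2),
                                    "acceleration", "m/s2")),
               1, tolerance = 0.15)
})

test_that("raising impact_peak widens the fall-vs-ADL max-magnitude gap", {
  gap <- function(peak) {
    prof <- fall_profile(peak = peak)
    falls <- sapply(1:20, function(s)
      max(sqrt(rowSums(generate_trial(prof, 18, 15, seed = s)$acc^2))))
    adls <- sapply(1:20, function(s)
      max(sqrt(rowSums(generate_trial(walk_profile(), 18, 15,
                                      seed = s)$acc^2))))
    mean(falls) - mean(adls)
  }
  gaps <- sapply(c(1.8, 2.6, 3.4), gap)
  expect_true(all(diff(gaps) > 0))
})

test_that("the default corpus keeps fall-window prevalence in the band", {
  man <- tiny_manifest()
  prev <- attr(man, "fall_window_prevalence")
  expect_gte(prev, 0.02)
  expect_lte(prev, 0.10)
})
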