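test_that("filenames parse and round-trip per the naming convention", {
  p <- parse_filename("UMA_Subject03_Activity14_Trial02")
  expect_equal(p, list(dataset = "UMA", subject = 3L, activity = 14L,
                       trial = 2L))
  expect_equal(parse_filename("UMA_Subject03_Activity14_Trial02.csv"), p)
  for (x in c("Weda_Subject01_Activity07_Trial03",
              "UP_Subject99_Activity11_Trial12")) {
    q <- parse_filename(x)
    expect_equal(format_filename(q$dataset, q$subject, q$activity, q$trial),
                 x)
  }
  expect_error(parse_filename("UMA_Subj3_Act14"), "token")
  expect_error(parse_filename("UMA_Subject3_Activity14_Trial02"), "Subject")
  expect_error(format_filename("UMA_Fall", 1, 1, 1), "_")
})

test_that("unit conversion matches the definitions and round-trips", {
  expect_equal(convert_units(9.80665, "acceleration", "m/s2"), 1.0)
  expect_equal(convert_units(180, "angular_velocity", "deg/s"), pi)
  expect_equal(convert_units(0.5, "acceleration", "g"), 0.5)
  expect_error(convert_units(1, "acceleration", "furlong"), "unknown")
  x <- runif(50, -10, 10)
  back <- convert_units(x, "angular_velocity", "deg/s") * 180 / pi
  expect_true(all(abs(back - x) <= 1e-12 * pmax(abs(x), 1)))
  back2 <- convert_units(x, "acceleration", "m/s2") * 9.80665
  expect_true(all(abs(back2 - x) <= 1e-12 * pmax(abs(x), 1)))
})

mk_rec <- function(rate, n, f = function(t) cbind(sin(t), cos(t), 1 + 0 * t)) {
  t <- (0:(n - 1)) / rate
  imu_recording("T", 1, 1, 1, rate, t, f(t), f(t) * 0.1,
                as.integer(t > t[n] / 2))
}

test_that("resampling hits the stated grid and preserves duration", {
  rec <- mk_rec(50, 501)   # exactly 10 s span
  out <- resample_recording(rec, 18)
  expect_equal(length(out$time), 181)
  expect_equal(out$sample_rate, 18)
  expect_lte(diff(range(rec$time)) - diff(range(out$time)), 1 / 18)
  # identity when rates match
  rec18 <- mk_rec(18, 270)
  expect_identical(resample_recording(rec18, 18), rec18)
  expect_error(resample_recording(rec, -1), "positive")
})

test_that("linear interpolation is exact on affine signals", {
  aff <- function(t) cbind(2 + 3 * t, -1 + 0.5 * t, 7 + 0 * t)
  rec <- mk_rec(20, 300, aff)
  out <- resample_recording(rec, 18)
  expect_equal(out$acc, aff(out$time), ignore_attr = TRUE,
               tolerance = 1e-12)
  # constant channels stay constant
  expect_true(all(abs(out$acc[, 3] - 7) < 1e-12))
})

test_that("labels transfer from the nearest original sample", {
  rec <- mk_rec(50, 501)
  out <- resample_recording(rec, 18)
  expect_true(all(out$labels %in% c(0L, 1L)))
  # label boundary moves by at most one source sample period
  t_switch_in <- rec$time[min(which(rec$labels == 1))]
  t_switch_out <- out$time[min(which(out$labels == 1))]
  expect_lte(abs(t_switch_in - t_switch_out), 1 / 18 + 1 / 50)
})

test_that("files containing any non-finite value are dropped whole", {
  dir <- withr::local_tempdir()
  man <- data.frame(dataset = "T", subject = 1:3, activity = 1, trial = 1,
                    path = sprintf("T_Subject%02d_Activity01_Trial01.csv",
                                   1:3),
                    sample_rate_hz = 18, acc_units = "g",
                    gyr_units = "rad/s", is_fall_activity = FALSE)
  base <- data.frame(time_s = (0:9) / 18, acc_x = 1, acc_y = 0, acc_z = 0,
                     gyr_x = 0, gyr_y = 0, gyr_z = 0, label = 0)
  ok <- base
  bad_sensor <- base; bad_sensor$acc_y[4] <- NA
  bad_label <- base; bad_label$label[2] <- NaN
  write.csv(ok, file.path(dir, man$path[1]), row.names = FALSE)
  write.csv(bad_sensor, file.path(dir, man$path[2]), row.names = FALSE)
  write.csv(bad_label, file.path(dir, man$path[3]), row.names = FALSE)
  out <- suppressMessages(drop_invalid(man, dir))
  expect_equal(out$subject, 1L)          # NaN in any column drops the file
  out2 <- suppressMessages(drop_invalid(man[1, ], dir))
  expect_equal(nrow(out2), 1)            # clean manifest unchanged
  man_missing <- man[1, ]; man_missing$path <- "T_Subject09_Activity01_Trial01.csv"
  expect_warning(res <- drop_invalid(man_missing, dir), "missing")
  expect_equal(nrow(res), 0)
})

test_that("per-dataset normalization maps channel extremes to [-1, 1]", {
  t <- (0:99) / 18
  recs <- list(
    imu_recording("A", 1, 1, 1, 18, t, cbind(seq(-2, 2, length.out = 100),
                                             rnorm(100), rep(5, 100)),
                  matrix(rnorm(300), 100), integer(100)),
    imu_recording("A", 2, 1, 1, 18, t, matrix(rnorm(300), 100),
                  matrix(rnorm(300), 100), integer(100)))
  out <- normalize_dataset(recs, "per_dataset")
  all_acc <- do.call(rbind, lapply(out$recordings, `[[`, "acc"))
  for (j in 1:2) {
    expect_equal(min(all_acc[, j]), -1)
    expect_equal(max(all_acc[, j]), 1)
  }
  # affine endpoint check against the pooled fitted min/max
  raw1 <- c(recs[[1]]$acc[, 1], recs[[2]]$acc[, 1])
  lo <- min(raw1); hi <- max(raw1)
  expect_equal(unname(out$recordings[[1]]$acc[50, 1]),
               unname(2 * (recs[[1]]$acc[50, 1] - lo) / (hi - lo) - 1))
  expect_equal(min(all_acc[, 1]), -1)
  expect_equal(max(all_acc[, 1]), 1)
  # constant channel (dataset-wide) maps to 0
  solo <- normalize_dataset(recs[1], "per_dataset")
  expect_true(all(solo$recordings[[1]]$acc[, 3] == 0))
  expect_error(normalize_dataset(list(), "per_dataset"), "no recordings")
})

test_that("normalization is idempotent under refitted parameters", {
  recs <- tiny_corpus()[1:6]
  once <- normalize_dataset(recs, "per_dataset")
  twice <- normalize_dataset(once$recordings, "per_dataset")
  for (i in seq_along(recs)) {
    expect_lte(max(abs(twice$recordings[[i]]$acc - once$recordings[[i]]$acc)),
               1e-12)
    expect_lte(max(abs(twice$recordings[[i]]$gyr - once$recordings[[i]]$gyr)),
               1e-12)
  }
})

test_that("fit_on_train reuses training parameters on held-out recordings", {
  recs <- tiny_corpus()[1:8]
  out <- normalize_dataset(recs, "fit_on_train", train_idx = 1:4)
  expect_true(is.matrix(out$params))
  tr_acc <- do.call(rbind, lapply(out$recordings[1:4], `[[`, "acc"))
  expect_equal(unname(apply(tr_acc, 2, min)), rep(-1, 3))
  # held-out values may exceed [-1, 1]: parameters were not fitted on them
  te_acc <- do.call(rbind, lapply(out$recordings[5:8], `[[`, "acc"))
  expect_true(all(is.finite(te_acc)))
})

test_that("harmonize_corpus unifies rates and units across sources", {
  corpus <- tiny_corpus()
  expect_true(all(vapply(corpus, function(r) r$sample_rate, numeric(1)) ==
                    18))
  # resting acceleration magnitude ~1 g in every source, incl. the m/s2 one
  for (ds in c("TinyA", "TinyB", "TinyC")) {
    rec <- corpus[[min(which(vapply(corpus, function(r)
      r$dataset == ds && r$activity == 1, logical(1))))]]
    expect_equal(median(sqrt(rowSums(rec$acc^2))), 1, tolerance = 0.2)
  }
})
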