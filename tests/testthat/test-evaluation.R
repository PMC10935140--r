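test_that("grouped k-fold partitions subjects and is subject-disjoint", {
  set.seed(1)
  for (rep in 1:20) {
    n_subj <- sample(5:30, 1)
    k <- sample(2:min(10, n_subj), 1)
    keys <- sample(sprintf("s%02d", 1:n_subj), 200, replace = TRUE)
    folds <- subject_group_kfold(keys, k, seed = rep)
    a <- folds$assignment
    expect_setequal(a$subject, unique(keys))
    expect_equal(anyDuplicated(a$subject), 0)
    expect_true(all(a$fold %in% 1:k))
    expect_equal(sort(unique(a$fold)), 1:k)
    # round-robin balance: fold sizes differ by at most one subject
    sizes <- table(a$fold)
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_equal(nrow(subject_group_kfold(sprintf("s%d", 1:10),
                                        10)$assignment), 10)
  expect_error(subject_group_kfold(c("a", "b"), 5), "smaller k")
})

test_that("confusion metrics evaluate their formulas", {
  y <- c(rep(1, 100), rep(0, 1000))
  p <- c(rep(1, 90), rep(0, 10), rep(1, 30), rep(0, 970))
  m <- confusion_metrics(y, p)
  expect_equal(unname(m["recall"]), 0.90)
  expect_equal(unname(m["specificity"]), 0.97)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["f1"]), 2 * 0.75 * 0.9 / (0.75 + 0.9))
  perfect <- confusion_metrics(c(0, 1, 1), c(0, 1, 1))
  expect_true(all(perfect == 1))
  w <- capture_warnings(m2 <- confusion_metrics(c(0, 1, 1), c(0, 0, 0)))
  expect_true(any(grepl("undefined", w)))
  expect_equal(unname(m2["recall"]), 0)
  expect_equal(unname(m2["specificity"]), 1)
  expect_equal(unname(m2["precision"]), 0)
  expect_error(confusion_metrics(c(0, 1), c(0)), "length")
})

test_that("AUC counts concordant pairs with ties at half credit", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "both classes")
  # invariance under strictly increasing transforms
  set.seed(2)
  y <- rbinom(60, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(60)
  expect_equal(roc_auc(y, s), roc_auc(y, exp(s)))
  expect_equal(roc_auc(y, s), roc_auc(y, 10 * s + 3))
})

test_that("maxSeSp matches the exhaustive threshold sweep", {
  expect_equal(max_sesp(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3)), 0.5)
  expect_equal(max_sesp(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1.0)
  expect_equal(max_sesp(c(0, 1, 0, 1), rep(0.5, 4)), 0.0)
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.4); y[1:2] <- c(0, 1)
    s <- round(rnorm(n), sample(0:2, 1))  # force some ties
    expect_equal(max_sesp(y, s), oracle_max_sesp(y, s))
    expect_equal(roc_auc(y, s), oracle_auc(y, s))
  }
})

test_that("maxSeSp is 1 exactly when scores separate the classes", {
  set.seed(4)
  y <- c(rep(0, 20), rep(1, 8))
  sep <- c(runif(20, 0, 0.4), runif(8, 0.6, 1))
  expect_equal(max_sesp(y, sep), 1.0)
  mixed <- sep
  mixed[1] <- 0.9   # one ADL window outscores every fall
  expect_lt(max_sesp(y, mixed), 1.0)
})

test_that("within-dataset CV reports k folds of finite aggregates", {
  rep1 <- run_within_dataset(tiny_corpus(), dataset = "TinyA", model = "svm",
                             k = 5, seed = 7, select = FALSE)
  expect_s3_class(rep1, "fd_eval")
  expect_equal(nrow(rep1$folds), 5)
  expect_true(all(is.finite(rep1$aggregate$mean)))
  expect_true(all(rep1$aggregate$mean >= 0 & rep1$aggregate$mean <= 1))
  expect_equal(eval_metric(rep1, "recall"), mean(rep1$folds$recall))
  # k larger than the subject count is auto-reduced with a warning
  expect_warning(rep2 <- run_within_dataset(tiny_corpus(), "TinyA",
                                            model = "threshold", k = 10,
                                            seed = 7, select = FALSE),
                 "reducing k")
  expect_equal(nrow(rep2$folds), 5)
})

test_that("fold metrics are invariant to subject enumeration order", {
  corpus <- tiny_corpus()
  dsets <- vapply(corpus, function(r) r$dataset, character(1))
  recsA <- corpus[dsets == "TinyA"]
  r1 <- run_within_dataset(recsA, model = "svm", k = 5, seed = 3,
                           select = FALSE)
  r2 <- run_within_dataset(rev(recsA), model = "svm", k = 5, seed = 3,
                           select = FALSE)
  expect_equal(r1$aggregate$mean, r2$aggregate$mean, tolerance = 1e-10)
})

test_that("combined experiments pool sources without subject leakage", {
  corpus <- tiny_corpus()
  rep <- run_combined(corpus, model = "svm", k = 5, seed = 9,
                      select = FALSE)
  feats <- tiny_features()
  expect_equal(rep$n_windows, nrow(feats))
  per_source <- table(feats$dataset)
  expect_equal(rep$n_windows, sum(per_source))  # conservation
  # partition property on the fold assignment
  a <- rep$fold_assignment$assignment
  keys <- paste(feats$dataset, feats$subject)
  expect_setequal(a$subject, unique(keys))
  fold_id <- fold_for(rep$fold_assignment, keys)
  for (f in 1:5)
    expect_length(intersect(keys[fold_id == f], keys[fold_id != f]), 0)
  # same seed, different normalization: identical fold assignments
  rep_n <- run_combined(corpus, model = "svm", k = 5, seed = 9,
                        normalization = "per_dataset", select = FALSE)
  expect_identical(rep$fold_assignment$assignment,
                   rep_n$fold_assignment$assignment)
})

test_that("cross-dataset training never sees held-out subjects", {
  corpus <- tiny_corpus()
  reps <- lapply(c("TinyA", "TinyB", "TinyC"), function(d)
    run_cross_dataset(corpus, d, model = "svm", seed = 5, select = FALSE))
  expect_length(reps, 3)
  for (r in reps) {
    expect_equal(nrow(r$folds), 1)
    expect_length(intersect(r$experiment$train_datasets,
                            r$experiment$test_datasets), 0)
  }
  expect_error(run_cross_dataset(corpus, "TinyA", c("TinyA", "TinyB")),
               "cannot also")
})

test_that("matched sources generalize; shifted fall dynamics degrade", {
  corpus <- tiny_corpus()
  within_rec <- eval_metric(
    run_within_dataset(corpus, "TinyA", model = "svm", k = 5, seed = 2,
                       select = FALSE), "recall")
  cross_rec <- eval_metric(
    run_cross_dataset(corpus, "TinyB", "TinyA", model = "svm", seed = 2,
                      select = FALSE), "recall")
  expect_lte(abs(within_rec - cross_rec), 0.1)

  # a target source with much weaker, barely-rotating falls
  weak <- default_activity_profiles()[c(1, 5)]
  weak <- c(weak, list(activity_profile(
    6L, "soft_fall", is_fall = TRUE, impact_peak = 1.4,
    impact_duration = 0.3, post_impact_orientation_change = 0.15,
    gyro_peak = 0.8, noise_std = 0.03)))
  cfgW <- generator_config(list(list(
    dataset_name = "ShiftT", sample_rate = 18, acc_units = "g",
    gyr_units = "rad/s", n_subjects = 5, activities = weak,
    trials_per_activity = 3, trial_duration = 15)), seed = 13)
  dirW <- withr::local_tempdir()
  manW <- suppressWarnings(generate_dataset(cfgW, dirW))
  shifted <- c(corpus, harmonize_corpus(manW))
  shift_rec <- eval_metric(
    run_cross_dataset(shifted, "TinyB", "ShiftT", model = "svm", seed = 2,
                      select = FALSE), "recall")
  expect_lt(shift_rec, cross_rec)
})

test_that("evaluation reports serialize to JSON", {
  rep <- run_within_dataset(tiny_corpus(), "TinyA", model = "threshold",
                            k = 3, seed = 1, select = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  rt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rt$n_windows, rep$n_windows)
  expect_equal(nrow(rt$folds), 3)
})
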