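#' Subject-disjoint k-fold assignment
#'
#' Shuffles the distinct subject keys with the seed and deals them
#' round-robin into k folds, so all of a subject's windows share one fold,
#' folds are pairwise disjoint, and they cover every subject. When labels
#' are supplied, the shuffle is retried (bounded) until every fold's test
#' split contains both classes, keeping the last attempt otherwise.
#'
#' @param subject_keys Per-row subject keys (e.g. `"dataset subject"`).
#' @param k Number of folds; must not exceed the number of distinct
#'   subjects.
#' @param seed Integer seed.
#' @param y Optional per-row binary labels for the both-classes retry.
#' @param max_retries Bound on reshuffles (default 20).
#' @return An object of class `fd_folds`: list with `k` and `assignment`
#'   (data frame subject -> fold).
#' @export
subject_group_kfold <- function(subject_keys, k, seed = 1, y = NULL,
                                max_retries = 20) {
  # sorted (locale-independent) so the assignment depends only on the set of
  # subjects, not the order rows happen to arrive in
  subjects <- sort(unique(as.character(subject_keys)), method = "radix")
  if (length(subjects) < k)
    stopf("only %d subjects for k = %d folds; use a smaller k",
          length(subjects), k)
  with_seed(seed, {
    assign_once <- function() {
      perm <- sample(subjects)
      stats::setNames(rep_len(seq_len(k), length(perm)), perm)
    }
    fold_map <- assign_once()
    if (!is.null(y)) {
      ok <- function(fm) {
        f <- unname(fm[as.character(subject_keys)])
        all(vapply(seq_len(k), function(i)
          length(unique(y[f == i])) == 2, logical(1)))
      }
      tries <- 0
      while (!ok(fold_map) && tries < max_retries) {
        fold_map <- assign_once()
        tries <- tries + 1
      }
    }
    structure(list(k = as.integer(k),
                   assignment = data.frame(subject = names(fold_map),
                                           fold = unname(fold_map),
                                           row.names = NULL)),
              class = "fd_folds")
  })
}

#' Map row keys to their fold
#'
#' @param folds An `fd_folds` assignment.
#' @param subject_keys Per-row subject keys.
#' @return Integer fold per row.
#' @export
fold_for <- function(folds, subject_keys) {
  m <- stats::setNames(folds$assignment$fold, folds$assignment$subject)
  unname(m[as.character(subject_keys)])
}

#' Confusion-matrix metrics
#'
#' Falls (label 1) are the positive class. Ratios with a zero denominator
#' return 0 with a warning.
#'
#' @param y_true,y_pred Equal-length binary vectors.
#' @return Named vector: recall, specificity, precision, f1, accuracy.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what))
      0
    } else num / den
  }
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  precision <- safe(tp, tp + fp, "precision")
  f1 <- if (precision + recall == 0) {
    warning("f1 undefined; returning 0")
    0
  } else 2 * precision * recall / (precision + recall)
  c(recall = recall, specificity = specificity, precision = precision,
    f1 = f1, accuracy = (tp + tn) / length(y_true))
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen fall outscores a randomly chosen
#' ADL window, ties counted one half (rank / Mann-Whitney formulation,
#' equivalent to trapezoidal ROC integration).
#'
#' @param y_true Binary labels with both classes present.
#' @param scores Continuous scores, larger = more fall-like.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(y_true, scores) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Best balanced operating point over thresholds
#'
#' Sweeps every decision threshold of the scores and returns the maximum
#' over thresholds of `min(sensitivity, specificity)` — the best operating
#' point at which neither class is sacrificed.
#'
#' @inheritParams roc_auc
#' @return maxSeSp in [0, 1].
#' @export
max_sesp <- function(y_true, scores) {
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes required for maxSeSp")
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]
  ss <- scores[ord]
  tps <- cumsum(ys == 1)
  fps <- cumsum(ys == 0)
  last <- which(c(diff(ss) != 0, TRUE))  # one operating point per threshold
  se <- tps[last] / n1
  sp <- 1 - fps[last] / n0
  max(c(0, pmin(se, sp)))  # 0 covers the all-negative operating point
}

# per-fold metric row; undefined entries become NA (excluded from means)
fold_metric_row <- function(y, pred, score) {
  tp <- sum(y == 1 & pred == 1); fn <- sum(y == 1 & pred == 0)
  tn <- sum(y == 0 & pred == 0); fp <- sum(y == 0 & pred == 1)
  two <- length(unique(y)) == 2
  c(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    f1 = if (tp + fn > 0 && tp + fp > 0 && 2 * tp + fp + fn > 0)
      2 * tp / (2 * tp + fp + fn) else NA_real_,
    accuracy = (tp + tn) / length(y),
    auc = if (two) roc_auc(y, score) else NA_real_,
    max_sesp = if (two) max_sesp(y, score) else NA_real_)
}

fit_and_score <- function(features, train, test, model, selected,
                          model_args, seed) {
  if (model == "threshold") {
    fit <- do.call(fd_fit, c(list(x = NULL, kind = "threshold", seed = seed),
                             model_args))
    score <- predict(fit, features$peak_acc_norm_g[test], type = "score")
    pred <- predict(fit, features$peak_acc_norm_g[test], type = "class")
  } else {
    w <- compute_class_weights(features$label[train])
    fit <- do.call(fd_fit, c(list(x = features[train, selected, drop = FALSE],
                                  y = features$label[train], kind = model,
                                  weights = w, seed = seed),
                             model_args))
    score <- predict(fit, features[test, selected, drop = FALSE],
                     type = "score")
    pred <- predict(fit, features[test, selected, drop = FALSE],
                    type = "class")
  }
  list(fit = fit, score = score, pred = pred)
}

cv_evaluate <- function(features, model, k, seed, selected, model_args,
                        experiment) {
  keys <- paste(features$dataset, features$subject)
  n_subj <- length(unique(keys))
  if (n_subj < k) {
    warning(sprintf("only %d subjects; reducing k from %d", n_subj, k))
    k <- n_subj
  }
  folds <- subject_group_kfold(keys, k, seed = seed, y = features$label)
  fold_id <- fold_for(folds, keys)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold_id == f
    fs <- fit_and_score(features, which(!te), which(te), model, selected,
                        model_args, seed)
    m <- fold_metric_row(features$label[te], fs$pred, fs$score)
    rows[[f]] <- data.frame(fold = f, n_test = sum(te),
                            n_test_fall = sum(features$label[te] == 1),
                            t(m))
  }
  fold_df <- do.call(rbind, rows)
  mnames <- c("recall", "specificity", "precision", "f1", "accuracy",
              "auc", "max_sesp")
  if (anyNA(fold_df[mnames]))
    warning("some folds had undefined metrics; excluded from aggregates")
  agg <- data.frame(
    metric = mnames,
    mean = vapply(mnames, function(m) mean(fold_df[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(mnames, function(m) stats::sd(fold_df[[m]], na.rm = TRUE),
                numeric(1)),
    n_folds_used = vapply(mnames, function(m) sum(!is.na(fold_df[[m]])),
                          integer(1)),
    row.names = NULL)
  structure(list(experiment = experiment, folds = fold_df, aggregate = agg,
                 fold_assignment = folds, n_windows = nrow(features)),
            class = "fd_eval")
}

#' @export
print.fd_eval <- function(x, digits = 4, ...) {
  e <- x$experiment
  cat(sprintf("<fd_eval> %s | model %s | normalization %s\n",
              e$design, e$model, e$normalization))
  cat(sprintf("  train: %s | test: %s | %d windows | %d features\n",
              paste(e$train_datasets, collapse = "+"),
              paste(e$test_datasets, collapse = "+"),
              x$n_windows, length(e$selected)))
  agg <- x$aggregate
  if (all(agg$n_folds_used <= 1)) {
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  %-12s %6.2f%%\n", agg$metric[i], 100 * agg$mean[i]))
  } else {
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  %-12s %6.2f +/- %5.2f %%  (%d folds)\n", agg$metric[i],
                  100 * agg$mean[i], 100 * agg$sd[i], agg$n_folds_used[i]))
  }
  invisible(x)
}

#' @export
summary.fd_eval <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics:\n")
  print(object$folds, digits = 3)
  invisible(object)
}

#' Pull one aggregated metric from an evaluation report
#'
#' @param report An `fd_eval`.
#' @param metric Metric name (e.g. `"recall"`, `"auc"`, `"max_sesp"`).
#' @return The across-fold mean.
#' @export
eval_metric <- function(report, metric) {
  agg <- report$aggregate
  if (!metric %in% agg$metric) stopf("unknown metric '%s'", metric)
  agg$mean[agg$metric == metric]
}

select_or_all <- function(features, select, select_args, seed) {
  feat_cols <- fd_feature_columns()
  if (inherits(select, "fd_selection")) return(select)
  if (isFALSE(select))
    return(structure(list(selected = feat_cols), class = "fd_selection"))
  do.call(fd_select, c(list(x = features[feat_cols], y = features$label,
                            groups = paste(features$dataset,
                                           features$subject),
                            seed = seed),
                       select_args))
}

#' Within-dataset cross-validated experiment
#'
#' Feature selection on the dataset, then subject-disjoint k-fold
#' cross-validation of one cost-sensitive model, aggregating each metric as
#' mean and standard deviation across folds.
#'
#' @param corpus List of harmonized [imu_recording()] objects.
#' @param dataset Dataset to evaluate (default: the corpus' only dataset).
#' @param model `"svm"`, `"ann"` or `"threshold"`.
#' @param normalization `"off"` or `"per_dataset"`.
#' @param k Folds (default 10; auto-reduced with a warning when the
#'   dataset has fewer subjects).
#' @param seed Integer seed (folds, selection, model).
#' @param spec A [window_spec()].
#' @param select `TRUE` (run [fd_select()]), `FALSE` (keep all 78), or an
#'   existing `fd_selection`.
#' @param select_args,model_args Extra arguments for [fd_select()] /
#'   [fd_fit()].
#' @return An `fd_eval` report.
#' @export
run_within_dataset <- function(corpus, dataset = NULL, model = "svm",
                               normalization = "off", k = 10, seed = 1,
                               spec = window_spec(rate = 18), select = TRUE,
                               select_args = list(), model_args = list()) {
  dsets <- vapply(corpus, function(r) r$dataset, character(1))
  dataset <- dataset %||% unique(dsets)
  if (length(dataset) != 1) stopf("specify one dataset (found: %s)",
                                  paste(unique(dsets), collapse = ", "))
  recs <- corpus[dsets == dataset]
  if (!length(recs)) stopf("no recordings for dataset '%s'", dataset)
  features <- featurize_corpus(recs, spec, normalization)
  sel <- select_or_all(features, select, select_args, seed)
  cv_evaluate(features, model, k, seed, sel$selected, model_args,
              experiment = list(design = "within-dataset",
                                train_datasets = dataset,
                                test_datasets = dataset,
                                normalization = normalization,
                                model = model, selected = sel$selected))
}

#' Combined-corpus cross-validated experiment
#'
#' Concatenates all sources with dataset-qualified subject keys, selects
#' features on the combined matrix, and runs subject-disjoint k-fold
#' cross-validation.
#'
#' @inheritParams run_within_dataset
#' @return An `fd_eval` report.
#' @export
run_combined <- function(corpus, model = "svm", normalization = "off",
                         k = 10, seed = 1, spec = window_spec(rate = 18),
                         select = TRUE, select_args = list(),
                         model_args = list()) {
  features <- featurize_corpus(corpus, spec, normalization)
  key <- with(features, paste(dataset, subject, activity, trial,
                              window_index))
  if (anyDuplicated(key))
    stopf("duplicate (dataset, subject, activity, trial, window) rows")
  sel <- select_or_all(features, select, select_args, seed)
  dsets <- unique(features$dataset)
  cv_evaluate(features, model, k, seed, sel$selected, model_args,
              experiment = list(design = "combined",
                                train_datasets = dsets,
                                test_datasets = dsets,
                                normalization = normalization,
                                model = model, selected = sel$selected))
}

#' Cross-dataset generalization experiment
#'
#' Selects features and trains on one full dataset, then evaluates once on
#' the pooled held-out datasets (no cross-validation; train and test share
#' no subject by construction).
#'
#' @inheritParams run_within_dataset
#' @param train_dataset Source used for selection and training.
#' @param test_datasets Held-out sources (default: all others); must not
#'   include `train_dataset`.
#' @param normalization `"off"`, `"per_dataset"`, or `"fit_on_train"`
#'   (min-max parameters fitted on the training source only).
#' @return An `fd_eval` report with a single evaluation row.
#' @export
run_cross_dataset <- function(corpus, train_dataset, test_datasets = NULL,
                              model = "svm", normalization = "off",
                              seed = 1, spec = window_spec(rate = 18),
                              select = TRUE, select_args = list(),
                              model_args = list()) {
  dsets <- vapply(corpus, function(r) r$dataset, character(1))
  test_datasets <- test_datasets %||% setdiff(unique(dsets), train_dataset)
  if (train_dataset %in% test_datasets)
    stopf("train dataset cannot also be a test dataset")
  if (!length(test_datasets)) stopf("no held-out datasets")
  use <- dsets %in% c(train_dataset, test_datasets)
  recs <- corpus[use]
  train_idx <- which(vapply(recs, function(r) r$dataset, character(1)) ==
                       train_dataset)
  features <- featurize_corpus(recs, spec, normalization,
                               train_idx = train_idx)
  tr <- which(features$dataset == train_dataset)
  te <- which(features$dataset %in% test_datasets)
  sel <- select_or_all(features[tr, ], select, select_args, seed)
  fs <- fit_and_score(features, tr, te, model, sel$selected, model_args,
                      seed)
  m <- fold_metric_row(features$label[te], fs$pred, fs$score)
  fold_df <- data.frame(fold = 1L, n_test = length(te),
                        n_test_fall = sum(features$label[te] == 1), t(m))
  agg <- data.frame(metric = names(m), mean = unname(m), sd = NA_real_,
                    n_folds_used = as.integer(!is.na(m)), row.names = NULL)
  structure(list(experiment = list(design = "cross-dataset",
                                   train_datasets = train_dataset,
                                   test_datasets = test_datasets,
                                   normalization = normalization,
                                   model = model, selected = sel$selected),
                 folds = fold_df, aggregate = agg,
                 fold_assignment = NULL, n_windows = nrow(features),
                 model_fit = fs$fit),
            class = "fd_eval")
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `fd_eval`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  out <- list(experiment = report$experiment, folds = report$folds,
              aggregate = report$aggregate, n_windows = report$n_windows)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
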