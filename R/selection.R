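#' Rank features by random-forest Gini importance
#'
#' Fits a seeded random forest and returns mean-decrease-in-impurity (Gini)
#' importances normalized to sum to 1, sorted in decreasing order; ties are
#' broken by feature-name lexicographic order so the ranking is
#' deterministic.
#'
#' @param x Feature data frame or matrix (finite values only).
#' @param y Binary labels (both classes present).
#' @param n_trees Number of trees (default 200).
#' @param seed Integer seed.
#' @return A data frame with columns `feature` and `importance`.
#' @export
rank_gini_importance <- function(x, y, n_trees = 200, seed = 1) {
  x <- as.data.frame(x)
  if (length(unique(y)) < 2) stopf("y must contain both classes")
  if (!all(vapply(x, function(col) all(is.finite(col)), logical(1))))
    stopf("feature matrix contains non-finite values")
  fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        num.trees = n_trees, importance = "impurity",
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp),
                                                   length(imp))
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL)
}

cv_accuracy_rf <- function(x, y, groups, folds, n_trees, seed,
                           balanced = FALSE) {
  accs <- numeric(folds$k)
  fold_of <- fold_for(folds, groups)
  for (f in seq_len(folds$k)) {
    te <- fold_of == f
    fit <- ranger::ranger(x = x[!te, , drop = FALSE],
                          y = factor(y[!te], levels = c(0, 1)),
                          num.trees = n_trees, seed = seed, num.threads = 1)
    # seed the prediction too: ranger breaks classification vote ties at
    # random, which would make ablation deltas non-deterministic
    pred <- stats::predict(fit, x[te, , drop = FALSE], seed = seed,
                           num.threads = 1)$predictions
    yt <- y[te]
    if (balanced) {
      se <- if (any(yt == 1)) mean(pred[yt == 1] == "1") else NA
      sp <- if (any(yt == 0)) mean(pred[yt == 0] == "0") else NA
      accs[f] <- mean(c(se, sp), na.rm = TRUE)
    } else {
      accs[f] <- mean(pred == as.character(yt))
    }
  }
  mean(accs)
}

#' One-at-a-time feature-exclusion accuracy deltas
#'
#' For each candidate feature f, computes
#' `delta(f) = CV accuracy(all candidates) - CV accuracy(candidates \ f)`
#' under subject-disjoint cross-validation with a random-forest probe
#' model; positive deltas mark features whose removal costs accuracy.
#'
#' @param x Feature data frame.
#' @param y Binary labels.
#' @param groups Per-row subject keys used to build subject-disjoint folds.
#' @param candidate_features Non-empty character vector of columns of `x`.
#' @param cv_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @param n_trees Probe forest size (default 101, odd so binary votes
#'   cannot tie).
#' @param metric `"accuracy"` (default, mirrors plain-accuracy screening)
#'   or `"balanced_accuracy"`.
#' @return A data frame with columns `feature` and `accuracy_delta`, in
#'   candidate order; attribute `baseline_accuracy` carries the
#'   all-candidate CV accuracy.
#' @export
ablation_accuracy_deltas <- function(x, y, groups, candidate_features,
                                     cv_folds = 5, seed = 1, n_trees = 101,
                                     metric = c("accuracy",
                                                "balanced_accuracy")) {
  metric <- match.arg(metric)
  if (length(candidate_features) == 0) stopf("candidate set is empty")
  x <- as.data.frame(x)
  miss <- setdiff(candidate_features, names(x))
  if (length(miss)) stopf("unknown candidate features: %s",
                          paste(miss, collapse = ", "))
  folds <- subject_group_kfold(groups, k = cv_folds, seed = seed, y = y)
  bal <- metric == "balanced_accuracy"
  base <- cv_accuracy_rf(x[candidate_features], y, groups, folds, n_trees,
                         seed, bal)
  deltas <- vapply(candidate_features, function(f) {
    rest <- setdiff(candidate_features, f)
    if (!length(rest)) return(base - 0.5)
    base - cv_accuracy_rf(x[rest], y, groups, folds, n_trees, seed, bal)
  }, numeric(1))
  out <- data.frame(feature = candidate_features,
                    accuracy_delta = unname(deltas), row.names = NULL)
  attr(out, "baseline_accuracy") <- base
  out
}

parse_keep_rule <- function(rule) {
  if (grepl("^top_k=\\d+$", rule))
    list(kind = "top_k", k = as.integer(sub("^top_k=", "", rule)))
  else if (rule %in% c("above_mean", "positive", "all"))
    list(kind = rule)
  else stopf("unknown keep rule '%s'", rule)
}

#' Two-stage random-forest feature selection
#'
#' Stage 1 ranks all features by Gini importance and keeps those passing
#' `importance_keep_rule`; stage 2 measures each survivor's one-at-a-time
#' exclusion delta and keeps those passing `ablation_keep_rule`. The
#' selected set is returned in ranking order. If the rules eliminate
#' everything, the top-ranked feature is kept with a warning.
#'
#' @param x Feature data frame.
#' @param y Binary labels.
#' @param groups Per-row subject keys for the subject-disjoint ablation CV.
#' @param importance_keep_rule `"above_mean"` (default: importance above
#'   the mean importance), `"top_k=K"`, or `"all"`.
#' @param ablation_keep_rule `"positive"` (default: delta > 0),
#'   `"top_k=K"`, or `"all"`.
#' @param n_trees Stage-1 forest size (default 200).
#' @param cv_folds,ablation_trees Stage-2 CV folds and probe forest size.
#' @param seed Integer seed.
#' @param metric Ablation metric, see [ablation_accuracy_deltas()].
#' @return An object of class `fd_selection`: list with `gini_ranking`,
#'   `ablation`, `selected` and `params`.
#' @export
fd_select <- function(x, y, groups, importance_keep_rule = "above_mean",
                      ablation_keep_rule = "positive", n_trees = 200,
                      cv_folds = 5, ablation_trees = 101, seed = 1,
                      metric = "accuracy") {
  ranking <- rank_gini_importance(x, y, n_trees = n_trees, seed = seed)
  r1 <- parse_keep_rule(importance_keep_rule)
  cand <- switch(r1$kind,
    above_mean = ranking$feature[ranking$importance >
                                   mean(ranking$importance)],
    top_k = utils::head(ranking$feature, r1$k),
    all = ranking$feature)
  if (!length(cand)) cand <- ranking$feature[1]

  ablation <- ablation_accuracy_deltas(x, y, groups, cand,
                                       cv_folds = cv_folds, seed = seed,
                                       n_trees = ablation_trees,
                                       metric = metric)
  r2 <- parse_keep_rule(ablation_keep_rule)
  keep <- switch(r2$kind,
    positive = ablation$feature[ablation$accuracy_delta > 0],
    top_k = ablation$feature[order(-ablation$accuracy_delta)][
      seq_len(min(r2$k, nrow(ablation)))],
    all = ablation$feature)
  selected <- ranking$feature[ranking$feature %in% keep]
  if (!length(selected)) {
    warning("keep rules eliminated every feature; falling back to the ",
            "top-ranked one")
    selected <- ranking$feature[1]
  }
  structure(list(gini_ranking = ranking, ablation = ablation,
                 selected = selected,
                 params = list(n_trees = n_trees,
                               importance_keep_rule = importance_keep_rule,
                               ablation_keep_rule = ablation_keep_rule,
                               cv_folds = cv_folds, metric = metric,
                               seed = seed)),
            class = "fd_selection")
}

#' @export
print.fd_selection <- function(x, ...) {
  cat(sprintf("<fd_selection> %d of %d features selected\n",
              length(x$selected), nrow(x$gini_ranking)))
  cat("  rules:", x$params$importance_keep_rule, "->",
      x$params$ablation_keep_rule, "\n")
  top <- utils::head(x$selected, 10)
  cat("  top:", paste(top, collapse = ", "),
      if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}

#' Serialize / read a selection report
#'
#' Writes the report as JSON and the selected features as a plain-text
#' one-per-line list alongside it.
#'
#' @param sel An `fd_selection`.
#' @param path JSON output path; `<path>.features.txt` receives the list.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(unclass(sel), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(sel$selected, paste0(path, ".features.txt"))
  invisible(path)
}
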