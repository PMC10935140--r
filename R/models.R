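#' Inverse-class-frequency training weights
#'
#' Computes per-class weights for cost-sensitive training,
#' `w_c = n / (2 * n_c)`, the inverse class frequency normalized so a
#' balanced set yields weight 1 for both classes; the minority class always
#' receives the strictly larger weight and the weight ratio equals the
#' inverse count ratio exactly. `literal = TRUE` instead returns the
#' frequency itself, `w_c = n_c / n`, which up-weights the majority class
#' and is provided only for comparison.
#'
#' @param labels Binary labels with both classes present.
#' @param literal Use the literal class-frequency weighting.
#' @return An object of class `class_weights`: a named numeric vector with
#'   elements `"0"` and `"1"`.
#' @export
compute_class_weights <- function(labels, literal = FALSE) {
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0) stopf("both classes must be present")
  n <- n0 + n1
  w <- if (literal) c("0" = n0 / n, "1" = n1 / n)
       else c("0" = n / (2 * n0), "1" = n / (2 * n1))
  structure(w, class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("<class_weights> ADL (0): %.4g  fall (1): %.4g  (ratio %.4g)\n",
              x[["0"]], x[["1"]], x[["1"]] / x[["0"]]))
  invisible(x)
}

# single-hidden-layer network, tanh hidden / sigmoid output, full-batch
# gradient descent on the class-weighted mean squared error
# J = 1/(2n) sum_i w_i (yhat_i - y_i)^2
ann_train_core <- function(x, y, w_sample, hidden_units, epochs,
                           learning_rate, momentum, seed) {
  n <- nrow(x); p <- ncol(x); H <- hidden_units
  with_seed(seed, {
    W1 <- matrix(stats::runif(p * H, -0.7, 0.7) / sqrt(p), p, H)
    b1 <- numeric(H)
    W2 <- matrix(stats::runif(H, -0.7, 0.7) / sqrt(H), H, 1)
    b2 <- 0
    vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- 0
    loss <- numeric(epochs)
    for (e in seq_len(epochs)) {
      A <- tanh(sweep(x %*% W1, 2, b1, "+"))
      yhat <- stats::plogis(as.vector(A %*% W2) + b2)
      err <- yhat - y
      loss[e] <- sum(w_sample * err^2) / (2 * n)
      dz <- (w_sample * err / n) * yhat * (1 - yhat)      # dJ/dz_out
      gW2 <- crossprod(A, dz)
      gb2 <- sum(dz)
      dA <- (dz %*% t(W2)) * (1 - A^2)
      gW1 <- crossprod(x, dA)
      gb1 <- colSums(dA)
      vW1 <- momentum * vW1 - learning_rate * gW1
      vb1 <- momentum * vb1 - learning_rate * gb1
      vW2 <- momentum * vW2 - learning_rate * gW2
      vb2 <- momentum * vb2 - learning_rate * gb2
      W1 <- W1 + vW1; b1 <- b1 + vb1; W2 <- W2 + vW2; b2 <- b2 + vb2
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, loss = loss)
  })
}

ann_forward <- function(net, x) {
  A <- tanh(sweep(x %*% net$W1, 2, net$b1, "+"))
  stats::plogis(as.vector(A %*% net$W2) + net$b2)
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(x, s) {
  sweep(sweep(x, 2, s$center, "-"), 2, s$scale, "/")
}

#' Fit a fall-detection classifier
#'
#' The single fitting front door for the package's detectors. `"svm"` fits
#' a soft-margin support vector machine whose per-sample slack penalty is
#' scaled by the class weight of its label (the per-class cost
#' `C * w_{y(i)}`); `"ann"` fits a single-hidden-layer neural network
#' (tanh hidden layer, sigmoid output in [0, 1]) by full-batch gradient
#' descent on the class-weighted mean squared error; `"threshold"` is the
#' untrained acceleration-magnitude baseline that flags a window as a fall
#' when its peak acceleration norm reaches `threshold` g. Both learners
#' standardize inputs internally (parameters stored in the model) and are
#' deterministic given `(data, hyperparameters, seed)`.
#'
#' @param x Feature data frame or matrix. For `kind = "threshold"`, a
#'   single numeric vector of per-window peak acceleration norms in g.
#' @param y Binary labels (0 = ADL, 1 = fall); ignored by the baseline.
#' @param kind `"svm"`, `"ann"` or `"threshold"`.
#' @param weights A [compute_class_weights()] result; defaults to inverse
#'   class frequency computed from `y`. `NULL` semantics: pass
#'   `weights = "none"` for unweighted training.
#' @param cost SVM slack penalty C (> 0, default 1).
#' @param kernel SVM kernel, `"radial"` (default, with
#'   `gamma = 1 / (p * var)`) or `"linear"`.
#' @param gamma Optional RBF width override.
#' @param hidden_units,epochs,learning_rate,momentum ANN hyperparameters.
#' @param threshold Baseline threshold in g (>= 0, default 2.5).
#' @param seed Integer seed (ANN initialization).
#' @return An object of class `fd_model`. Continuous scores are the SVM
#'   decision value (oriented so positive means fall), the ANN sigmoid
#'   output, or the peak norm itself; hard labels threshold the score at
#'   0, 0.5 and `threshold` respectively.
#' @export
fd_fit <- function(x, y = NULL, kind = c("svm", "ann", "threshold"),
                   weights = NULL, cost = 1,
                   kernel = c("radial", "linear"), gamma = NULL,
                   hidden_units = 32, epochs = 400, learning_rate = 0.5,
                   momentum = 0.9, threshold = 2.5, seed = 1) {
  kind <- match.arg(kind)

  if (kind == "threshold") {
    if (threshold < 0) stopf("threshold must be >= 0")
    return(structure(list(kind = "threshold", fit = list(threshold = threshold),
                          feature_names = "peak_acc_norm_g",
                          weights = NULL, hyper = list(threshold = threshold),
                          seed = seed),
                     class = "fd_model"))
  }

  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stopf("features must be finite")
  if (length(unique(y)) < 2) stopf("y must contain both classes")
  unweighted <- identical(weights, "none")
  if (is.null(weights) || unweighted) {
    w <- if (unweighted) structure(c("0" = 1, "1" = 1),
                                   class = "class_weights")
         else compute_class_weights(y)
  } else w <- weights
  std <- standardize_fit(x)
  xs <- standardize_apply(x, std)

  if (kind == "svm") {
    kernel <- match.arg(kernel)
    if (cost <= 0) stopf("cost must be > 0")
    p <- ncol(xs)
    if (is.null(gamma)) {
      v <- stats::var(as.vector(xs))
      gamma <- if (is.finite(v) && v > 0) 1 / (p * v) else 1 / p
    }
    yf <- factor(y, levels = c(0, 1))
    fit <- e1071::svm(x = xs, y = yf,
                      class.weights = c("0" = unname(w[["0"]]),
                                        "1" = unname(w[["1"]])),
                      cost = cost, kernel = kernel, gamma = gamma,
                      scale = FALSE)
    # orient the margin so positive favors the fall class
    dv <- attr(stats::predict(fit, xs[1, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    flip <- if (colnames(dv)[1] == "0/1") -1 else 1
    hyper <- list(cost = cost, kernel = kernel, gamma = gamma)
    fitobj <- list(svm = fit, flip = flip)
  } else {
    if (hidden_units < 1) stopf("hidden_units must be >= 1")
    if (epochs < 1) stopf("epochs must be >= 1")
    w_sample <- unname(w[as.character(y)])
    w_sample <- w_sample / mean(w_sample)  # scale absorbed by learning rate
    net <- ann_train_core(xs, as.numeric(y), w_sample, hidden_units,
                          epochs, learning_rate, momentum, seed)
    hyper <- list(hidden_units = hidden_units, epochs = epochs,
                  learning_rate = learning_rate, momentum = momentum)
    fitobj <- net
  }

  structure(list(kind = kind, fit = fitobj,
                 feature_names = colnames(x), weights = w, hyper = hyper,
                 std = std, seed = seed,
                 loss_trace = if (kind == "ann") fitobj$loss),
            class = "fd_model")
}

#' Predict from a fitted fall-detection model
#'
#' @param object An `fd_model`.
#' @param newdata Feature matrix/data frame with the model's feature
#'   columns (a numeric vector of peak norms for the baseline).
#' @param type `"class"` for hard 0/1 labels or `"score"` for the
#'   continuous score (SVM margin, ANN sigmoid output, or peak norm).
#' @param ... Unused.
#' @return Numeric vector of labels or scores.
#' @export
predict.fd_model <- function(object, newdata, type = c("class", "score"),
                             ...) {
  type <- match.arg(type)
  if (object$kind == "threshold") {
    peaks <- if (is.data.frame(newdata)) newdata[["peak_acc_norm_g"]]
             else as.numeric(newdata)
    if (is.null(peaks)) stopf("newdata must carry peak_acc_norm_g")
    return(if (type == "score") peaks
           else as.integer(peaks >= object$fit$threshold))
  }
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) stopf("newdata missing features: %s",
                          paste(miss, collapse = ", "))
  xs <- standardize_apply(as.matrix(newdata[object$feature_names]),
                          object$std)
  if (object$kind == "svm") {
    pr <- stats::predict(object$fit$svm, xs, decision.values = TRUE)
    score <- object$fit$flip * as.numeric(attr(pr, "decision.values"))
    if (type == "score") score else as.integer(score > 0)
  } else {
    score <- ann_forward(object$fit, xs)
    if (type == "score") score else as.integer(score >= 0.5)
  }
}

#' @export
print.fd_model <- function(x, ...) {
  cat(sprintf("<fd_model:%s> %d features\n", x$kind,
              length(x$feature_names)))
  if (!is.null(x$weights))
    cat(sprintf("  class weights: ADL %.3g, fall %.3g\n",
                x$weights[["0"]], x$weights[["1"]]))
  hp <- paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")
  cat("  ", hp, "\n", sep = "")
  invisible(x)
}

#' @export
summary.fd_model <- function(object, ...) {
  print(object)
  if (object$kind == "ann" && !is.null(object$loss_trace)) {
    lt <- object$loss_trace
    cat(sprintf("  training loss: %.4g -> %.4g over %d epochs\n",
                lt[1], lt[length(lt)], length(lt)))
  }
  if (object$kind == "svm")
    cat(sprintf("  support vectors: %d\n", object$fit$svm$tot.nSV))
  invisible(object)
}

#' Acceleration-magnitude threshold baseline
#'
#' Labels a window as a fall when the maximum acceleration norm
#' `sqrt(ax^2 + ay^2 + az^2)` over the window reaches `threshold` g.
#' Windows must carry raw (unnormalized) acceleration.
#'
#' @param peak_norms Per-window peak acceleration norms in g (e.g. the
#'   `peak_acc_norm_g` column of a feature matrix).
#' @param threshold Threshold in g (>= 0, default 2.5).
#' @return Integer labels, 1 = fall.
#' @export
threshold_baseline <- function(peak_norms, threshold = 2.5) {
  if (threshold < 0) stopf("threshold must be >= 0")
  as.integer(as.numeric(peak_norms) >= threshold)
}
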