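# independent brute-force oracles used to cross-check the implementation;
# deliberately written from the definitions, not by calling package code

oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(xs[n])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

oracle_feature <- function(name, x) {
  n <- length(x)
  switch(name,
    max = max(x),
    min = min(x),
    zero_crossings = {
      cnt <- 0L
      for (i in seq_len(n - 1)) if (x[i] * x[i + 1] < 0) cnt <- cnt + 1L
      cnt
    },
    q3 = oracle_quantile(x, 0.75),
    std = sqrt(sum((x - sum(x) / n)^2) / n),
    mean = sum(x) / n,
    median = oracle_quantile(x, 0.5),
    skewness = e1071::skewness(x, type = 1),
    energy = sum(x^2) / n,
    rms = sqrt(sum(x^2) / n),
    q1 = oracle_quantile(x, 0.25),
    kurtosis = e1071::kurtosis(x, type = 1) + 3,
    autocorr = as.numeric(stats::acf(x, lag.max = 1, plot = FALSE,
                                     demean = TRUE)$acf[2]),
    stop("unknown feature"))
}

# exhaustive pairwise AUC: fraction of (positive, negative) pairs in which
# the positive outscores the negative, ties half credit
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# exhaustive threshold sweep for max over thresholds of min(Se, Sp)
oracle_max_sesp <- function(y, s) {
  best <- 0
  for (t in c(unique(s), Inf)) {
    pred <- as.integer(s >= t)
    se <- sum(pred == 1 & y == 1) / sum(y == 1)
    sp <- sum(pred == 0 & y == 0) / sum(y == 0)
    best <- max(best, min(se, sp))
  }
  best
}

# two-Gaussian-blob fixture for cost-sensitivity checks: overlapping
# classes with the stated imbalance
make_blobs <- function(n0, n1, sep = 1.5, seed = 1, p = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n0 * p, 0), n0, p),
             matrix(rnorm(n1 * p, sep), n1, p))
  y <- c(rep(0L, n0), rep(1L, n1))
  idx <- sample(length(y))
  list(x = as.data.frame(x[idx, ]), y = y[idx])
}
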