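#' Sliding-window specification
#'
#' Windows of `duration` seconds with fractional `overlap` at a given
#' sampling rate; `window_len = round(duration * rate)` samples and
#' `stride = round(window_len * (1 - overlap))` samples.
#'
#' @param duration Window duration in seconds (default 2).
#' @param overlap Fractional overlap in [0, 1) (default 0.5).
#' @param rate Sampling rate in Hz.
#' @return An object of class `window_spec` with fields `duration`,
#'   `overlap`, `rate`, `window_len`, `stride`.
#' @export
window_spec <- function(duration = 2, overlap = 0.5, rate = 18) {
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  window_len <- round(duration * rate)
  stride <- round(window_len * (1 - overlap))
  if (window_len < 1) stopf("window_len must be >= 1")
  if (stride < 1) stopf("stride must be >= 1")
  structure(list(duration = duration, overlap = overlap, rate = rate,
                 window_len = as.integer(window_len),
                 stride = as.integer(stride)),
            class = "window_spec")
}

#' Enumerate sliding-window index ranges
#'
#' Windows start at multiples of the stride; a trailing partial window is
#' discarded. With `n_samples >= window_len` the count is
#' `floor((n_samples - window_len) / stride) + 1`, otherwise 0.
#'
#' @param n_samples Stream length in samples (>= 0).
#' @param spec A [window_spec()].
#' @return A two-column integer matrix of 1-based inclusive (start, end)
#'   pairs, zero rows when the stream is shorter than one window.
#' @export
segment_windows <- function(n_samples, spec) {
  if (n_samples < 0) stopf("n_samples must be >= 0")
  wl <- spec$window_len; st <- spec$stride
  if (n_samples < wl)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  k <- (n_samples - wl) %/% st + 1L
  start <- (seq_len(k) - 1L) * st + 1L
  cbind(start = start, end = start + wl - 1L)
}

#' Majority label of a window
#'
#' Returns the modal per-sample label; an exact tie resolves to 1 (fall),
#' prioritizing sensitivity.
#'
#' @param labels Non-empty vector over \{0, 1\}.
#' @return 0 or 1.
#' @export
majority_label <- function(labels) {
  if (length(labels) == 0) stopf("empty window has no majority label")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0 or 1")
  as.integer(2 * sum(labels) >= length(labels))
}

#' Compute one window statistic
#'
#' The 13 statistics computed on every channel window. Fixed definitions:
#' `zero_crossings` counts strict sign changes of the raw signal;
#' `std` is the population standard deviation; `q1`/`q3` are
#' linear-interpolation quartiles; `skewness` is m3 / m2^(3/2) and
#' `kurtosis` m4 / m2^2 (non-excess), both 0 for zero-variance windows;
#' `energy` is the mean of squared values (mean signal power, so
#' `rms^2 == energy`); `autocorr` is the lag-1 sample autocorrelation
#' coefficient, 0 for zero-variance windows.
#'
#' @param name One of max, min, zero_crossings, q3, std, mean, median,
#'   skewness, energy, rms, q1, kurtosis, autocorr.
#' @param x Numeric window (>= 2 samples for dispersion/shape features).
#' @return A scalar.
#' @export
compute_feature <- function(name, x) {
  n <- length(x)
  mx <- mean(x)
  cx <- x - mx
  m2 <- mean(cx^2)
  switch(name,
    max = max(x),
    min = min(x),
    zero_crossings = sum(x[-n] * x[-1] < 0),
    q3 = unname(stats::quantile(x, 0.75, type = 7)),
    std = sqrt(m2),
    mean = mx,
    median = stats::median(x),
    skewness = if (m2 > 0) mean(cx^3) / m2^1.5 else 0,
    energy = mean(x^2),
    rms = sqrt(mean(x^2)),
    q1 = unname(stats::quantile(x, 0.25, type = 7)),
    kurtosis = if (m2 > 0) mean(cx^4) / m2^2 else 0,
    autocorr = if (m2 > 0) sum(cx[-n] * cx[-1]) / (n * m2) else 0,
    stopf("unknown feature '%s'", name))
}

# all 13 features for every column of a window matrix (samples x windows),
# vectorized across windows; same definitions as compute_feature
channel_features <- function(W) {
  n <- nrow(W); k <- ncol(W)
  mx <- colMeans(W)
  C <- W - rep(mx, each = n)
  m2 <- colMeans(C^2)
  m3 <- colMeans(C^3)
  m4 <- colMeans(C^4)
  pos <- m2 > 0
  msq <- colMeans(W^2)
  out <- matrix(0, k, 13, dimnames = list(NULL, fd_feature_names()))
  out[, "max"] <- apply(W, 2, max)
  out[, "min"] <- apply(W, 2, min)
  out[, "zero_crossings"] <- colSums(W[-n, , drop = FALSE] *
                                       W[-1, , drop = FALSE] < 0)
  out[, "q3"] <- apply(W, 2, stats::quantile, probs = 0.75, type = 7)
  out[, "std"] <- sqrt(m2)
  out[, "mean"] <- mx
  out[, "median"] <- apply(W, 2, stats::median)
  out[pos, "skewness"] <- m3[pos] / m2[pos]^1.5
  out[, "energy"] <- msq
  out[, "rms"] <- sqrt(msq)
  out[, "q1"] <- apply(W, 2, stats::quantile, probs = 0.25, type = 7)
  out[pos, "kurtosis"] <- m4[pos] / m2[pos]^2
  out[pos, "autocorr"] <- (colSums(C[-n, pos, drop = FALSE] *
                                     C[-1, pos, drop = FALSE]) /
                             (n * m2[pos]))
  out
}

#' Extract the windowed feature matrix of one recording
#'
#' Segments the recording with `spec`, assigns each window its majority
#' label, and computes the 13 statistics on each of the 6 channels — 78
#' feature columns named `<channel>__<feature>` — plus metadata columns
#' (`dataset`, `subject`, `activity`, `trial`, `window_index`, `label`) and
#' `peak_acc_norm_g`, the window's maximum acceleration norm, used by the
#' magnitude-threshold baseline (meaningful only when the recording is in
#' raw g, i.e. before normalization).
#'
#' @param rec An [imu_recording()].
#' @param spec A [window_spec()]; defaults to 2 s / 50 % at the recording's
#'   rate.
#' @return A data frame with one row per window (zero rows when the
#'   recording is shorter than one window).
#' @export
extract_features <- function(rec, spec = window_spec(rate = rec$sample_rate)) {
  win <- segment_windows(n_samples(rec), spec)
  k <- nrow(win)
  feat_cols <- fd_feature_columns()
  if (k == 0) {
    empty <- as.data.frame(matrix(numeric(0), 0, 7 + 78))
    names(empty) <- c("dataset", "subject", "activity", "trial",
                      "window_index", "label", "peak_acc_norm_g", feat_cols)
    return(empty)
  }
  idx <- sapply(seq_len(k), function(i) win[i, 1]:win[i, 2])  # wl x k
  chans <- cbind(rec$acc, rec$gyr)
  feats <- matrix(NA_real_, k, 78, dimnames = list(NULL, feat_cols))
  for (c_i in 1:6) {
    W <- matrix(chans[idx, c_i], nrow = spec$window_len)
    feats[, ((c_i - 1) * 13 + 1):(c_i * 13)] <- channel_features(W)
  }
  norm2 <- sqrt(rowSums(rec$acc^2))
  peak <- apply(matrix(norm2[idx], nrow = spec$window_len), 2, max)
  lab <- apply(matrix(rec$labels[idx], nrow = spec$window_len), 2,
               majority_label)
  cbind(data.frame(dataset = rec$dataset, subject = rec$subject,
                   activity = rec$activity, trial = rec$trial,
                   window_index = seq_len(k), label = lab,
                   peak_acc_norm_g = peak),
        as.data.frame(feats))
}

#' Featurize a harmonized corpus
#'
#' Applies the requested normalization, then extracts the windowed feature
#' matrix of every recording and row-binds them. The
#' `peak_acc_norm_g` column is always computed from the raw
#' (pre-normalization) acceleration so the threshold baseline sees
#' physical g.
#'
#' @param recordings List of harmonized [imu_recording()] objects.
#' @param spec A [window_spec()] at the corpus rate.
#' @param normalization `"off"`, `"per_dataset"` or `"fit_on_train"`
#'   (see [normalize_dataset()]).
#' @param train_idx Training recording indices for `"fit_on_train"`.
#' @return A feature matrix data frame; attribute `norm_params` carries the
#'   fitted normalization parameters.
#' @export
featurize_corpus <- function(recordings, spec = window_spec(rate = 18),
                             normalization = "off", train_idx = NULL) {
  if (!length(recordings)) stopf("no recordings to featurize")
  raw_peaks <- lapply(recordings, function(rec) {
    win <- segment_windows(n_samples(rec), spec)
    if (!nrow(win)) return(numeric(0))
    idx <- sapply(seq_len(nrow(win)), function(i) win[i, 1]:win[i, 2])
    norm2 <- sqrt(rowSums(rec$acc^2))
    apply(matrix(norm2[idx], nrow = spec$window_len), 2, max)
  })
  norm <- normalize_dataset(recordings, mode = normalization,
                            train_idx = train_idx)
  rows <- lapply(norm$recordings, extract_features, spec = spec)
  out <- do.call(rbind, rows)
  out$peak_acc_norm_g <- unlist(raw_peaks)
  rownames(out) <- NULL
  attr(out, "norm_params") <- norm$params
  out
}
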