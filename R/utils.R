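# internal helpers shared across modules

#' Canonical channel, feature and column vocabularies
#'
#' Column order is part of the package contract: feature matrices carry the
#' metadata columns first, then for each channel (acc_x, acc_y, acc_z,
#' gyr_x, gyr_y, gyr_z) the 13 statistics in the fixed order max, min,
#' zero_crossings, q3, std, mean, median, skewness, energy, rms, q1,
#' kurtosis, autocorr, named `<channel>__<feature>`.
#'
#' @return Character vectors: the 6 channels, the 13 feature names, and the
#'   78 feature column names respectively.
#' @export
fd_channels <- function() c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")

#' @rdname fd_channels
#' @export
fd_feature_names <- function() {
  c("max", "min", "zero_crossings", "q3", "std", "mean", "median",
    "skewness", "energy", "rms", "q1", "kurtosis", "autocorr")
}

#' @rdname fd_channels
#' @export
fd_feature_columns <- function() {
  as.vector(t(outer(fd_channels(), fd_feature_names(), paste, sep = "__")))
}

# run code under a temporary RNG state so seeded internals never clobber the
# caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
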