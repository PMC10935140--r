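#' Construct a single-trial IMU recording
#'
#' An `imu_recording` holds one trial of a wrist-worn inertial stream in the
#' package's canonical units: triaxial acceleration in g, triaxial angular
#' velocity in rad/s, a uniform time grid in seconds, and a per-sample binary
#' label (0 = activity of daily living, 1 = fall).
#'
#' @param dataset Dataset (source) name; must not contain underscores, since
#'   the filename convention uses `_` as a separator.
#' @param subject,activity,trial Positive integer identifiers.
#' @param sample_rate Sampling rate in Hz.
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   and uniform to within one sample period's tolerance.
#' @param acc,gyr Numeric matrices with one row per sample and columns
#'   x, y, z; acceleration in g, angular velocity in rad/s.
#' @param labels Integer vector over \{0, 1\}, one entry per sample.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(dataset, subject, activity, trial,
                          sample_rate, time, acc, gyr, labels) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stopf("sample_rate must be a single positive number")
  acc <- as.matrix(acc)
  gyr <- as.matrix(gyr)
  n <- length(time)
  if (nrow(acc) != n || nrow(gyr) != n || length(labels) != n)
    stopf("time, acc, gyr and labels must all have %d samples", n)
  if (ncol(acc) != 3 || ncol(gyr) != 3)
    stopf("acc and gyr must each have 3 columns (x, y, z)")
  if (!all(labels %in% c(0L, 1L)))
    stopf("labels must be 0 (ADL) or 1 (fall)")
  if (n >= 2) {
    dt <- diff(time)
    if (any(dt <= 0)) stopf("time must be strictly increasing")
    if (max(dt) - min(dt) > 1 / sample_rate + 1e-9)
      stopf("time grid is not uniform within one sample period")
  }
  colnames(acc) <- c("x", "y", "z")
  colnames(gyr) <- c("x", "y", "z")
  structure(
    list(dataset = as.character(dataset), subject = as.integer(subject),
         activity = as.integer(activity), trial = as.integer(trial),
         sample_rate = sample_rate, time = as.numeric(time),
         acc = acc, gyr = gyr, labels = as.integer(labels)),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s subject %d, activity %d, trial %d\n",
              x$dataset, x$subject, x$activity, x$trial))
  cat(sprintf("  %d samples at %g Hz (%.2f s), %d fall-labeled\n",
              length(x$time), x$sample_rate,
              if (length(x$time)) diff(range(x$time)) else 0,
              sum(x$labels)))
  invisible(x)
}

n_samples <- function(rec) length(rec$time)
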