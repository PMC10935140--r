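#' Parse a trial filename
#'
#' Trial files follow the convention
#' `<Dataset>_SubjectXX_ActivityXX_TrialXX`, with two-digit zero-padded
#' integers; an optional `.csv` extension is tolerated.
#'
#' @param name Filename (with or without `.csv`).
#' @return A list with components `dataset` (character) and `subject`,
#'   `activity`, `trial` (integers).
#' @seealso [format_filename()], its inverse.
#' @export
parse_filename <- function(name) {
  stem <- sub("\\.csv$", "", basename(name))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) != 4)
    stopf("malformed trial name '%s': expected 4 '_'-separated tokens, got %d",
          stem, length(parts))
  pats <- c(dataset = "^[A-Za-z0-9]+$", subject = "^Subject[0-9]{2,}$",
            activity = "^Activity[0-9]{2,}$", trial = "^Trial[0-9]{2,}$")
  for (i in seq_along(pats)) {
    if (!grepl(pats[i], parts[i]))
      stopf("malformed trial name '%s': token '%s' does not match %s",
            stem, parts[i], names(pats)[i])
  }
  list(dataset = parts[1],
       subject = as.integer(sub("^Subject", "", parts[2])),
       activity = as.integer(sub("^Activity", "", parts[3])),
       trial = as.integer(sub("^Trial", "", parts[4])))
}

#' Format a trial filename
#'
#' @param dataset Dataset name (no underscores).
#' @param subject,activity,trial Positive integers.
#' @return The `<Dataset>_SubjectXX_ActivityXX_TrialXX` stem.
#' @export
format_filename <- function(dataset, subject, activity, trial) {
  if (grepl("_", dataset)) stopf("dataset name must not contain '_'")
  sprintf("%s_Subject%02d_Activity%02d_Trial%02d",
          dataset, as.integer(subject), as.integer(activity),
          as.integer(trial))
}

#' Convert sensor values to canonical units
#'
#' Acceleration is unified to g (1 g = 9.80665 m/s²) and angular velocity
#' to rad/s.
#'
#' @param values Numeric vector or matrix.
#' @param quantity `"acceleration"` or `"angular_velocity"`.
#' @param from_units Source units: `"g"` or `"m/s2"` (also accepted:
#'   `"m/s^2"`) for acceleration; `"rad/s"` or `"deg/s"` for angular
#'   velocity.
#' @return `values` in g or rad/s.
#' @export
convert_units <- function(values,
                          quantity = c("acceleration", "angular_velocity"),
                          from_units) {
  quantity <- match.arg(quantity)
  if (quantity == "acceleration") {
    switch(from_units,
           "g" = values,
           "m/s2" = , "m/s^2" = values / 9.80665,
           stopf("unknown acceleration unit '%s'", from_units))
  } else {
    switch(from_units,
           "rad/s" = values,
           "deg/s" = values * pi / 180,
           stopf("unknown angular-velocity unit '%s'", from_units))
  }
}

#' Read one trial CSV into a recording
#'
#' Reads the `time_s, acc_x..gyr_z, label` trial layout and converts values
#' to canonical units using the units declared in the manifest row.
#'
#' @param path File path.
#' @param dataset,subject,activity,trial Metadata (parsed from the filename
#'   when omitted).
#' @param sample_rate Sampling rate in Hz; inferred from the median time
#'   step when `NULL`.
#' @param acc_units,gyr_units Units of the stored values.
#' @return An [imu_recording()], or `NULL` with a warning when the file
#'   contains any non-finite sensor or label value.
#' @export
read_trial_csv <- function(path, dataset = NULL, subject = NULL,
                           activity = NULL, trial = NULL, sample_rate = NULL,
                           acc_units = "g", gyr_units = "rad/s") {
  if (is.null(dataset)) {
    meta <- parse_filename(path)
    dataset <- meta$dataset; subject <- meta$subject
    activity <- meta$activity; trial <- meta$trial
  }
  df <- utils::read.csv(path)
  need <- c("time_s", "acc_x", "acc_y", "acc_z",
            "gyr_x", "gyr_y", "gyr_z", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing columns %s", path,
                          paste(miss, collapse = ", "))
  vals <- as.matrix(df[need])
  if (!all(is.finite(vals))) {
    warning(sprintf("%s: non-finite values; file dropped", basename(path)))
    return(NULL)
  }
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(diff(df$time_s))
  acc <- convert_units(as.matrix(df[c("acc_x", "acc_y", "acc_z")]),
                       "acceleration", acc_units)
  gyr <- convert_units(as.matrix(df[c("gyr_x", "gyr_y", "gyr_z")]),
                       "angular_velocity", gyr_units)
  imu_recording(dataset, subject, activity, trial, sample_rate,
                df$time_s, acc, gyr, df$label)
}

#' Drop trials containing non-finite values from a manifest
#'
#' Mirrors whole-file removal: a trial with even a single missing or
#' non-finite cell in any sensor or label column is removed entirely; each
#' removal is logged. Missing files are removed with a warning.
#'
#' @param manifest Manifest data frame with a `path` column.
#' @param base_dir Directory paths are relative to (defaults to the
#'   manifest's `out_dir` attribute).
#' @return The filtered manifest.
#' @export
drop_invalid <- function(manifest, base_dir = attr(manifest, "out_dir")) {
  keep <- rep(TRUE, nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- file.path(base_dir, manifest$path[i])
    if (!file.exists(p)) {
      warning(sprintf("missing trial file removed: %s", manifest$path[i]))
      keep[i] <- FALSE
      next
    }
    df <- utils::read.csv(p)
    num <- as.matrix(df[vapply(df, is.numeric, logical(1))])
    if (!all(is.finite(num))) {
      message(sprintf("dropping %s: non-finite values", manifest$path[i]))
      keep[i] <- FALSE
    }
  }
  out <- manifest[keep, , drop = FALSE]
  attr(out, "out_dir") <- base_dir
  out
}

#' Resample a recording onto a uniform target grid
#'
#' Channels are linearly interpolated onto a uniform grid at `target_rate`
#' spanning the original time range; the output has
#' `floor((t_end - t0) * target_rate) + 1` samples. Labels are categorical
#' and are taken from the nearest original sample. A recording already at
#' the target rate (within 1e-9 relative) is returned unchanged.
#'
#' @param rec An [imu_recording()] with at least 2 samples.
#' @param target_rate Target rate in Hz (default 18, the lowest rate among
#'   typical wrist-wearable sources).
#' @param lowpass Optional anti-alias cutoff fraction of the target Nyquist
#'   frequency; `NULL` (default) applies no filtering before
#'   interpolation. When set, a simple moving-average smoother of width
#'   `ceiling(rate / target_rate)` samples is applied first.
#' @return The resampled [imu_recording()].
#' @export
resample_recording <- function(rec, target_rate = 18, lowpass = NULL) {
  if (target_rate <= 0) stopf("target_rate must be positive")
  if (n_samples(rec) < 2) stopf("recording must have >= 2 samples")
  if (abs(rec$sample_rate - target_rate) <= 1e-9 * target_rate) return(rec)

  acc <- rec$acc; gyr <- rec$gyr
  if (!is.null(lowpass) && rec$sample_rate > target_rate) {
    w <- ceiling(rec$sample_rate / target_rate)
    smooth <- function(x) as.numeric(stats::filter(x, rep(1 / w, w),
                                                   sides = 2))
    pad <- function(x, orig) ifelse(is.na(x), orig, x)
    acc <- apply(acc, 2, function(col) pad(smooth(col), col))
    gyr <- apply(gyr, 2, function(col) pad(smooth(col), col))
  }

  t0 <- rec$time[1]
  span <- rec$time[n_samples(rec)] - t0
  m <- floor(span * target_rate + 1e-9)
  grid <- t0 + (0:m) / target_rate
  interp <- function(col) stats::approx(rec$time, col, xout = grid,
                                        rule = 2)$y
  acc_o <- apply(acc, 2, interp)
  gyr_o <- apply(gyr, 2, interp)
  nearest <- pmin(pmax(round((grid - t0) * rec$sample_rate) + 1, 1),
                  n_samples(rec))
  imu_recording(rec$dataset, rec$subject, rec$activity, rec$trial,
                target_rate, grid, acc_o, gyr_o, rec$labels[nearest])
}

fit_minmax <- function(recordings) {
  ch <- fd_channels()
  mins <- rep(Inf, 6); maxs <- rep(-Inf, 6)
  for (rec in recordings) {
    vals <- cbind(rec$acc, rec$gyr)
    mins <- pmin(mins, apply(vals, 2, min))
    maxs <- pmax(maxs, apply(vals, 2, max))
  }
  params <- rbind(min = mins, max = maxs)
  colnames(params) <- ch
  params
}

apply_minmax <- function(rec, params) {
  vals <- cbind(rec$acc, rec$gyr)
  for (j in 1:6) {
    lo <- params["min", j]; hi <- params["max", j]
    vals[, j] <- if (hi > lo) 2 * (vals[, j] - lo) / (hi - lo) - 1 else 0
  }
  imu_recording(rec$dataset, rec$subject, rec$activity, rec$trial,
                rec$sample_rate, rec$time, vals[, 1:3], vals[, 4:6],
                rec$labels)
}

#' Min-max normalize a set of recordings to [-1, 1]
#'
#' Each of the six channels is mapped affinely so that the fitted minimum
#' becomes -1 and the fitted maximum +1. The fitting scope depends on
#' `mode`: `"per_dataset"` fits one parameter set per dataset over all of
#' its recordings (mirrors pooled pre-split normalization);
#' `"fit_on_train"` fits a single parameter set on the recordings indexed
#' by `train_idx` and applies it to everything (the leakage-free variant);
#' `"off"` returns the input unchanged. Constant channels map to 0.
#'
#' @param recordings List of [imu_recording()] objects.
#' @param mode `"per_dataset"`, `"fit_on_train"` or `"off"`.
#' @param train_idx Indices of the training recordings
#'   (`mode = "fit_on_train"` only; defaults to all).
#' @param params Optional previously fitted parameters to reuse (as
#'   returned in `$params`), bypassing fitting.
#' @return A list with `recordings` (normalized) and `params` (per-dataset
#'   named list of 2 x 6 min/max matrices, or a single matrix under
#'   `"fit_on_train"`).
#' @export
normalize_dataset <- function(recordings,
                              mode = c("per_dataset", "fit_on_train", "off"),
                              train_idx = NULL, params = NULL) {
  mode <- match.arg(mode)
  if (length(recordings) == 0) stopf("no recordings to normalize")
  if (mode == "off") return(list(recordings = recordings, params = NULL))

  if (mode == "per_dataset") {
    dsets <- vapply(recordings, function(r) r$dataset, character(1))
    if (is.null(params)) {
      params <- lapply(split(recordings, dsets), fit_minmax)
    }
    out <- mapply(function(rec, d) apply_minmax(rec, params[[d]]),
                  recordings, dsets, SIMPLIFY = FALSE)
  } else {
    if (is.null(params)) {
      train_idx <- train_idx %||% seq_along(recordings)
      params <- fit_minmax(recordings[train_idx])
    }
    out <- lapply(recordings, apply_minmax, params = params)
  }
  list(recordings = out, params = params)
}

#' Load and harmonize a generated corpus
#'
#' Reads every manifest row, converts units to g and rad/s, removes files
#' with non-finite values, and resamples each trial to the common corpus
#' rate.
#'
#' @param manifest Manifest data frame (see [generate_dataset()]).
#' @param base_dir Directory the manifest paths are relative to.
#' @param target_rate Common rate in Hz (default 18).
#' @param lowpass Passed to [resample_recording()].
#' @return A list of harmonized [imu_recording()] objects.
#' @export
harmonize_corpus <- function(manifest, base_dir = attr(manifest, "out_dir"),
                             target_rate = 18, lowpass = NULL) {
  recs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- read_trial_csv(file.path(base_dir, row$path),
                          dataset = row$dataset, subject = row$subject,
                          activity = row$activity, trial = row$trial,
                          sample_rate = row$sample_rate_hz,
                          acc_units = row$acc_units,
                          gyr_units = row$gyr_units)
    if (!is.null(rec)) recs[[i]] <- resample_recording(rec, target_rate,
                                                       lowpass)
  }
  recs[!vapply(recs, is.null, logical(1))]
}
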