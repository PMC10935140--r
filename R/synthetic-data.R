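#' Describe one activity class for the synthetic generator
#'
#' An activity profile parameterizes the piecewise kinematic model used to
#' emulate one activity class on a wrist-worn IMU: a quasi-periodic movement
#' component superimposed on gravity for activities of daily living (ADL),
#' plus — for falls — a brief high-magnitude impact spike followed by a
#' quiescent lying segment with a rotated gravity axis.
#'
#' @param activity_id Positive integer id used in filenames.
#' @param name Short human-readable label.
#' @param is_fall Logical; does this activity end in a fall?
#' @param base_magnitude Resting acceleration magnitude in g (~1 for a worn
#'   device at rest).
#' @param oscillation_freq Movement frequency in Hz (arm swing, steps,
#'   claps, ...).
#' @param oscillation_amp Movement amplitude in g on top of gravity.
#' @param impact_peak Fall impact peak magnitude in g (falls only); must
#'   exceed `base_magnitude`.
#' @param impact_duration Impact spike duration in seconds (falls only).
#' @param post_impact_orientation_change Rotation of the gravity axis after
#'   the fall, in radians (falls only).
#' @param gyro_peak Peak angular velocity in rad/s.
#' @param noise_std Per-axis sensor noise standard deviation in g.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(activity_id, name, is_fall = FALSE,
                             base_magnitude = 1, oscillation_freq = 1,
                             oscillation_amp = 0.2, impact_peak = NULL,
                             impact_duration = 0.3,
                             post_impact_orientation_change = pi / 2,
                             gyro_peak = 1, noise_std = 0.02) {
  if (noise_std < 0) stopf("noise_std must be >= 0")
  if (oscillation_freq < 0) stopf("oscillation_freq must be >= 0")
  if (is_fall) {
    if (is.null(impact_peak)) stopf("fall profiles require impact_peak")
    if (impact_peak <= base_magnitude)
      stopf("impact_peak (%g) must exceed base_magnitude (%g)",
            impact_peak, base_magnitude)
    if (impact_duration <= 0) stopf("impact_duration must be > 0")
  }
  structure(
    list(activity_id = as.integer(activity_id), name = name,
         is_fall = isTRUE(is_fall), base_magnitude = base_magnitude,
         oscillation_freq = oscillation_freq,
         oscillation_amp = oscillation_amp, impact_peak = impact_peak,
         impact_duration = impact_duration,
         post_impact_orientation_change = post_impact_orientation_change,
         gyro_peak = gyro_peak, noise_std = noise_std),
    class = "activity_profile")
}

#' Default activity taxonomy for the synthetic corpus
#'
#' Five ADL classes (walking, sit-to-stand transitions, quiet standing,
#' jogging, clapping) and two fall classes (forward fall while walking,
#' backward/side fall). The clapping profile deliberately produces
#' acceleration spikes above 2.5 g with little gyroscope activity and no
#' orientation change, so magnitude-threshold detectors face realistic false
#' positives while learned models can still separate the classes.
#'
#' @return A list of [activity_profile()] objects.
#' @export
default_activity_profiles <- function() {
  list(
    activity_profile(1L, "walk", oscillation_freq = 2, oscillation_amp = 0.25,
                     gyro_peak = 1.5, noise_std = 0.03),
    activity_profile(2L, "sit_stand", oscillation_freq = 0.4,
                     oscillation_amp = 0.35, gyro_peak = 1.2,
                     noise_std = 0.03),
    activity_profile(3L, "stand_quiet", oscillation_freq = 0.3,
                     oscillation_amp = 0.05, gyro_peak = 0.2,
                     noise_std = 0.02),
    activity_profile(4L, "jog", oscillation_freq = 2.8, oscillation_amp = 0.6,
                     gyro_peak = 2.5, noise_std = 0.05),
    activity_profile(5L, "clap", oscillation_freq = 4, oscillation_amp = 1.7,
                     gyro_peak = 1.0, noise_std = 0.05),
    activity_profile(6L, "fall_forward", is_fall = TRUE,
                     oscillation_freq = 2, oscillation_amp = 0.25,
                     impact_peak = 3.2, impact_duration = 0.35,
                     post_impact_orientation_change = pi / 2,
                     gyro_peak = 5, noise_std = 0.03),
    activity_profile(7L, "fall_backward", is_fall = TRUE,
                     oscillation_freq = 1.5, oscillation_amp = 0.2,
                     impact_peak = 2.8, impact_duration = 0.3,
                     post_impact_orientation_change = 2.0,
                     gyro_peak = 4, noise_std = 0.03))
}

#' Configure the multi-source synthetic corpus generator
#'
#' @param sources A list of sources, each a list with fields `dataset_name`,
#'   `sample_rate` (Hz), `acc_units` (`"g"` or `"m/s2"`), `gyr_units`
#'   (`"rad/s"` or `"deg/s"`), `n_subjects`, `activities` (list of
#'   [activity_profile()]), `trials_per_activity` (>= 3) and
#'   `trial_duration` (s, default 15).
#' @param seed Integer seed controlling every random draw of the generator.
#' @param label_post_impact_s Seconds of the post-impact lying segment that
#'   carry the fall label, in addition to the impact interval itself;
#'   `Inf` (the default) labels the whole lying segment, so no
#'   feature-identical lying window is ever labeled ADL.
#' @param prevalence_band Expected band for the fraction of fall-labeled
#'   windows after 2 s / 50 %-overlap windowing; a warning is emitted when a
#'   generated corpus lands outside it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sources, seed = 1L, label_post_impact_s = Inf,
                             prevalence_band = c(0.02, 0.10)) {
  for (src in sources) {
    req <- c("dataset_name", "sample_rate", "acc_units", "gyr_units",
             "n_subjects", "activities", "trials_per_activity")
    miss <- setdiff(req, names(src))
    if (length(miss)) stopf("source missing fields: %s",
                            paste(miss, collapse = ", "))
    if (grepl("_", src$dataset_name))
      stopf("dataset_name must not contain '_': %s", src$dataset_name)
    if (src$sample_rate <= 0) stopf("sample_rate must be > 0")
    if ((src$trial_duration %||% 15) <= 0) stopf("trial_duration must be > 0")
    if (src$trials_per_activity < 3) stopf("trials_per_activity must be >= 3")
    falls <- vapply(src$activities, function(p) p$is_fall, logical(1))
    if (!any(falls)) stopf("source %s has no fall profile", src$dataset_name)
    if (all(falls)) stopf("source %s has no ADL profile", src$dataset_name)
  }
  structure(list(sources = sources, seed = as.integer(seed),
                 label_post_impact_s = label_post_impact_s,
                 prevalence_band = prevalence_band),
            class = "generator_config")
}

#' Default three-source study configuration
#'
#' Mirrors the heterogeneity the harmonization stage must handle: three
#' sources at 18, 20 and 50 Hz, one of which reports acceleration in m/s²
#' and angular velocity in deg/s. Ten subjects per source perform the seven
#' default activities (five ADL, two falls) three times each for 15 s.
#'
#' @param seed Integer seed.
#' @param n_subjects Subjects per source.
#' @param trials_per_activity Trials per (subject, activity).
#' @return A [generator_config()].
#' @export
default_generator_config <- function(seed = 1L, n_subjects = 10L,
                                     trials_per_activity = 3L) {
  acts <- default_activity_profiles()
  mk <- function(name, rate, acc_u, gyr_u)
    list(dataset_name = name, sample_rate = rate, acc_units = acc_u,
         gyr_units = gyr_u, n_subjects = n_subjects, activities = acts,
         trials_per_activity = trials_per_activity, trial_duration = 15)
  generator_config(
    sources = list(mk("SynA", 18, "g", "rad/s"),
                   mk("SynB", 20, "m/s2", "deg/s"),
                   mk("SynC", 50, "g", "rad/s")),
    seed = seed)
}

unit_vector <- function(v) v / sqrt(sum(v^2))

rot_x <- function(theta) {
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
}

#' Generate one labeled IMU trial
#'
#' Draws one trial from the piecewise kinematic model of an
#' [activity_profile()]: ADL trials are gravity plus quasi-periodic movement
#' and sensor noise; fall trials are a pre-fall movement segment, a
#' half-sine impact spike on the acceleration norm reaching `impact_peak`,
#' and a quiescent lying segment with the gravity axis rotated by
#' `post_impact_orientation_change`. Samples inside the impact interval and
#' the first `label_post_impact_s` seconds of lying are labeled 1; every
#' other sample (and every ADL sample) is labeled 0. Output is in canonical
#' units (g, rad/s). Sensor noise is attenuated inside the impact interval
#' so the configured peak is the realized peak magnitude.
#'
#' Draws come from the current RNG stream unless `seed` is given, in which
#' case the stream is restored afterwards; the same seed reproduces the
#' same trial exactly.
#'
#' @param profile An [activity_profile()].
#' @param rate Sampling rate in Hz.
#' @param duration Trial duration in seconds; `duration * rate` must be >= 1.
#' @param label_post_impact_s Lying-segment seconds labeled as fall
#'   (`Inf` labels through the end of the trial).
#' @param dataset,subject,trial Metadata stamped on the recording.
#' @param seed Optional integer seed for a self-contained draw.
#' @return An [imu_recording()].
#' @export
generate_trial <- function(profile, rate, duration, label_post_impact_s = Inf,
                           dataset = "Syn", subject = 1L, trial = 1L,
                           seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, generate_trial(
      profile, rate, duration, label_post_impact_s, dataset, subject, trial)))
  }
  if (rate <= 0 || duration <= 0) stopf("rate and duration must be positive")
  n <- floor(duration * rate)
  if (n < 1) stopf("duration x rate must be >= 1")
  t <- (0:(n - 1)) / rate
  sd_n <- profile$noise_std

  # movement component shared by ADL and the pre-fall segment
  osc_matrix <- function(tt, amp, freq) {
    ph <- stats::runif(3, 0, 2 * pi)
    w <- stats::runif(3, 0.4, 1)
    sapply(1:3, function(a) amp * w[a] * sin(2 * pi * freq * tt + ph[a]))
  }
  g0 <- unit_vector(c(stats::rnorm(2, 0, 0.08), 1)) * profile$base_magnitude

  if (!profile$is_fall) {
    acc <- matrix(g0, n, 3, byrow = TRUE) +
      osc_matrix(t, profile$oscillation_amp, profile$oscillation_freq) +
      matrix(stats::rnorm(3 * n, 0, sd_n), n, 3)
    gyr <- osc_matrix(t, profile$gyro_peak * 0.6, profile$oscillation_freq) +
      matrix(stats::rnorm(3 * n, 0, sd_n * 2), n, 3)
    labels <- integer(n)
  } else {
    t_imp <- stats::runif(1, 0.65, 0.80) * duration
    t_end_imp <- t_imp + profile$impact_duration
    pre <- t < t_imp
    imp <- t >= t_imp & t <= t_end_imp
    post <- t > t_end_imp

    acc <- matrix(0, n, 3)
    gyr <- matrix(0, n, 3)

    acc[pre, ] <- matrix(g0, sum(pre), 3, byrow = TRUE) +
      osc_matrix(t[pre], profile$oscillation_amp, profile$oscillation_freq)
    gyr[pre, ] <- osc_matrix(t[pre], profile$gyro_peak * 0.3,
                             profile$oscillation_freq)

    # impact: deterministic half-sine on the norm along a random direction,
    # with the sample nearest the spike center pinned at impact_peak
    if (any(imp)) {
      tau <- (t[imp] - t_imp) / profile$impact_duration
      m <- profile$base_magnitude +
        (profile$impact_peak - profile$base_magnitude) * sin(pi * tau)
      m[which.min(abs(tau - 0.5))] <- profile$impact_peak
      u <- unit_vector(stats::rnorm(3))
      acc[imp, ] <- outer(m, u)
      gimp <- profile$gyro_peak * sin(pi * tau)
      ug <- unit_vector(stats::rnorm(3))
      gyr[imp, ] <- outer(gimp, ug)
    }

    g1 <- as.vector(rot_x(profile$post_impact_orientation_change) %*% g0)
    if (any(post)) {
      acc[post, ] <- matrix(g1, sum(post), 3, byrow = TRUE) +
        osc_matrix(t[post], profile$oscillation_amp * 0.05, 0.5)
      gyr[post, ] <- osc_matrix(t[post], profile$gyro_peak * 0.03, 0.5)
    }

    noise_scale <- ifelse(imp, 0.3, 1)
    acc <- acc + matrix(stats::rnorm(3 * n, 0, sd_n), n, 3) * noise_scale
    gyr <- gyr + matrix(stats::rnorm(3 * n, 0, sd_n * 2), n, 3) * noise_scale

    labels <- as.integer(t >= t_imp &
                           t <= t_end_imp + label_post_impact_s)
  }

  imu_recording(dataset, subject, profile$activity_id, trial,
                rate, t, acc, gyr, labels)
}

write_trial_csv <- function(rec, path, acc_units, gyr_units) {
  acc <- rec$acc
  gyr <- rec$gyr
  if (acc_units %in% c("m/s2", "m/s^2")) acc <- acc * 9.80665
  if (gyr_units == "deg/s") gyr <- gyr * 180 / pi
  df <- data.frame(time_s = round(rec$time, 6),
                   acc_x = round(acc[, 1], 6), acc_y = round(acc[, 2], 6),
                   acc_z = round(acc[, 3], 6),
                   gyr_x = round(gyr[, 1], 6), gyr_y = round(gyr[, 2], 6),
                   gyr_z = round(gyr[, 3], 6),
                   label = rec$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Generate a multi-source corpus on disk
#'
#' Writes one CSV per (subject, activity, trial) under
#' `out_dir/<dataset>/`, named `<Dataset>_SubjectXX_ActivityXX_TrialXX.csv`,
#' in each source's declared units, together with a `manifest.csv` listing
#' every file with its sampling rate and units. All randomness derives from
#' `config$seed`: the same configuration reproduces byte-identical files.
#' After generation the expected fall-window prevalence (2 s windows, 50 %
#' overlap, majority label) is estimated per source and a warning is issued
#' if the corpus-wide value leaves `config$prevalence_band`.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a data frame (invisibly written to
#'   `out_dir/manifest.csv`), with columns dataset, subject, activity,
#'   trial, path (relative to `out_dir`), sample_rate_hz, acc_units,
#'   gyr_units, is_fall_activity, and attribute `out_dir`.
#' @export
generate_dataset <- function(config, out_dir) {
  if (!inherits(config, "generator_config")) stopf("config must be a generator_config")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stopf("cannot write to output directory: %s", out_dir)

  rows <- list()
  n_fall_win <- 0
  n_win <- 0
  with_seed(config$seed, {
    for (src in config$sources) {
      ddir <- file.path(out_dir, src$dataset_name)
      dir.create(ddir, showWarnings = FALSE)
      dur <- src$trial_duration %||% 15
      for (subj in seq_len(src$n_subjects)) {
        for (prof in src$activities) {
          for (tr in seq_len(src$trials_per_activity)) {
            rec <- generate_trial(prof, src$sample_rate, dur,
                                  config$label_post_impact_s,
                                  dataset = src$dataset_name,
                                  subject = subj, trial = tr)
            fname <- paste0(format_filename(src$dataset_name, subj,
                                            prof$activity_id, tr), ".csv")
            write_trial_csv(rec, file.path(ddir, fname),
                            src$acc_units, src$gyr_units)
            rows[[length(rows) + 1]] <- data.frame(
              dataset = src$dataset_name, subject = subj,
              activity = prof$activity_id, trial = tr,
              path = file.path(src$dataset_name, fname),
              sample_rate_hz = src$sample_rate,
              acc_units = src$acc_units, gyr_units = src$gyr_units,
              is_fall_activity = prof$is_fall)
            spec <- window_spec(2, 0.5, rate = src$sample_rate)
            win <- segment_windows(n_samples(rec), spec)
            if (nrow(win)) {
              wl <- apply(win, 1, function(se)
                majority_label(rec$labels[se[1]:se[2]]))
              n_fall_win <- n_fall_win + sum(wl)
              n_win <- n_win + length(wl)
            }
          }
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  prev <- if (n_win) n_fall_win / n_win else 0
  if (prev < config$prevalence_band[1] || prev > config$prevalence_band[2])
    warning(sprintf(
      "fall-window prevalence %.1f%% outside the configured band [%g%%, %g%%]",
      100 * prev, 100 * config$prevalence_band[1],
      100 * config$prevalence_band[2]))
  attr(manifest, "out_dir") <- out_dir
  attr(manifest, "fall_window_prevalence") <- prev
  invisible(manifest)
}
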