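#' Synthetic IMU trial generator configuration
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' multi-subject collections of waist-worn IMU trials with per-timestep
#' three-class annotations — gravity-dominated quasi-periodic ADL movement,
#' an elevated-jerk hazard interval (Pre-Fall), and for impacting falls a
#' free-fall dip, an impact peak, and post-impact rest. The signal model is
#' phenomenological (gravity projection + band-limited gait oscillation +
#' event templates + Gaussian noise), not a biomechanical simulation: its
#' job is statistical structure for testing, not realism.
#'
#' Two event durations are distinguished: `prefall_duration_s` (default
#' 0.3 s) is the brief transition immediately preceding ground impact — falls
#' last only around 0.8 s — while `hazard_duration_s` (default 1.5 s) is the
#' sustained dangerous interval of a near-fall the person recovers from,
#' which annotation practice marks as an extended alert window.
#'
#' @param n_young,n_elderly Subjects per group.
#' @param trials_per_subject Trials recorded per subject.
#' @param sample_rate_hz Sampling rate (default 200).
#' @param trial_duration_s Length of each trial in seconds.
#' @param adl_amplitude_g Peak gait-oscillation amplitude during ADLs (g).
#' @param fall_peak_g Impact-peak magnitude (g).
#' @param prefall_duration_s Pre-impact transition length in fall trials (s).
#' @param hazard_duration_s Alert-interval length in near-fall trials (s).
#' @param fall_duration_s Fall-event length (default 0.8 s, the typical
#'   duration of a fall).
#' @param noise_std Accelerometer noise sd (g); gyroscope noise scales with
#'   it.
#' @param gyro_adl_dps,gyro_hazard_dps Gyroscope amplitudes (deg/s) during
#'   ADLs and hazard intervals.
#' @param kind_probs Mixing probabilities for (ADL, near-fall,
#'   fall-with-impact) trials.
#' @param difficulty `"easy"` (wide class separation, so a correct trainer
#'   must succeed) or `"hard"` (overlapping amplitudes, exercising imbalance
#'   handling). The preset only fills parameters not explicitly supplied.
#' @param rng_seed Seed; identical seeds give identical datasets.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_young = 4L, n_elderly = 2L,
                             trials_per_subject = 60L,
                             sample_rate_hz = 200,
                             trial_duration_s = 6,
                             adl_amplitude_g = 0.3,
                             fall_peak_g = 5,
                             prefall_duration_s = 0.3,
                             hazard_duration_s = 1.5,
                             fall_duration_s = 0.8,
                             noise_std = 0.02,
                             gyro_adl_dps = 30,
                             gyro_hazard_dps = 150,
                             kind_probs = c(adl = 0.12, near_fall = 0.33,
                                            fall = 0.55),
                             difficulty = c("easy", "hard"),
                             rng_seed = 1L) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "hard") {
    if (missing(fall_peak_g)) fall_peak_g <- 2
    if (missing(adl_amplitude_g)) adl_amplitude_g <- 0.5
    if (missing(noise_std)) noise_std <- 0.05
    if (missing(gyro_hazard_dps)) gyro_hazard_dps <- 60
  }
  stopifnot(
    n_young >= 1L, n_elderly >= 0L, trials_per_subject >= 1L,
    sample_rate_hz > 0, trial_duration_s > 0,
    prefall_duration_s > 0, hazard_duration_s > 0, fall_duration_s > 0,
    fall_peak_g > adl_amplitude_g, noise_std >= 0,
    length(kind_probs) == 3L, all(kind_probs >= 0),
    abs(sum(kind_probs) - 1) < 1e-8
  )
  structure(
    list(n_young = as.integer(n_young), n_elderly = as.integer(n_elderly),
         trials_per_subject = as.integer(trials_per_subject),
         sample_rate_hz = sample_rate_hz, trial_duration_s = trial_duration_s,
         adl_amplitude_g = adl_amplitude_g, fall_peak_g = fall_peak_g,
         prefall_duration_s = prefall_duration_s,
         hazard_duration_s = hazard_duration_s,
         fall_duration_s = fall_duration_s,
         noise_std = noise_std,
         gyro_adl_dps = gyro_adl_dps, gyro_hazard_dps = gyro_hazard_dps,
         kind_probs = unname(kind_probs), difficulty = difficulty,
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_config"
  )
}

default_subject_profile <- function(subject_id = "SA01", group = "young") {
  list(subject_id = subject_id, group = group,
       gait_freq = if (group == "young") 1.9 else 1.4,
       amp_scale = 1, tilt = diag(3), phase = 0)
}

random_subject_profile <- function(subject_id, group) {
  p <- default_subject_profile(subject_id, group)
  p$gait_freq <- p$gait_freq + stats::rnorm(1L, 0, 0.1)
  p$amp_scale <- exp(stats::rnorm(1L, 0, 0.05))
  p$tilt <- rotation_matrix(stats::rnorm(3L), stats::rnorm(1L, 0, 3 * pi / 180))
  p$phase <- stats::runif(1L, 0, 2 * pi)
  p
}

# Gait oscillation with per-axis amplitude coefficients chosen so its vector
# norm never exceeds ~0.54 * amp, keeping the ADL acceleration norm within
# adl_amplitude_g of 1 g even with noise on top.
gait_oscillation <- function(tt, freq, amp, phase) {
  cbind(0.4 * amp * sin(2 * pi * freq * tt + phase),
        0.3 * amp * sin(2 * pi * freq * tt + phase + 1.1),
        0.2 * amp * sin(4 * pi * freq * tt + phase + 0.4))
}

#' Generate one annotated synthetic trial
#'
#' `ADL` trials are gravity-dominated quasi-periodic movement, all labels
#' Non-Fall. `NEAR_FALL` trials contain a hazard interval (rising tilt,
#' elevated jerk, large angular rates) labeled Pre-Fall, then return to
#' Non-Fall. `FALL_WITH_IMPACT` trials follow the hazard transition with a
#' Fall segment holding a free-fall dip, an impact peak of about
#' `fall_peak_g`, and post-impact rest; labels follow the segments exactly.
#'
#' @param kind One of `"ADL"`, `"NEAR_FALL"`, `"FALL_WITH_IMPACT"`.
#' @param cfg A [synthetic_config()].
#' @param subject Optional subject profile (internal); default young subject.
#' @param trial_index Trial number used in the file-name metadata.
#' @return An `annotated_trial` with 9 channels in physical units.
#' @export
generate_trial <- function(kind = c("ADL", "NEAR_FALL", "FALL_WITH_IMPACT"),
                           cfg = synthetic_config(),
                           subject = NULL, trial_index = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(subject)) subject <- default_subject_profile()
  rate <- cfg$sample_rate_hz
  T_ <- round(cfg$trial_duration_s * rate)
  tt <- (seq_len(T_) - 1L) / rate
  labels <- rep(NON_FALL, T_)

  gvec <- as.numeric(subject$tilt %*% c(0, -1, 0))  # gravity in sensor frame, g
  amp <- cfg$adl_amplitude_g * subject$amp_scale
  acc <- matrix(gvec, T_, 3L, byrow = TRUE) +
    gait_oscillation(tt, subject$gait_freq, amp, subject$phase)
  gyr <- cbind(cfg$gyro_adl_dps * sin(2 * pi * subject$gait_freq * tt + subject$phase),
               0.6 * cfg$gyro_adl_dps * sin(2 * pi * subject$gait_freq * tt + 0.8),
               0.4 * cfg$gyro_adl_dps * sin(4 * pi * subject$gait_freq * tt + 1.6))

  if (kind != "ADL") {
    pre_len <- round((if (kind == "NEAR_FALL") cfg$hazard_duration_s
                      else cfg$prefall_duration_s) * rate)
    fall_len <- round(cfg$fall_duration_s * rate)
    tail_needed <- pre_len + (if (kind == "FALL_WITH_IMPACT") fall_len else 0L) +
      round(0.5 * rate)
    t0 <- sample.int(max(1L, T_ - tail_needed - round(0.3 * T_)), 1L) +
      round(0.3 * T_)
    pre_idx <- t0:min(T_, t0 + pre_len - 1L)
    labels[pre_idx] <- PRE_FALL
    # hazard: the body tips out of its controlled posture — a sustained tilt
    # drift of the gravity direction plus a slow large sway (2-3 Hz, inside
    # the low-pass band) and fast sustained rotation on the gyroscope
    ph <- stats::runif(3L, 0, 2 * pi)
    # fast onset, then sustained: the signature fills the labeled interval
    ramp <- pmin(1, seq_along(pre_idx) / max(1, round(0.15 * length(pre_idx))))
    tilt_dir <- stats::rnorm(3L); tilt_dir <- tilt_dir / sqrt(sum(tilt_dir^2))
    sway_amp <- max(2.5 * cfg$adl_amplitude_g, 0.6)
    acc[pre_idx, ] <- acc[pre_idx, ] +
      0.7 * ramp %o% tilt_dir +
      cbind(sway_amp * ramp * sin(2 * pi * 2.5 * tt[pre_idx] + ph[1L]),
            0.8 * sway_amp * ramp * sin(2 * pi * 3 * tt[pre_idx] + ph[2L]),
            0.6 * sway_amp * ramp * sin(2 * pi * 2 * tt[pre_idx] + ph[3L]))
    gyr[pre_idx, ] <- gyr[pre_idx, ] +
      cbind(cfg$gyro_hazard_dps * ramp * sin(2 * pi * 1.5 * tt[pre_idx] + ph[1L]),
            0.7 * cfg$gyro_hazard_dps * ramp * sin(2 * pi * 2 * tt[pre_idx] + ph[2L]),
            0.5 * cfg$gyro_hazard_dps * ramp * cos(2 * pi * 1.5 * tt[pre_idx] + ph[3L]))

    if (kind == "FALL_WITH_IMPACT") {
      f0 <- pre_idx[length(pre_idx)] + 1L
      fall_idx <- f0:min(T_, f0 + fall_len - 1L)
      labels[fall_idx] <- FALL
      nf <- length(fall_idx)
      lying <- as.numeric(subject$tilt %*% c(-0.95, 0, -0.31))
      impact_at <- max(2L, round(0.45 * nf))
      rel <- seq_len(nf)
      # free-fall dip: acceleration norm collapses towards zero
      dip <- pmax(0, 1 - rel / impact_at)
      acc[fall_idx, ] <- matrix(gvec, nf, 3L, byrow = TRUE) * dip * 0.15
      # impact: short, large spike dominated by one axis
      spike <- cfg$fall_peak_g * exp(-((rel - impact_at) / 1.5)^2)
      acc[fall_idx, 2L] <- acc[fall_idx, 2L] - spike
      acc[fall_idx, 1L] <- acc[fall_idx, 1L] + 0.3 * spike
      # post-impact: settle onto the lying orientation with decaying ringing
      post <- rel > impact_at
      settle <- 1 - exp(-(rel[post] - impact_at) / (0.08 * rate))
      ring <- exp(-(rel[post] - impact_at) / (0.05 * rate)) *
        sin(2 * pi * 15 * tt[fall_idx[post]])
      acc[fall_idx[post], ] <- matrix(lying, sum(post), 3L, byrow = TRUE) * settle +
        0.4 * cfg$fall_peak_g * ring * cbind(0.3, 1, 0.2)[rep(1L, sum(post)), ]
      gyr[fall_idx, ] <- cbind(
        1.5 * cfg$gyro_hazard_dps * exp(-rel / (0.3 * rate)) * sin(2 * pi * 2 * rel / nf),
        1.2 * cfg$gyro_hazard_dps * exp(-rel / (0.3 * rate)),
        0.8 * cfg$gyro_hazard_dps * exp(-rel / (0.25 * rate)))
      # after the fall event: at rest, lying
      if (fall_idx[length(fall_idx)] < T_) {
        rest_idx <- (fall_idx[length(fall_idx)] + 1L):T_
        acc[rest_idx, ] <- matrix(lying, length(rest_idx), 3L, byrow = TRUE)
        gyr[rest_idx, ] <- 0
      }
    }
  }

  acc <- acc + matrix(stats::rnorm(3L * T_, 0, cfg$noise_std), T_, 3L)
  gyr <- gyr + matrix(stats::rnorm(3L * T_, 0, 40 * cfg$noise_std), T_, 3L)
  acc2 <- acc + matrix(stats::rnorm(3L * T_, 0, cfg$noise_std), T_, 3L)
  samples <- cbind(acc, gyr, acc2)
  colnames(samples) <- c("ax1", "ay1", "az1", "gx", "gy", "gz",
                         "ax2", "ay2", "az2")
  meta <- list(
    subject_id = subject$subject_id, subject_group = subject$group,
    activity_code = switch(kind, ADL = "D01", NEAR_FALL = "F01",
                           FALL_WITH_IMPACT = "F02"),
    activity_class = if (kind == "ADL") "ADL" else "FALL",
    trial_index = as.integer(trial_index)
  )
  annotate_trial(new_raw_trial(samples, meta, rate), labels)
}

#' Generate a multi-subject annotated trial collection
#'
#' Builds `n_young + n_elderly` subjects with individual gait frequency,
#' amplitude, and mounting-tilt offsets (so subject-wise splits are
#' meaningful) and `trials_per_subject` trials each, mixing the three trial
#' kinds by `kind_probs`. Non-Fall dominates the resulting block labels, as
#' in real recordings.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `trials` (list of `annotated_trial`) and `roster`
#'   (data frame of `subject_id`, `group`).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$rng_seed)
  roster <- data.frame(
    subject_id = c(sprintf("SA%02d", seq_len(cfg$n_young)),
                   if (cfg$n_elderly > 0L) sprintf("SE%02d", seq_len(cfg$n_elderly))),
    group = c(rep("young", cfg$n_young), rep("elderly", cfg$n_elderly)),
    stringsAsFactors = FALSE
  )
  kinds <- c("ADL", "NEAR_FALL", "FALL_WITH_IMPACT")
  trials <- list()
  for (i in seq_len(nrow(roster))) {
    prof <- random_subject_profile(roster$subject_id[i], roster$group[i])
    counter <- c(D01 = 0L, F01 = 0L, F02 = 0L)
    for (k in seq_len(cfg$trials_per_subject)) {
      kind <- sample(kinds, 1L, prob = cfg$kind_probs)
      code <- switch(kind, ADL = "D01", NEAR_FALL = "F01",
                     FALL_WITH_IMPACT = "F02")
      counter[code] <- counter[code] + 1L
      trials[[length(trials) + 1L]] <-
        generate_trial(kind, cfg, prof, trial_index = counter[code])
    }
  }
  list(trials = trials, roster = roster)
}

#' Write a generated dataset in the SisFall on-disk dialect
#'
#' Emits one `.txt` trial file (integer ADC counts) and one annotation file
#' per trial, so tests exercise the real reader path end to end.
#'
#' @param dataset Result of [generate_dataset()].
#' @param raw_dir,annot_dir Output directories.
#' @param scale A [sisfall_scales()] object.
#' @return Invisibly, the vector of trial file paths.
#' @export
write_sisfall_dataset <- function(dataset, raw_dir, annot_dir,
                                  scale = sisfall_scales()) {
  paths <- vapply(dataset$trials, write_sisfall_trial, "", raw_dir = raw_dir,
                  annot_dir = annot_dir, scale = scale)
  invisible(paths)
}
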