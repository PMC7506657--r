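#' Parameters of the synthetic gait generator
#'
#' The generator emulates the structure of step-segmented waist-sensor
#' recordings: five activity classes with a configurable (by default
#' heavily imbalanced, 13/12/63/6/6 percent) class distribution, per-step
#' segments of a few tenths of a second at 100 Hz, accelerations within
#' +/-4 g and angular velocities within +/-500 deg/s.
#'
#' Each step is a sum of a class-dependent fundamental sinusoid at the
#' step frequency plus one harmonic on the forward axis, a ~1 g gravity
#' offset on the vertical accelerometer axis, a class-dependent pitch
#' pattern on the gyroscope (opposite signs for up/down variants), and
#' white Gaussian noise. `separation` spaces the class-conditional
#' amplitudes in units of the noise standard deviation: at 0 all five
#' classes are statistically identical; at >= 4 the classes are separable
#' nearly without error. The forward axis is randomized per synthetic
#' subject so forward-direction selection is genuinely exercised.
#'
#' @param sampling_rate Sampling rate [Hz].
#' @param duration_range Step duration range [s], within (0, 2].
#' @param base_amplitude Baseline forward-acceleration amplitude [g].
#' @param base_gyro_amplitude Baseline gyroscope pitch amplitude [deg/s].
#' @param step_frequency Baseline step frequency [Hz].
#' @param noise_sd_acc Accelerometer noise sd [g].
#' @param noise_sd_gyr Gyroscope noise sd [deg/s].
#' @param separation Inter-class spacing in noise-sd units (>= 0).
#' @param class_proportions Five non-negative weights (normalized
#'   internally); defaults to the 13/12/63/6/6 percent imbalance.
#' @param n_subjects Number of synthetic subjects (each with its own axis
#'   orientation and gain).
#' @param seed Integer seed.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(sampling_rate = 100,
                             duration_range = c(0.4, 0.8),
                             base_amplitude = 0.5,
                             base_gyro_amplitude = 60,
                             step_frequency = 2,
                             noise_sd_acc = 0.08,
                             noise_sd_gyr = 12,
                             separation = 2,
                             class_proportions = c(0.13, 0.12, 0.63,
                                                   0.06, 0.06),
                             n_subjects = 10,
                             seed = 1) {
  stopifnot(length(duration_range) == 2, all(duration_range > 0),
            all(duration_range <= 2), separation >= 0,
            length(class_proportions) == 5, all(class_proportions >= 0),
            sum(class_proportions) > 0)
  structure(list(sampling_rate = sampling_rate,
                 duration_range = sort(duration_range),
                 base_amplitude = base_amplitude,
                 base_gyro_amplitude = base_gyro_amplitude,
                 step_frequency = step_frequency,
                 noise_sd_acc = noise_sd_acc,
                 noise_sd_gyr = noise_sd_gyr,
                 separation = separation,
                 class_proportions = class_proportions /
                   sum(class_proportions),
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "generator_params")
}

# Class-conditional offsets applied on top of the baseline parameters,
# all scaled by `separation`: amp/gyr offsets in noise-sd units (what the
# statistical features see), freq/dur as relative shifts and harm as an
# additive harmonic weight (what survives the offset/scale-invariant GAF
# encoding: cycles per step and waveform shape). At separation 0 all five
# profiles coincide.
.class_profile <- function(activity) {
  switch(activity,
    down_incline = list(amp = -0.6, gyr = 0.8, gyr_sign = -1,
                        freq = 0.06, dur = 0.00, harm = -0.05),
    up_incline   = list(amp = 0.6, gyr = 0.8, gyr_sign = 1,
                        freq = -0.06, dur = 0.00, harm = 0.05),
    level        = list(amp = 0, gyr = 0, gyr_sign = 1,
                        freq = 0, dur = 0, harm = 0),
    down_stairs  = list(amp = 1.4, gyr = 2.0, gyr_sign = -1,
                        freq = 0.10, dur = -0.03, harm = 0.10),
    up_stairs    = list(amp = 1.8, gyr = 2.4, gyr_sign = 1,
                        freq = -0.10, dur = 0.04, harm = 0.15))
}

# per-subject sensor orientation: permutation of (forward, lateral,
# vertical) onto the x/y/z axes, plus a small per-subject gain
.subject_profiles <- function(n_subjects) {
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1),
                c(1, 3, 2), c(2, 3, 1), c(3, 1, 2))
  lapply(seq_len(n_subjects), function(i) {
    list(axes = perms[[sample.int(6, 1)]],
         gain = stats::runif(1, 0.9, 1.1))
  })
}

#' Generate one synthetic step segment
#'
#' @param activity One of [gait_activities()].
#' @param params A [generator_params()].
#' @param subject Optional subject profile (internal); a fresh one is
#'   drawn when `NULL`.
#' @return A [step_segment()] with `provenance = "synthetic"`.
#' @export
generate_step <- function(activity, params = generator_params(),
                          subject = NULL) {
  activity <- as.character(parse_activity(activity))
  p <- .class_profile(activity)
  if (is.null(subject)) subject <- .subject_profiles(1)[[1]]
  sep <- params$separation
  dur <- stats::runif(1, params$duration_range[1], params$duration_range[2])
  dur <- dur * (1 + sep * p$dur)
  dur <- min(max(dur, params$duration_range[1]), params$duration_range[2])
  n <- max(4L, as.integer(round(dur * params$sampling_rate)))
  t <- (seq_len(n) - 1) / params$sampling_rate
  freq <- params$step_frequency * (1 + sep * p$freq)
  # independent phases per sensor: with a shared phase the class-dependent
  # pitch sign would be identifiable from cross-sensor correlations even at
  # separation 0, where all classes must be statistically identical
  phase <- stats::runif(1, 0, 2 * pi)
  phase_g <- stats::runif(1, 0, 2 * pi)
  g <- subject$gain

  amp <- g * (params$base_amplitude + sep * p$amp * params$noise_sd_acc)
  gyr_amp <- g * (params$base_gyro_amplitude +
                    sep * p$gyr * params$noise_sd_gyr)
  harm <- min(max(0.3 + sep * p$harm, 0), 1.2)
  w <- 2 * pi * freq
  forward <- amp * (sin(w * t + phase) + harm * sin(2 * w * t + phase))
  vertical <- g * 1.0 + 0.8 * amp * sin(w * t + phase + pi / 2) +
    0.3 * amp * harm * sin(2 * w * t + phase)
  lateral <- 0.3 * amp * sin(w * t / 2 + phase)
  pitch <- p$gyr_sign * gyr_amp *
    (sin(w * t + phase_g) + 0.3 * harm * sin(2 * w * t + phase_g))
  roll <- 0.3 * gyr_amp * sin(w * t / 2 + phase_g)
  yaw <- 0.2 * gyr_amp * sin(w * t + phase_g + pi / 3)

  acc <- cbind(forward, lateral, vertical)[, order(subject$axes)]
  gyr <- cbind(pitch, roll, yaw)[, order(subject$axes)]
  acc <- acc + stats::rnorm(3 * n, 0, params$noise_sd_acc)
  gyr <- gyr + stats::rnorm(3 * n, 0, params$noise_sd_gyr)
  acc <- pmin(pmax(acc, -4), 4)
  gyr <- pmin(pmax(gyr, -500), 500)
  step_segment(acc, gyr, label = activity,
               sampling_rate = params$sampling_rate,
               subject_id = NA_character_,
               provenance = "synthetic")
}

#' Largest-remainder apportionment of class counts
#'
#' @param n_total Total instance count.
#' @param proportions Five non-negative weights.
#' @return Named integer counts over the five activities summing to
#'   `n_total`.
#' @export
apportion_counts <- function(n_total, proportions) {
  p <- proportions / sum(proportions)
  raw <- n_total * p
  counts <- floor(raw)
  short <- n_total - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), GAIT_ACTIVITIES)
}

#' Generate a synthetic step dataset
#'
#' Per-class counts follow largest-remainder apportionment of the class
#' proportions; steps are assigned round-robin to synthetic subjects.
#' Deterministic under the params seed.
#'
#' @param n_total Total number of steps (>= 5).
#' @param params A [generator_params()].
#' @param name Dataset name.
#' @return A [step_dataset()].
#' @examples
#' d <- generate_dataset(100, generator_params(seed = 7))
#' class_histogram(d)  # 13 12 63 6 6
#' @export
generate_dataset <- function(n_total, params = generator_params(),
                             name = "synthetic_gait") {
  stopifnot(n_total >= 5)
  set.seed(params$seed)
  counts <- apportion_counts(n_total, params$class_proportions)
  subjects <- .subject_profiles(params$n_subjects)
  segs <- list()
  for (cl in GAIT_ACTIVITIES) {
    for (i in seq_len(counts[[cl]])) {
      sidx <- ((length(segs)) %% params$n_subjects) + 1L
      s <- generate_step(cl, params, subject = subjects[[sidx]])
      s$subject_id <- sprintf("S%02d", sidx)
      segs[[length(segs) + 1L]] <- s
    }
  }
  step_dataset(segs, name = name)
}
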