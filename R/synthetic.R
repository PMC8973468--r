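#' Synthetic digit-span generator configuration
#'
#' Defines the experimental structure the generator emulates: a 2 s
#' prestimulus fixation ("X" on screen), then a digit sequence shown one digit
#' per second — 3, 5 or 8 digits for low / medium / high difficulty — followed
#' by a short retention interval. The mean pupil trajectory holds the
#' subject's baseline during fixation, ramps linearly to a
#' difficulty-dependent peak at the end of digit presentation, then decays
#' exponentially (2 s time constant). Subjects differ in baseline diameter and
#' in a multiplicative dilation sensitivity; both eyes see the common
#' trajectory plus independent jitter and shared measurement noise, and blinks
#' appear as short runs of invalid samples.
#'
#' @param n_subjects number of subjects (default 24).
#' @param trials_per_level trials per subject per difficulty level (default 12).
#' @param sampling_rate samples per second (default 50, a typical remote eye
#'   tracker rate; may be set as low as 1 to mimic coarse per-second records).
#' @param prestimulus_s length of the fixation phase (default 2 s).
#' @param digits_per_level named integer vector: digits shown per level.
#' @param post_digit_s retention time appended after the last digit (default 2 s).
#' @param baseline_mean,baseline_sd_between_subjects population mean and
#'   between-subject SD of the baseline diameter (mm). Defaults 4.0 and 0.5 mm:
#'   plausible for a bright room. The baseline distribution is identical
#'   across difficulty levels by construction.
#' @param amplitude_by_level named numeric vector: mean peak dilation above
#'   baseline per level (mm), strictly increasing under the defaults
#'   (0.12 / 0.24 / 0.44 mm, magnitudes in line with reported visual and aural
#'   digit-retention dilations).
#' @param amplitude_subject_sd between-subject SD of the dilation amplitude
#'   (mm); converted into the log-scale spread of a unit-median lognormal
#'   sensitivity factor by dividing by the mean amplitude. Default 0.05 mm.
#' @param noise_sd per-sample measurement noise SD (mm), default 0.05.
#' @param eye_jitter_sd independent per-eye jitter SD (mm), default 0.02.
#' @param blink_prob per-sample probability that a blink (a run of 2-10
#'   consecutive invalid samples) starts, default 0.01.
#' @param seed integer seed making the dataset fully reproducible.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 24L,
                             trials_per_level = 12L,
                             sampling_rate = 50,
                             prestimulus_s = 2.0,
                             digits_per_level = c(low = 3L, medium = 5L, high = 8L),
                             post_digit_s = 2.0,
                             baseline_mean = 4.0,
                             baseline_sd_between_subjects = 0.5,
                             amplitude_by_level = c(low = 0.12, medium = 0.24, high = 0.44),
                             amplitude_subject_sd = 0.05,
                             noise_sd = 0.05,
                             eye_jitter_sd = 0.02,
                             blink_prob = 0.01,
                             seed = 1L) {
  stopifnot(n_subjects >= 1L, trials_per_level >= 1L, sampling_rate >= 1,
            prestimulus_s > 0, post_digit_s >= 0,
            all(DIFFICULTY_LEVELS %in% names(digits_per_level)),
            all(DIFFICULTY_LEVELS %in% names(amplitude_by_level)),
            baseline_mean > 0, baseline_sd_between_subjects >= 0,
            amplitude_subject_sd >= 0, noise_sd >= 0, eye_jitter_sd >= 0,
            blink_prob >= 0, blink_prob <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_level = as.integer(trials_per_level),
                 sampling_rate = sampling_rate,
                 prestimulus_s = prestimulus_s,
                 digits_per_level = digits_per_level[DIFFICULTY_LEVELS],
                 post_digit_s = post_digit_s,
                 baseline_mean = baseline_mean,
                 baseline_sd_between_subjects = baseline_sd_between_subjects,
                 amplitude_by_level = amplitude_by_level[DIFFICULTY_LEVELS],
                 amplitude_subject_sd = amplitude_subject_sd,
                 noise_sd = noise_sd,
                 eye_jitter_sd = eye_jitter_sd,
                 blink_prob = blink_prob,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Null-condition generator configuration
#'
#' The same generator with the difficulty label made uninformative: every
#' level uses the same dilation amplitude *and* the same number of digits, so
#' trial duration, trajectory and all downstream features are identically
#' distributed across labels. Used for type-I-error studies.
#'
#' @param ... overrides passed to [generator_config()].
#' @param amplitude common peak dilation (mm) for all levels (default 0.24).
#' @param digits common digit count for all levels (default 5).
#' @return list of class `generator_config`.
#' @export
null_generator_config <- function(..., amplitude = 0.24, digits = 5L) {
  generator_config(
    amplitude_by_level = c(low = amplitude, medium = amplitude, high = amplitude),
    digits_per_level = c(low = digits, medium = digits, high = digits),
    ...)
}

#' Draw one subject profile
#'
#' Baseline is Normal(baseline_mean, baseline_sd) truncated to positive values
#' (redrawn); sensitivity is lognormal with unit median and log-scale SD
#' `amplitude_subject_sd / mean(amplitude_by_level)`.
#'
#' @param config a [generator_config()].
#' @param subject_id identifier for the profile.
#' @return list with `subject_id`, `baseline` (mm), `sensitivity` (factor).
#' @export
sample_subject <- function(config, subject_id = "s01") {
  baseline <- -1
  while (baseline <= 0) {
    baseline <- rnorm(1L, config$baseline_mean,
                      config$baseline_sd_between_subjects)
  }
  sdlog <- config$amplitude_subject_sd / mean(config$amplitude_by_level)
  sensitivity <- rlnorm(1L, meanlog = 0, sdlog = sdlog)
  list(subject_id = subject_id, baseline = baseline, sensitivity = sensitivity)
}

# mean trajectory at onset-relative times `t` (t < 0 is prestimulus):
# baseline, linear ramp to baseline + amp peaking at t_peak, exp decay after
trajectory_mean <- function(t, baseline, amp, t_peak, decay_s = 2.0) {
  y <- rep(baseline, length(t))
  ramp <- t >= 0 & t <= t_peak
  y[ramp] <- baseline + amp * t[ramp] / t_peak
  post <- t > t_peak
  y[post] <- baseline + amp * exp(-(t[post] - t_peak) / decay_s)
  y
}

#' Simulate one digit-span trial
#'
#' Consumes the current RNG stream; seed management belongs to
#' [simulate_dataset()].
#'
#' @param subject profile from [sample_subject()].
#' @param difficulty `"low"`, `"medium"` or `"high"`.
#' @param config a [generator_config()].
#' @param trial_id identifier for the trial.
#' @return data.frame of trial rows in the [pupil_dataset()] long format.
#' @export
simulate_trial <- function(subject, difficulty, config, trial_id = "t001") {
  stopifnot(difficulty %in% DIFFICULTY_LEVELS)
  digits <- config$digits_per_level[[difficulty]]
  amp <- config$amplitude_by_level[[difficulty]] * subject$sensitivity
  dt <- 1 / config$sampling_rate
  t <- seq(-config$prestimulus_s, digits + config$post_digit_s, by = dt)
  mu <- trajectory_mean(t, subject$baseline, amp, t_peak = digits)
  n <- length(t)
  common <- mu + rnorm(n, 0, config$noise_sd)
  left <- pmax(common + rnorm(n, 0, config$eye_jitter_sd), 0.1)
  right <- pmax(common + rnorm(n, 0, config$eye_jitter_sd), 0.1)
  valid <- rep(TRUE, n)
  starts <- which(runif(n) < config$blink_prob)
  for (s in starts) {
    len <- sample(2:10, 1L)
    valid[s:min(n, s + len - 1L)] <- FALSE
  }
  left[!valid] <- NA_real_
  right[!valid] <- NA_real_
  data.frame(subject_id = subject$subject_id, trial_id = trial_id,
             difficulty = difficulty, time_s = t,
             left_mm = left, right_mm = right, valid = valid,
             stringsAsFactors = FALSE)
}

#' Simulate a full digit-span dataset
#'
#' `n_subjects * 3 * trials_per_level` trials; each subject performs
#' `trials_per_level` trials at every level in a randomized order. The result
#' is bit-reproducible from `config$seed`, and the caller's RNG stream is left
#' untouched.
#'
#' @param config a [generator_config()].
#' @return a [pupil_dataset()].
#' @export
simulate_dataset <- function(config = generator_config()) {
  with_seed(config$seed, {
    subjects <- lapply(seq_len(config$n_subjects), function(i) {
      sample_subject(config, sprintf("s%02d", i))
    })
    rows <- vector("list", config$n_subjects)
    for (i in seq_along(subjects)) {
      levels_seq <- sample(rep(DIFFICULTY_LEVELS, config$trials_per_level))
      trial_rows <- vector("list", length(levels_seq))
      for (j in seq_along(levels_seq)) {
        trial_rows[[j]] <- simulate_trial(subjects[[i]], levels_seq[j], config,
                                          trial_id = sprintf("t%03d", j))
      }
      rows[[i]] <- do.call(rbind, trial_rows)
    }
    pupil_dataset(do.call(rbind, rows), validate = FALSE)
  })
}
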