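# fixtures shared across test files; everything is built in code

# one trial in the long sample format
make_trial_df <- function(subject = "s01", trial = "t01", difficulty = "low",
                          time, left, right = left, valid = TRUE) {
  data.frame(subject_id = subject, trial_id = trial, difficulty = difficulty,
             time_s = time, left_mm = left, right_mm = right,
             valid = rep_len(valid, length(time)), stringsAsFactors = FALSE)
}

# minimal well-formed trial: 2 prestimulus + n stimulus samples at 1 Hz
make_simple_trial <- function(stim = c(4.0, 4.2, 4.4, 4.3), ...) {
  n <- length(stim)
  make_trial_df(time = c(-2, -1, seq(0, n - 1)), left = c(4.0, 4.0, stim), ...)
}

# a clean_trial built directly, bypassing preprocessing
make_clean_trial <- function(pre_diam = c(4.0, 4.2),
                             stim_times = 0:5,
                             stim_diam = c(4.1, 4.3, 4.5, 4.4, 4.2, 4.1),
                             difficulty = "low") {
  structure(list(subject_id = "s01", trial_id = "t01",
                 difficulty = difficulty,
                 pre_times = seq(-2, by = 1, length.out = length(pre_diam)),
                 pre_diam = pre_diam,
                 stim_times = stim_times, stim_diam = stim_diam,
                 n_dropped = 0L, invalid_fraction = 0, smoothed = FALSE),
            class = "clean_trial")
}

# small fast generator setup for pipeline-level tests
small_generator <- function(...) {
  generator_config(n_subjects = 6L, trials_per_level = 3L, sampling_rate = 5,
                   ...)
}

# feature-style data simulated straight from the mixed model:
# y = mu + offset[level] + subject intercept + noise
make_lmm_data <- function(n_subjects = 24L, trials_per_level = 12L,
                          offsets = c(low = 0, medium = 0.1, high = 0.3),
                          mu = 0, subject_sd = 0.05, sigma = 0.05,
                          seed = 1L) {
  set.seed(seed)
  levels3 <- c("low", "medium", "high")
  d <- expand.grid(subject_id = sprintf("s%02d", seq_len(n_subjects)),
                   difficulty = levels3,
                   rep = seq_len(trials_per_level),
                   stringsAsFactors = FALSE)
  b <- stats::setNames(rnorm(n_subjects, 0, subject_sd),
                       sprintf("s%02d", seq_len(n_subjects)))
  d$y <- mu + offsets[d$difficulty] + b[d$subject_id] +
    rnorm(nrow(d), 0, sigma)
  d
}

# three well-separated gaussian clusters in feature space, one per level
make_separable_features <- function(n_per_class = 50L, seed = 1L) {
  set.seed(seed)
  levels3 <- c("low", "medium", "high")
  centers <- list(low = c(0, 0), medium = c(6, 0), high = c(0, 6))
  rows <- lapply(levels3, function(lev) {
    data.frame(difficulty = lev,
               f1 = rnorm(n_per_class, centers[[lev]][1], 0.3),
               f2 = rnorm(n_per_class, centers[[lev]][2], 0.3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$subject_id <- sprintf("s%02d", rep_len(1:10, nrow(out)))
  out
}
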