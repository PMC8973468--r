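#' Preprocessing configuration
#'
#' @param window Savitzky-Golay window length in samples; must be odd and
#'   larger than `polyorder`. Default 7: at the trace lengths involved this is
#'   mild smoothing that preserves the peak structure of the dilation.
#' @param polyorder Savitzky-Golay polynomial order (default 2).
#' @param max_invalid_fraction trials with a larger proportion of invalid
#'   records are rejected; the bound is inclusive ("not more than 20%").
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(window = 7L, polyorder = 2L,
                              max_invalid_fraction = 0.20) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  stopifnot(window %% 2L == 1L, window > polyorder, polyorder >= 0L,
            max_invalid_fraction >= 0, max_invalid_fraction <= 1)
  structure(list(window = window, polyorder = polyorder,
                 max_invalid_fraction = max_invalid_fraction),
            class = "preprocess_config")
}

#' Merge the two eyes into a single diameter
#'
#' Records with information in both eyes are averaged; records with data in
#' only one eye pass through unchanged; records with neither eye are missing.
#' Vectorized and symmetric in its arguments.
#'
#' @param left,right pupil diameters in mm, `NA` when missing.
#' @return numeric vector of merged diameters (mm), `NA` where both missing.
#' @export
merge_eyes <- function(left, right) {
  m <- rowMeans(cbind(left, right), na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

#' Remove invalid records from a trial
#'
#' A record is invalid iff its validity flag is false or both diameters are
#' missing (the eye tracker's validity codes stand in for blink detection).
#'
#' @param trial data.frame with at least `left_mm`, `right_mm`, `valid`.
#' @return list with `samples` (the retained rows) and `invalid_fraction`
#'   (removed / total).
#' @export
drop_invalid <- function(trial) {
  stopifnot(nrow(trial) > 0L)
  bad <- !trial$valid | (is.na(trial$left_mm) & is.na(trial$right_mm))
  frac <- mean(bad)
  if (all(bad)) stop("empty trial: all records invalid")
  list(samples = trial[!bad, , drop = FALSE], invalid_fraction = frac)
}

#' Trial validity rule
#'
#' A valid trial must not have more than `threshold` invalid records; the
#' comparison is inclusive, so a fraction exactly at the threshold is kept.
#'
#' @param invalid_fraction proportion of invalid records in `[0, 1]`.
#' @param threshold maximum tolerated proportion (default 0.20).
#' @return logical.
#' @export
trial_is_valid <- function(invalid_fraction, threshold = 0.20) {
  stopifnot(all(invalid_fraction >= 0), all(invalid_fraction <= 1))
  invalid_fraction <= threshold
}

#' Savitzky-Golay smoothing of a diameter series
#'
#' Local least-squares polynomial smoothing; reproduces exactly any input that
#' is a polynomial of degree at most `polyorder` (including the endpoints).
#' Series shorter than the window are returned unchanged with a warning, since
#' a trial is only guaranteed to hold three stimulus measurements.
#'
#' @param diam numeric series (mm).
#' @param window odd window length in samples.
#' @param polyorder polynomial order, `< window`.
#' @return smoothed series of the same length.
#' @export
smooth_trace <- function(diam, window = 7L, polyorder = 2L) {
  window <- as.integer(window)
  stopifnot(window %% 2L == 1L, window > polyorder)
  if (length(diam) < window) {
    warning(sprintf("series of length %d shorter than window %d: unsmoothed",
                    length(diam), window))
    return(diam)
  }
  as.numeric(signal::sgolayfilt(diam, p = polyorder, n = window))
}

#' Preprocess one trial
#'
#' Applies the record-level cleaning, the binocular merge, the invalid-trial
#' rule and stimulus-phase smoothing, in that order. The baseline (prestimulus)
#' series stays unsmoothed. Rejection is returned as a value, not signalled.
#'
#' @param trial data.frame of one trial's rows (long format, see
#'   [pupil_dataset()]).
#' @param config a [preprocess_config()].
#' @return On success, a list of class `clean_trial` with elements
#'   `subject_id`, `trial_id`, `difficulty`, `pre_times`, `pre_diam`,
#'   `stim_times`, `stim_diam`, `n_dropped`, `invalid_fraction`, `smoothed`.
#'   On rejection, a list of class `trial_rejection` with a `reason`.
#' @export
preprocess_trial <- function(trial, config = preprocess_config()) {
  rejection <- function(reason) {
    structure(list(subject_id = trial$subject_id[1L],
                   trial_id = trial$trial_id[1L], reason = reason),
              class = "trial_rejection")
  }
  dropped <- tryCatch(drop_invalid(trial), error = function(e) NULL)
  if (is.null(dropped)) return(rejection("all records invalid"))
  if (!trial_is_valid(dropped$invalid_fraction, config$max_invalid_fraction)) {
    return(rejection(sprintf("invalid_fraction %.3f > %.2f",
                             dropped$invalid_fraction,
                             config$max_invalid_fraction)))
  }
  kept <- dropped$samples
  diam <- merge_eyes(kept$left_mm, kept$right_mm)
  pre <- kept$time_s < 0
  if (!any(pre)) stop("empty prestimulus phase: baseline undefined")
  if (sum(!pre) < 3L) return(rejection("fewer than 3 stimulus samples"))
  stim_diam <- diam[!pre]
  smoothed <- length(stim_diam) >= config$window
  if (smoothed) {
    stim_diam <- smooth_trace(stim_diam, config$window, config$polyorder)
  }
  structure(list(subject_id = trial$subject_id[1L],
                 trial_id = trial$trial_id[1L],
                 difficulty = trial$difficulty[1L],
                 pre_times = kept$time_s[pre],
                 pre_diam = diam[pre],
                 stim_times = kept$time_s[!pre],
                 stim_diam = stim_diam,
                 n_dropped = nrow(trial) - nrow(kept),
                 invalid_fraction = dropped$invalid_fraction,
                 smoothed = smoothed),
            class = "clean_trial")
}

#' Preprocess every trial of a dataset
#'
#' @param dataset a [pupil_dataset()].
#' @param config a [preprocess_config()].
#' @return list with `trials` (list of `clean_trial`) and `rejections`
#'   (data.frame `subject_id`, `trial_id`, `reason`; zero rows when nothing
#'   was rejected). Accepted and rejected trials partition the input.
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  out <- suppressWarnings(
    lapply(dataset_trials(dataset), function(tr) {
      tryCatch(preprocess_trial(tr, config = config), error = function(e) {
        structure(list(subject_id = tr$subject_id[1L],
                       trial_id = tr$trial_id[1L],
                       reason = conditionMessage(e)),
                  class = "trial_rejection")
      })
    })
  )
  rejected <- vapply(out, inherits, logical(1L), "trial_rejection")
  rej <- out[rejected]
  rejections <- data.frame(
    subject_id = vapply(rej, `[[`, character(1L), "subject_id"),
    trial_id = vapply(rej, `[[`, character(1L), "trial_id"),
    reason = vapply(rej, `[[`, character(1L), "reason"),
    stringsAsFactors = FALSE)
  list(trials = unname(out[!rejected]), rejections = rejections)
}
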