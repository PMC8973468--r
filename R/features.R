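#' Feature-extraction configuration
#'
#' @param entropy_bin_width bin width in mm for the pupil-size entropy. The
#'   stimulus-phase diameters are discretized into bins of this width anchored
#'   at the trial minimum; 0.01 mm matches typical device quantization.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(entropy_bin_width = 0.01) {
  stopifnot(entropy_bin_width > 0)
  structure(list(entropy_bin_width = entropy_bin_width),
            class = "feature_config")
}

FEATURE_NAMES <- c("BLPS", "MPDC", "APCPS", "PD", "E_pupil", "TTP", "PDS")

#' Baseline pupil size
#'
#' Mean pupil diameter over the prestimulus fixation phase; the per-trial
#' reference from which every change feature is measured.
#'
#' @param pre_diam prestimulus diameters (mm), non-empty.
#' @return mm.
#' @export
compute_blps <- function(pre_diam) {
  if (length(pre_diam) == 0L) stop("baseline undefined: empty prestimulus series")
  mean(pre_diam)
}

#' Mean pupil diameter change
#'
#' Mean stimulus-phase diameter minus the baseline; negative values indicate
#' net constriction.
#'
#' @param stim_diam stimulus-phase diameters (mm), non-empty.
#' @param blps baseline (mm).
#' @return mm.
#' @export
compute_mpdc <- function(stim_diam, blps) {
  if (length(stim_diam) == 0L) stop("empty stimulus series")
  mean(stim_diam) - blps
}

#' Per-sample percentage change in pupil size
#'
#' @param stim_diam stimulus-phase diameters (mm).
#' @param blps baseline (mm), strictly positive.
#' @return dimensionless proportion series `(PS_i - BLPS) / BLPS`.
#' @export
compute_pcps <- function(stim_diam, blps) {
  if (!is.finite(blps) || blps <= 0) stop("baseline must be positive")
  (stim_diam - blps) / blps
}

#' Average percentage change in pupil size
#'
#' @param pcps proportion series from [compute_pcps()], non-empty.
#' @return dimensionless proportion. Satisfies `APCPS * BLPS == MPDC` exactly
#'   (algebraic identity of the three definitions).
#' @export
compute_apcps <- function(pcps) {
  if (length(pcps) == 0L) stop("empty series")
  mean(pcps)
}

#' Peak pupil dilation
#'
#' The peak pupil diameter (PPD) is the stimulus-phase maximum; PD subtracts
#' the baseline to remove between-eye/person size differences. Ties are broken
#' by first occurrence (earliest attainment of the maximum).
#'
#' @param stim_diam stimulus-phase diameters (mm), non-empty.
#' @param blps baseline (mm).
#' @return list with `pd` (mm), `ppd` (mm) and `peak_index` (1-based).
#' @export
compute_pd <- function(stim_diam, blps) {
  if (length(stim_diam) == 0L) stop("empty stimulus series")
  peak_index <- which.max(stim_diam)
  ppd <- stim_diam[peak_index]
  list(pd = ppd - blps, ppd = ppd, peak_index = peak_index)
}

#' Pupil-size entropy
#'
#' Shannon entropy (base 2) of the relative-frequency distribution of the
#' stimulus-phase diameters discretized into bins of width `bin_width`
#' anchored at the series minimum.
#'
#' @param stim_diam stimulus-phase diameters (mm), non-empty.
#' @param bin_width bin width (mm), positive.
#' @return bits (non-negative).
#' @export
compute_entropy <- function(stim_diam, bin_width = 0.01) {
  if (length(stim_diam) == 0L) stop("empty stimulus series")
  stopifnot(bin_width > 0)
  bin <- floor((stim_diam - min(stim_diam)) / bin_width)
  p <- tabulate(bin + 1L) / length(stim_diam)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Time to peak
#'
#' Latency from stimulus onset to the (first) peak diameter sample.
#'
#' @param stim_times stimulus-phase times (s, onset-relative).
#' @param peak_index index of the peak from [compute_pd()].
#' @return seconds.
#' @export
compute_ttp <- function(stim_times, peak_index) {
  if (peak_index < 1L || peak_index > length(stim_times)) {
    stop("peak index out of range")
  }
  stim_times[peak_index]
}

#' Peak dilation speed
#'
#' Ordinary least-squares slope of diameter (mm) against time (s) over the
#' segment from stimulus onset through the peak sample inclusive, reported as
#' the angle `atan(slope)` in radians.
#'
#' @param stim_times stimulus-phase times (s).
#' @param stim_diam stimulus-phase diameters (mm).
#' @param peak_index index of the peak from [compute_pd()].
#' @return radians in `(-pi/2, pi/2)`.
#' @export
compute_pds <- function(stim_times, stim_diam, peak_index) {
  if (peak_index < 2L) stop("slope undefined: fewer than 2 points up to peak")
  t <- stim_times[seq_len(peak_index)]
  d <- stim_diam[seq_len(peak_index)]
  n <- length(t)
  denom <- sum(t^2) - sum(t)^2 / n
  if (denom <= 0) stop("slope undefined: zero time variance")
  m <- (sum(t * d) - sum(t) * sum(d) / n) / denom
  atan(m)
}

#' Extract the seven pupillometric features from one clean trial
#'
#' @param trial a `clean_trial` from [preprocess_trial()].
#' @param config a [feature_config()].
#' @return one-row data.frame: `subject_id`, `trial_id`, `difficulty`,
#'   `BLPS`, `MPDC`, `APCPS`, `PD`, `E_pupil`, `TTP`, `PDS`.
#' @export
extract_features <- function(trial, config = feature_config()) {
  stopifnot(inherits(trial, "clean_trial"))
  blps <- compute_blps(trial$pre_diam)
  mpdc <- compute_mpdc(trial$stim_diam, blps)
  apcps <- compute_apcps(compute_pcps(trial$stim_diam, blps))
  pd <- compute_pd(trial$stim_diam, blps)
  ep <- compute_entropy(trial$stim_diam, config$entropy_bin_width)
  ttp <- compute_ttp(trial$stim_times, pd$peak_index)
  pds <- if (pd$peak_index >= 2L) {
    compute_pds(trial$stim_times, trial$stim_diam, pd$peak_index)
  } else 0
  data.frame(subject_id = trial$subject_id, trial_id = trial$trial_id,
             difficulty = trial$difficulty,
             BLPS = blps, MPDC = mpdc, APCPS = apcps, PD = pd$pd,
             E_pupil = ep, TTP = ttp, PDS = pds,
             stringsAsFactors = FALSE)
}

#' Feature matrix for a list of clean trials
#'
#' @param trials list of `clean_trial` objects (the `trials` element of
#'   [preprocess_dataset()]).
#' @param config a [feature_config()].
#' @return data.frame, one row per trial, columns as in [extract_features()].
#' @export
extract_feature_table <- function(trials, config = feature_config()) {
  stopifnot(length(trials) > 0L)
  do.call(rbind, lapply(trials, extract_features, config = config))
}
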