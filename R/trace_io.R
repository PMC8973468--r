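DIFFICULTY_LEVELS <- c("low", "medium", "high")

TRACE_COLUMNS <- c("subject_id", "trial_id", "difficulty", "time_s",
                   "left_mm", "right_mm", "valid")

#' Construct a pupil-trace dataset
#'
#' A `pupil_dataset` is a long-format table of pupil-diameter samples, one row
#' per timestamped binocular measurement. Rows belonging to the same
#' `(subject_id, trial_id)` pair form one digit-span trial. Times are in
#' seconds relative to stimulus onset, so the 2 s prestimulus fixation phase
#' carries negative times; diameters are in millimetres, with `NA` for a
#' missing eye.
#'
#' @param samples data.frame with columns `subject_id`, `trial_id`,
#'   `difficulty` (one of `"low"`, `"medium"`, `"high"`), `time_s`, `left_mm`,
#'   `right_mm`, `valid` (logical).
#' @param validate if `TRUE` (default), check the dataset invariants.
#' @return An object of class `pupil_dataset` (a data.frame).
#' @export
pupil_dataset <- function(samples, validate = TRUE) {
  stopifnot(is.data.frame(samples))
  missing_cols <- setdiff(TRACE_COLUMNS, names(samples))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  samples <- as.data.frame(samples)[, TRACE_COLUMNS]
  samples$subject_id <- as.character(samples$subject_id)
  samples$trial_id <- as.character(samples$trial_id)
  samples$difficulty <- as.character(samples$difficulty)
  samples$time_s <- as.numeric(samples$time_s)
  samples$left_mm <- as.numeric(samples$left_mm)
  samples$right_mm <- as.numeric(samples$right_mm)
  samples$valid <- as.logical(samples$valid)
  rownames(samples) <- NULL
  x <- structure(samples, class = c("pupil_dataset", "data.frame"))
  if (validate) validate_pupil_dataset(x)
  x
}

#' Validate a pupil dataset
#'
#' Checks the structural invariants: known difficulty labels, one label per
#' trial, strictly increasing times within each trial, strictly positive
#' diameters where present, and at least one prestimulus plus three stimulus
#' samples per trial.
#'
#' @param x a `pupil_dataset`.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_pupil_dataset <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  bad <- !(x$difficulty %in% DIFFICULTY_LEVELS)
  if (any(bad)) {
    stop("unknown difficulty label(s): ",
         paste(unique(x$difficulty[bad]), collapse = ", "))
  }
  if (any(x$left_mm <= 0, na.rm = TRUE) || any(x$right_mm <= 0, na.rm = TRUE)) {
    stop("pupil diameters must be strictly positive where present")
  }
  key <- paste(x$subject_id, x$trial_id, sep = "\r")
  for (idx in split(seq_len(nrow(x)), key)) {
    tr <- x[idx, ]
    id <- sprintf("subject %s trial %s", tr$subject_id[1L], tr$trial_id[1L])
    if (length(unique(tr$difficulty)) != 1L) {
      stop(id, ": more than one difficulty label")
    }
    if (is.unsorted(tr$time_s, strictly = TRUE)) {
      stop(id, ": sample times not strictly increasing")
    }
    if (!any(tr$time_s < 0)) stop(id, ": no prestimulus samples")
    if (sum(tr$time_s >= 0) < 3L) stop(id, ": fewer than 3 stimulus samples")
  }
  invisible(x)
}

#' Split a dataset into per-trial data frames
#'
#' @param x a `pupil_dataset`.
#' @return Named list of data.frames, one per `(subject_id, trial_id)` pair,
#'   in order of first appearance.
#' @export
dataset_trials <- function(x) {
  key <- paste(x$subject_id, x$trial_id, sep = "\r")
  split(as.data.frame(x), factor(key, levels = unique(key)))
}

#' @export
print.pupil_dataset <- function(x, ...) {
  key <- unique(paste(x$subject_id, x$trial_id, sep = "\r"))
  cat(sprintf("<pupil_dataset> %d samples, %d trials, %d subjects\n",
              nrow(x), length(key), length(unique(x$subject_id))))
  if (nrow(x) > 0L) {
    cat("difficulty counts (trials):\n")
    first <- x[!duplicated(paste(x$subject_id, x$trial_id, sep = "\r")), ]
    print(table(factor(first$difficulty, levels = DIFFICULTY_LEVELS)))
  }
  invisible(x)
}

#' Plot mean pupil traces by difficulty
#'
#' Interpolates every trial onto a common time grid (binocular mean of valid
#' samples) and draws the per-difficulty average trace.
#'
#' @param x a `pupil_dataset`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pupil_dataset <- function(x, ...) {
  grid <- seq(min(x$time_s), max(x$time_s), length.out = 200L)
  d <- merge_eyes(x$left_mm, x$right_mm)
  curves <- sapply(DIFFICULTY_LEVELS, function(lev) {
    sel <- x$difficulty == lev & x$valid & !is.na(d)
    if (!any(sel)) return(rep(NA_real_, length(grid)))
    stats::approx(x$time_s[sel][order(x$time_s[sel])],
                  d[sel][order(x$time_s[sel])], xout = grid,
                  ties = mean, rule = 2)$y
  })
  graphics::matplot(grid, curves, type = "l", lty = 1, col = c(3, 4, 2),
                    xlab = "time from stimulus onset (s)",
                    ylab = "pupil diameter (mm)", ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topleft", legend = DIFFICULTY_LEVELS,
                   col = c(3, 4, 2), lty = 1, bty = "n")
  invisible(x)
}

#' Read pupil trials from a delimited text file
#'
#' Expects the comma-delimited long format written by [write_trials()]:
#' header `subject_id,trial_id,difficulty,time_s,left_mm,right_mm,valid`,
#' one row per sample, empty cells for missing diameters.
#'
#' @param path file to read.
#' @param sep field delimiter (default comma).
#' @return A [pupil_dataset()].
#' @export
read_trials <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- suppressWarnings(utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = c(subject_id = "character",
                                          trial_id = "character",
                                          difficulty = "character",
                                          time_s = "character",
                                          left_mm = "character",
                                          right_mm = "character",
                                          valid = "character"),
                           na.strings = "", quote = "\"",
                           stringsAsFactors = FALSE))
  missing_cols <- setdiff(TRACE_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("header lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  parse_num <- function(col, name) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(out))
    if (length(bad) > 0L) {
      stop(sprintf("line %d: malformed %s value '%s'",
                   bad[1L] + 1L, name, col[bad[1L]]))
    }
    out
  }
  raw$time_s <- parse_num(raw$time_s, "time_s")
  raw$left_mm <- parse_num(raw$left_mm, "left_mm")
  raw$right_mm <- parse_num(raw$right_mm, "right_mm")
  v <- toupper(trimws(raw$valid))
  bad <- which(!v %in% c("TRUE", "FALSE", "T", "F", "1", "0"))
  if (length(bad) > 0L) {
    stop(sprintf("line %d: malformed valid flag '%s'",
                 bad[1L] + 1L, raw$valid[bad[1L]]))
  }
  raw$valid <- v %in% c("TRUE", "T", "1")
  pupil_dataset(raw)
}

#' Write pupil trials to a delimited text file
#'
#' Lossless long-format export: numerics are written with 17 significant
#' digits so that [read_trials()] recovers the dataset bit-for-bit.
#'
#' @param dataset a `pupil_dataset`.
#' @param path output file.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path, sep = ",") {
  validate_pupil_dataset(dataset)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- data.frame(subject_id = dataset$subject_id,
                    trial_id = dataset$trial_id,
                    difficulty = dataset$difficulty,
                    time_s = fmt(dataset$time_s),
                    left_mm = fmt(dataset$left_mm),
                    right_mm = fmt(dataset$right_mm),
                    valid = ifelse(dataset$valid, "TRUE", "FALSE"),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
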