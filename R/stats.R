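#' Fit the per-feature linear mixed model
#'
#' Model: feature ~ difficulty + (difficulty | subject), i.e. a fixed
#' difficulty effect with random subject intercepts and random subject-level
#' (per-difficulty) effects. When the random-slope fit is singular — common
#' with a 3-level factor and modest subject counts — the model is simplified
#' to a random intercept and the simplification is recorded.
#'
#' @param data data.frame with the response column, `difficulty` and
#'   `subject_id`.
#' @param response name of the feature column to model.
#' @param random `"slope"` (default: intercept + difficulty random effects,
#'   with automatic downgrade) or `"intercept"`.
#' @param REML fit by REML (default `TRUE`); likelihood-ratio tests refit by ML.
#' @return list of class `pupil_lmm`: `fit` (lmerMod), `response`, `random`
#'   (structure actually used), `simplified` (logical), `data`.
#' @export
fit_lmm <- function(data, response, random = c("slope", "intercept"),
                    REML = TRUE) {
  random <- match.arg(random)
  if (!response %in% names(data)) stop("unknown response column: ", response)
  stopifnot(all(c("difficulty", "subject_id") %in% names(data)))
  data <- data.frame(y = data[[response]],
                     difficulty = factor(data$difficulty,
                                         levels = DIFFICULTY_LEVELS),
                     subject_id = factor(data$subject_id))
  if (any(table(data$difficulty) == 0L)) {
    stop("all three difficulty levels must be present")
  }
  if (nlevels(data$subject_id) < 2L) stop("at least 2 subjects required")
  per_subj <- table(data$subject_id,
                    data$difficulty)
  if (any(rowSums(per_subj > 0) < 2L)) {
    stop("every subject must be observed at >= 2 difficulty levels")
  }
  simplified <- FALSE
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  if (random == "slope") {
    fit <- lme4::lmer(y ~ difficulty + (difficulty | subject_id),
                      data = data, REML = REML, control = ctrl)
    if (lme4::isSingular(fit, tol = 1e-4)) {
      simplified <- TRUE
      random <- "intercept"
    }
  }
  if (random == "intercept") {
    fit <- lme4::lmer(y ~ difficulty + (1 | subject_id),
                      data = data, REML = REML, control = ctrl)
  }
  structure(list(fit = fit, response = response, random = random,
                 simplified = simplified, data = data),
            class = "pupil_lmm")
}

#' @export
print.pupil_lmm <- function(x, ...) {
  cat(sprintf("<pupil_lmm> response %s, random %s%s\n", x$response, x$random,
              if (x$simplified) " (downgraded from slope: singular fit)" else ""))
  print(summary(x$fit), ...)
  invisible(x)
}

#' Likelihood-ratio test for the difficulty effect
#'
#' Compares the model with the fixed difficulty effect against the one
#' without it. Both models are refit by maximum likelihood (REML
#' log-likelihoods are not comparable across fixed-effect structures); the
#' statistic is `2 * (ll_full - ll_reduced)` on 2 degrees of freedom.
#'
#' @inheritParams fit_lmm
#' @return one-row data.frame `feature`, `chi2`, `df`, `p_value`.
#' @export
lrt_difficulty <- function(data, response, random = c("slope", "intercept")) {
  full <- fit_lmm(data, response, random = random, REML = FALSE)
  re_term <- if (full$random == "slope") "(difficulty | subject_id)" else
    "(1 | subject_id)"
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  reduced <- lme4::lmer(as.formula(paste("y ~ 1 +", re_term)),
                        data = full$data, REML = FALSE, control = ctrl)
  chi2 <- max(0, 2 * (as.numeric(logLik(full$fit)) -
                        as.numeric(logLik(reduced))))
  data.frame(feature = response, chi2 = chi2, df = 2L,
             p_value = pchisq(chi2, df = 2L, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Pairwise difficulty contrasts ("Tukey-style")
#'
#' Estimates the three level differences (medium-low, high-low, high-medium)
#' of the estimated marginal means with a multivariate-t family adjustment —
#' the mixed-model analogue of a Tukey HSD test (exact studentized-range
#' theory does not apply to LMMs).
#'
#' @param model a `pupil_lmm` from [fit_lmm()].
#' @return data.frame `feature`, `contrast`, `estimate`, `std_error`,
#'   `adjusted_p`, always three rows satisfying
#'   `high-low == (high-medium) + (medium-low)` exactly.
#' @export
pairwise_contrasts <- function(model) {
  stopifnot(inherits(model, "pupil_lmm"))
  emm <- emmeans::emmeans(model$fit, "difficulty", lmer.df = "asymptotic")
  prs <- summary(emmeans::contrast(emm, method = "revpairwise"),
                 adjust = "mvt", infer = c(FALSE, TRUE))
  out <- data.frame(feature = model$response,
                    contrast = gsub(" ", "", prs$contrast),
                    estimate = prs$estimate,
                    std_error = prs$SE,
                    adjusted_p = prs$p.value,
                    stringsAsFactors = FALSE)
  order_wanted <- c("medium-low", "high-low", "high-medium")
  out[match(order_wanted, out$contrast), , drop = FALSE]
}

#' Influence screening by standardized conditional residuals
#'
#' Flags observations whose absolute standardized (Pearson-scaled) conditional
#' residual exceeds `threshold` (default 3 residual SDs), for refitting the
#' "final model" without them.
#'
#' @param model a `pupil_lmm`.
#' @param threshold absolute standardized-residual cutoff.
#' @return list with `flagged` (integer row indices into the model data) and
#'   `retained` (the model data without the flagged rows).
#' @export
influence_screen <- function(model, threshold = 3.0) {
  stopifnot(inherits(model, "pupil_lmm"), threshold > 0)
  r <- resid(model$fit, scaled = TRUE)
  flagged <- which(abs(r) > threshold)
  list(flagged = flagged,
       retained = model$data[setdiff(seq_len(nrow(model$data)), flagged), ,
                             drop = FALSE])
}

#' Mixed-model analysis of every feature
#'
#' For each feature column: REML fit (random slope with automatic downgrade),
#' ML likelihood-ratio test of the difficulty effect, pairwise contrasts, then
#' influence screening (default 3 SD) and a re-analysis of the retained data
#' ("final" stage).
#'
#' @param features feature table from [extract_feature_table()].
#' @param feature_names columns to analyse (default the seven features).
#' @param random random-effect structure request, see [fit_lmm()].
#' @param influence_threshold standardized-residual cutoff for the screen.
#' @return object of class `pupil_feature_analysis`: `lrt` (one row per
#'   feature and stage), `contrasts` (three rows per feature and stage),
#'   `n_flagged` (named count of screened observations per feature),
#'   `simplified` (features whose random slope was dropped).
#' @export
run_feature_analysis <- function(features, feature_names = FEATURE_NAMES,
                                 random = c("slope", "intercept"),
                                 influence_threshold = 3.0) {
  random <- match.arg(random)
  stopifnot(length(unique(features$difficulty)) == 3L)
  lrt <- list(); ctr <- list(); nflag <- integer(0); simplified <- character(0)
  for (f in feature_names) {
    m0 <- fit_lmm(features, f, random = random)
    if (m0$simplified) simplified <- c(simplified, f)
    l0 <- lrt_difficulty(features, f, random = random)
    c0 <- pairwise_contrasts(m0)
    scr <- influence_screen(m0, influence_threshold)
    nflag[f] <- length(scr$flagged)
    kept <- scr$retained
    names(kept)[names(kept) == "y"] <- f
    l1 <- lrt_difficulty(kept, f, random = random)
    c1 <- pairwise_contrasts(fit_lmm(kept, f, random = random))
    l0$stage <- "initial"; l1$stage <- "final"
    c0$stage <- "initial"; c1$stage <- "final"
    lrt[[f]] <- rbind(l0, l1)
    ctr[[f]] <- rbind(c0, c1)
  }
  structure(list(lrt = do.call(rbind, c(lrt, make.row.names = FALSE)),
                 contrasts = do.call(rbind, c(ctr, make.row.names = FALSE)),
                 n_flagged = nflag, simplified = simplified,
                 influence_threshold = influence_threshold),
            class = "pupil_feature_analysis")
}

#' @export
print.pupil_feature_analysis <- function(x, ...) {
  cat("Likelihood-ratio tests for the difficulty effect (initial stage)\n")
  ini <- x$lrt[x$lrt$stage == "initial", c("feature", "chi2", "df", "p_value")]
  ini$chi2 <- round(ini$chi2, 2)
  ini$p_value <- signif(ini$p_value, 3)
  print(ini, row.names = FALSE)
  cat(sprintf("\nInfluence screen (>%g SD): %s\n", x$influence_threshold,
              paste(sprintf("%s=%d", names(x$n_flagged), x$n_flagged),
                    collapse = " ")))
  if (length(x$simplified) > 0L) {
    cat("random slope dropped (singular) for:",
        paste(x$simplified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.pupil_feature_analysis <- function(object, ...) {
  print(object)
  cat("\nPairwise contrasts (multivariate-t adjusted)\n")
  ct <- object$contrasts
  ct$estimate <- signif(ct$estimate, 4)
  ct$std_error <- signif(ct$std_error, 3)
  ct$adjusted_p <- signif(ct$adjusted_p, 3)
  print(ct, row.names = FALSE)
  invisible(object)
}
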