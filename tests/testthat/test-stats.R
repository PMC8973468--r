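test_that("null data give grand-mean fixed effects and near-zero level effects", {
  d <- make_lmm_data(n_subjects = 12L, trials_per_level = 6L,
                     offsets = c(low = 0, medium = 0, high = 0),
                     mu = 4, subject_sd = 0, sigma = 0.01, seed = 2L)
  m <- fit_lmm(d, "y")
  fe <- lme4::fixef(m$fit)
  expect_equal(unname(fe[1]), 4, tolerance = 0.01)
  expect_lt(max(abs(fe[-1])), 0.02)
})

test_that("model preconditions are enforced", {
  d <- make_lmm_data(n_subjects = 1L, trials_per_level = 6L)
  expect_error(fit_lmm(d, "y"), "2 subjects")
  d <- make_lmm_data(n_subjects = 6L)
  expect_error(fit_lmm(d[d$difficulty != "high", ], "y"), "three difficulty")
  expect_error(fit_lmm(d, "nope"), "nope")
})

test_that("known level offsets are recovered within 3 standard errors", {
  d <- make_lmm_data(offsets = c(low = 0, medium = 0.1, high = 0.3),
                     sigma = 0.01, seed = 7L)
  m <- fit_lmm(d, "y")
  ct <- pairwise_contrasts(m)
  expect_equal(ct$contrast, c("medium-low", "high-low", "high-medium"))
  truth <- c(0.1, 0.3, 0.2)
  expect_true(all(abs(ct$estimate - truth) <= 3 * ct$std_error))
  # exact linear identity of the three contrasts
  expect_equal(ct$estimate[ct$contrast == "high-low"],
               ct$estimate[ct$contrast == "high-medium"] +
                 ct$estimate[ct$contrast == "medium-low"])
})

test_that("contrast estimates agree with direct computation from the fixed effects", {
  d <- make_lmm_data(seed = 11L)
  m <- fit_lmm(d, "y", random = "intercept")
  ct <- pairwise_contrasts(m)
  fe <- lme4::fixef(m$fit)        # (intercept, medium-low, high-low)
  V <- as.matrix(vcov(m$fit))
  hand <- c(fe[["difficultymedium"]], fe[["difficultyhigh"]],
            fe[["difficultyhigh"]] - fe[["difficultymedium"]])
  expect_equal(ct$estimate, unname(hand), tolerance = 1e-8)
  L <- rbind(c(0, 1, 0), c(0, 0, 1), c(0, -1, 1))
  hand_se <- sqrt(diag(L %*% V %*% t(L)))
  expect_equal(ct$std_error, unname(hand_se), tolerance = 1e-8)
})

test_that("the likelihood-ratio test has 2 df and matches a manual ML refit", {
  d <- make_lmm_data(seed = 3L)
  out <- lrt_difficulty(d, "y", random = "intercept")
  expect_equal(out$df, 2L)
  expect_gte(out$chi2, 0)
  # manual dual-route check with plain lmer calls
  dd <- data.frame(y = d$y, difficulty = factor(d$difficulty,
                                                levels = c("low", "medium", "high")),
                   subject_id = d$subject_id)
  full <- lme4::lmer(y ~ difficulty + (1 | subject_id), dd, REML = FALSE)
  red <- lme4::lmer(y ~ 1 + (1 | subject_id), dd, REML = FALSE)
  chi2 <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
  expect_equal(out$chi2, chi2, tolerance = 1e-6)
  expect_equal(out$p_value, pchisq(chi2, 2, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("the LRT statistic is invariant to affine rescaling of the response", {
  d <- make_lmm_data(seed = 13L)
  a <- lrt_difficulty(d, "y", random = "intercept")
  d$y <- 1000 * d$y + 5
  b <- lrt_difficulty(d, "y", random = "intercept")
  expect_equal(a$chi2, b$chi2, tolerance = 1e-4)
})

test_that("a null response is non-significant and a strong effect is detected", {
  null_d <- make_lmm_data(offsets = c(low = 0, medium = 0, high = 0),
                          sigma = 0.1, seed = 5L)
  expect_gt(lrt_difficulty(null_d, "y", random = "intercept")$p_value, 0.01)
  eff_d <- make_lmm_data(offsets = c(low = 0, medium = 0.1, high = 0.3),
                         sigma = 0.05, seed = 5L)
  expect_lt(lrt_difficulty(eff_d, "y")$p_value, 1e-6)
})

test_that("permuted labels are almost never significant at the 0.001 level", {
  d <- make_lmm_data(n_subjects = 12L, trials_per_level = 8L,
                     offsets = c(low = 0, medium = 0.1, high = 0.3),
                     sigma = 0.05, seed = 19L)
  set.seed(101)
  hits <- 0L
  for (i in 1:20) {
    perm <- d
    perm$difficulty <- sample(perm$difficulty)
    p <- lrt_difficulty(perm, "y", random = "intercept")$p_value
    hits <- hits + (p < 0.001)
  }
  expect_lte(hits, 2L)
})

test_that("influence screening flags gross outliers and nothing at infinity", {
  d <- make_lmm_data(sigma = 0.05, seed = 23L)
  m <- fit_lmm(d, "y", random = "intercept")
  scr_inf <- influence_screen(m, threshold = Inf)
  expect_length(scr_inf$flagged, 0L)
  # inject a 10-SD outlier
  d2 <- d
  d2$y[100] <- d2$y[100] + 10 * 0.05
  m2 <- fit_lmm(d2, "y", random = "intercept")
  scr <- influence_screen(m2, threshold = 3)
  expect_true(100 %in% scr$flagged)
  # clean gaussian data: roughly the normal tail mass (well under 2%)
  expect_lt(length(influence_screen(m, 3)$flagged) / nrow(d), 0.02)
  expect_equal(nrow(scr$retained) + length(scr$flagged), nrow(d2))
})

test_that("the per-feature analysis reports every feature at both stages", {
  cfg <- generator_config(n_subjects = 8L, trials_per_level = 6L,
                          sampling_rate = 5, seed = 31L)
  ft <- extract_feature_table(preprocess_dataset(simulate_dataset(cfg))$trials)
  an <- run_feature_analysis(ft)
  expect_s3_class(an, "pupil_feature_analysis")
  expect_equal(nrow(an$lrt), 7L * 2L)
  expect_equal(nrow(an$contrasts), 21L * 2L)
  expect_setequal(unique(an$lrt$stage), c("initial", "final"))
  expect_true(all(an$lrt$chi2 >= 0))
  expect_true(all(an$lrt$p_value >= 0 & an$lrt$p_value <= 1))
  # three contrasts per feature per stage, satisfying the linear identity
  for (f in unique(an$contrasts$feature)) {
    for (st in c("initial", "final")) {
      cc <- an$contrasts[an$contrasts$feature == f & an$contrasts$stage == st, ]
      expect_equal(nrow(cc), 3L)
      expect_equal(cc$estimate[cc$contrast == "high-low"],
                   cc$estimate[cc$contrast == "high-medium"] +
                     cc$estimate[cc$contrast == "medium-low"],
                   tolerance = 1e-10)
    }
  }
  expect_output(print(an), "Likelihood-ratio tests")
  # generated difficulty effects are dilating: medium-low and high-low
  # contrasts come out positive for every amplitude-driven feature
  ini <- an$contrasts[an$contrasts$stage == "initial" &
                        an$contrasts$contrast %in% c("medium-low", "high-low") &
                        an$contrasts$feature %in%
                          c("MPDC", "APCPS", "PD", "E_pupil", "TTP"), ]
  expect_true(all(ini$estimate > 0))
})
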