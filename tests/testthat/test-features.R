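# hand oracles for the seven per-trial features, then composite and
# property-style checks on generated trials

test_that("baseline is the prestimulus mean", {
  expect_equal(compute_blps(c(4, 4, 4)), 4)
  expect_equal(compute_blps(c(3.9, 4.1)), 4.0)
  expect_error(compute_blps(numeric(0)), "empty")
})

test_that("mean pupil diameter change subtracts the baseline", {
  expect_equal(compute_mpdc(rep(4, 5), 4), 0)
  expect_equal(compute_mpdc(c(4.2, 4.4, 4.6), 4.0), 0.4)
  expect_equal(compute_mpdc(3.8, 4.0), -0.2)  # constriction is negative
  expect_error(compute_mpdc(numeric(0), 4), "empty")
})

test_that("percentage change is relative to the baseline", {
  expect_equal(compute_pcps(4.4, 4.0), 0.1)
  expect_equal(compute_pcps(rep(4, 3), 4), rep(0, 3))
  expect_equal(compute_pcps(2.0, 4.0), -0.5)
  expect_error(compute_pcps(4, 0), "positive")
  expect_error(compute_pcps(4, -1), "positive")
})

test_that("average percentage change is the mean of the series", {
  expect_equal(compute_apcps(rep(0, 4)), 0)
  expect_equal(compute_apcps(c(0.1, 0.3)), 0.2)
  expect_equal(compute_apcps(0.37), 0.37)
  expect_error(compute_apcps(numeric(0)), "empty")
})

test_that("peak dilation takes the first maximum minus baseline", {
  out <- compute_pd(c(4.0, 4.5, 4.3), 4.0)
  expect_equal(out$pd, 0.5)
  expect_equal(out$ppd, 4.5)
  expect_equal(out$peak_index, 2L)
  expect_equal(compute_pd(rep(4, 3), 4)$pd, 0)
  expect_equal(compute_pd(c(4.5, 4.5), 4)$peak_index, 1L)  # first-occurrence tie
  expect_error(compute_pd(numeric(0), 4), "empty")
})

test_that("pupil-size entropy matches direct summation over bin frequencies", {
  expect_equal(compute_entropy(rep(4.001, 5), 0.01), 0)        # one bin
  expect_equal(compute_entropy(c(4.00, 4.00, 4.05, 4.05), 0.01), 1)  # 2 equal bins
  # 10 samples, frequencies {5, 3, 2}
  x <- c(rep(4.000, 5), rep(4.030, 3), rep(4.070, 2))
  oracle <- -(0.5 * log2(0.5) + 0.3 * log2(0.3) + 0.2 * log2(0.2))
  expect_equal(compute_entropy(x, 0.01), oracle)
  expect_equal(oracle, 1.4854752972273344, tolerance = 1e-12)
  expect_error(compute_entropy(4, 0), "bin_width")
})

test_that("time to peak looks up the onset-relative peak time", {
  expect_equal(compute_ttp(c(0, 0.5, 1.0), 1L), 0)
  expect_equal(compute_ttp(c(0, 0.5, 1.0), 3L), 1.0)
  expect_error(compute_ttp(c(0, 0.5), 5L), "out of range")
})

test_that("peak dilation speed is the arctangent of the OLS slope to the peak", {
  expect_equal(compute_pds(0:2, c(4, 4, 4.0001), 2L), 0, tolerance = 1e-3)
  expect_equal(compute_pds(c(0, 1, 2), c(4.0, 4.1, 4.2), 3L), atan(0.1))
  expect_equal(atan(0.1), 0.09966865249116204, tolerance = 1e-15)
  expect_equal(compute_pds(c(0, 1), c(4, 5), 2L), pi / 4)
  expect_error(compute_pds(0:2, c(4, 4, 4), 1L), "fewer than 2")
  # negative slope comes out negative
  expect_lt(compute_pds(c(0, 1, 2), c(4.4, 4.2, 4.0), 3L), 0)
})

test_that("a constant trace at baseline yields the all-zero feature vector", {
  ct <- make_clean_trial(pre_diam = c(4, 4), stim_times = 0:5,
                         stim_diam = rep(4, 6))
  fv <- extract_features(ct)
  expect_equal(fv$MPDC, 0)
  expect_equal(fv$APCPS, 0)
  expect_equal(fv$PD, 0)
  expect_equal(fv$E_pupil, 0)
  expect_equal(fv$PDS, 0)
  expect_equal(fv$TTP, 0)   # peak tie resolved to the first sample
})

test_that("an 8-sample hand-built trial matches the per-feature oracles", {
  ct <- make_clean_trial(pre_diam = c(4.0, 4.2),
                         stim_times = 0:5,
                         stim_diam = c(4.1, 4.3, 4.5, 4.4, 4.2, 4.1))
  fv <- extract_features(ct)
  expect_equal(fv$BLPS, 4.1)
  expect_equal(fv$MPDC, mean(c(4.1, 4.3, 4.5, 4.4, 4.2, 4.1)) - 4.1)
  expect_equal(fv$APCPS, fv$MPDC / 4.1)
  expect_equal(fv$PD, 0.4)
  expect_equal(fv$TTP, 2)
  expect_equal(fv$PDS, atan(0.2))  # OLS on (0,4.1),(1,4.3),(2,4.5)
  # bins of width 0.01 anchored at 4.1: counts {2,1,1,1,1}
  expect_equal(fv$E_pupil,
               -(2 / 6 * log2(2 / 6) + 4 * (1 / 6 * log2(1 / 6))))
  expect_equal(fv$difficulty, "low")
})

test_that("feature invariants hold across generated trials", {
  cfg <- small_generator(seed = 21L, blink_prob = 0.03)
  pp <- preprocess_dataset(simulate_dataset(cfg))
  ft <- extract_feature_table(pp$trials)
  expect_equal(nrow(ft), length(pp$trials))
  # algebraic identity APCPS * BLPS == MPDC
  expect_equal(ft$APCPS * ft$BLPS, ft$MPDC, tolerance = 1e-12)
  # the max deviation dominates the mean deviation
  expect_true(all(ft$PD >= ft$MPDC))
  expect_true(all(ft$E_pupil >= 0))
  last_t <- vapply(pp$trials, function(ct) max(ct$stim_times), numeric(1))
  expect_true(all(ft$TTP >= 0 & ft$TTP <= last_t))
})

test_that("features are time-shift invariant except TTP, which shifts", {
  ct <- make_clean_trial()
  shifted <- ct
  shifted$stim_times <- ct$stim_times + 0.75
  shifted$pre_times <- ct$pre_times + 0.75
  f0 <- extract_features(ct)
  f1 <- extract_features(shifted)
  for (f in c("BLPS", "MPDC", "APCPS", "PD", "E_pupil", "PDS")) {
    expect_equal(f1[[f]], f0[[f]], info = f)
  }
  expect_equal(f1$TTP, f0$TTP + 0.75)
})

test_that("scaling diameters scales MPDC and PD, leaves APCPS unchanged", {
  ct <- make_clean_trial()
  scaled <- ct
  scaled$pre_diam <- ct$pre_diam * 1.7
  scaled$stim_diam <- ct$stim_diam * 1.7
  f0 <- extract_features(ct)
  f1 <- extract_features(scaled)
  expect_equal(f1$MPDC, 1.7 * f0$MPDC)
  expect_equal(f1$PD, 1.7 * f0$PD)
  expect_equal(f1$BLPS, 1.7 * f0$BLPS)
  expect_equal(f1$APCPS, f0$APCPS)
})
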