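test_that("per-leaf RMS errors recover injected deviations", {
  # perfect tracking -> all zeros
  fracs <- seq(0, 1, by = 0.05)
  rec0 <- toy_record(fracs, planned_a = 10 * fracs)
  s0 <- rms_leaf_errors(rec0)
  expect_equal(max(s0$per_leaf_rms), 0)
  expect_equal(s0$max_rms, 0)
  # constant 0.5 mm offset on every bank-A leaf
  rec1 <- toy_record(fracs, planned_a = 10 * fracs,
                     recorded_a = 10 * fracs - 0.5)
  s1 <- rms_leaf_errors(rec1)
  expect_equal(unname(s1$per_leaf_rms[, "A"]), rep(0.5, 60))
  expect_equal(unname(s1$per_leaf_rms[, "B"]), rep(0, 60))
  expect_equal(s1$max_rms, 0.5)
  # beam-hold snapshots are excluded
  rec2 <- toy_record(fracs, planned_a = 10 * fracs,
                     recorded_a = 10 * fracs - 0.5,
                     beam_on = c(FALSE, rep(TRUE, length(fracs) - 1)))
  expect_equal(rms_leaf_errors(rec2)$max_rms, 0.5)
  rec3 <- toy_record(c(0, 1), planned_a = c(0, 1),
                     beam_on = c(FALSE, FALSE))
  expect_error(rms_leaf_errors(rec3), "beam-on")
})

test_that("zero-mean jitter converges to its SD in RMS over many snapshots", {
  # ~10^4 snapshots: 5500 MU at 600 MU/min (0.55 MU per 55 ms step); all
  # pairs wide open so the closed-pair collision interlock never clips jitter
  beam <- static_beam(xa = -50, xb = 50, open_pairs = 1:60, total_mu = 5500)
  rec <- simulate_delivery(beam, seed = 101,
                           error_model = delivery_error_model(jitter_sd_mm = 0.3))
  s <- rms_leaf_errors(rec)
  # recorded = planned + jitter + 0.01 cm quantization:
  # E[RMS] = sqrt(0.3^2 + 0.1^2/12) = 0.3014
  expect_equal(mean(s$per_leaf_rms), 0.3014, tolerance = 0.01 / 0.3014)
  expect_lte(max(abs(s$per_leaf_rms - 0.3014)), 0.015)
})

test_that("Pearson correlation behaves on exact and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 5)), "variance")
  expect_error(pearson_correlation(x, 1:4), "equal-length")
  # pairing matters: a shuffle of one column destroys the correlation
  tab <- validation_ratios()
  paired <- pearson_correlation(tab$dcalc_ratio, tab$dmeas_ratio)$r
  shuffled <- pearson_correlation(tab$dcalc_ratio,
                                  tab$dmeas_ratio[c(3, 8, 1, 10, 6, 2, 9, 4, 7, 5)])$r
  expect_gt(paired, 0.99)
  expect_lt(shuffled, paired)
})

test_that("the confidence limit follows |mean| + 1.96 sd with sample SD", {
  expect_equal(confidence_limit(c(1, -1)), 1.96 * sqrt(2))
  expect_equal(confidence_limit(rep(0, 10)), 0)
  d <- c(0.3, -0.2, 0.1, 0.4, -0.5)
  expect_equal(confidence_limit(d), abs(mean(d)) + 1.96 * sd(d))
  # negating all differences leaves the statistic unchanged
  expect_equal(confidence_limit(-d), confidence_limit(d))
  expect_error(confidence_limit(1), ">= 2")
})

test_that("plan comparisons flag strictly beyond the action level", {
  audit <- clinical_dvh_audit()
  hn1 <- audit[audit$case == "H&N#1", ]
  cmp <- compare_plans(
    list(d98 = hn1$d98_orig, d2 = hn1$d2_orig, dmean = hn1$dmean_orig),
    list(d98 = hn1$d98_recon, d2 = hn1$d2_recon, dmean = hn1$dmean_recon))
  expect_equal(unname(cmp$diffs), c(-0.1, -0.1, 0.0))
  expect_equal(cmp$verdict, "pass")
  # boundary case: a difference of exactly the action level passes
  lung3 <- audit[audit$case == "Lung#3", ]
  cmp3 <- compare_plans(
    list(d98 = lung3$d98_orig, d2 = lung3$d2_orig, dmean = lung3$dmean_orig),
    list(d98 = lung3$d98_recon, d2 = lung3$d2_recon, dmean = lung3$dmean_recon))
  expect_equal(unname(cmp3$diffs["d98"]), 1.0)
  expect_equal(cmp3$verdict, "pass")
  m <- list(d98 = 95, d2 = 104, dmean = 100)
  expect_equal(unname(compare_plans(m, m)$diffs), c(0, 0, 0))
  expect_equal(compare_plans(m, list(d98 = 95, d2 = 105.1, dmean = 100))$verdict,
               "flag")
})

test_that("bundled audit fixtures are complete and internally consistent", {
  tab <- validation_ratios()
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$dcalc_ratio > 0 & tab$dmeas_ratio > 0))
  audit <- clinical_dvh_audit()
  expect_equal(nrow(audit), 20)
  expect_equal(sort(unique(audit$site)),
               c("breast", "head_neck", "lung", "prostate"))
  diffs <- audit_differences(audit)
  expect_equal(nrow(diffs), 60)
  # per-case D98 <= Dmean <= D2 in both columns
  expect_true(all(audit$d98_orig <= audit$dmean_orig &
                    audit$dmean_orig <= audit$d2_orig))
  expect_true(all(audit$d98_recon <= audit$dmean_recon &
                    audit$dmean_recon <= audit$d2_recon))
})
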