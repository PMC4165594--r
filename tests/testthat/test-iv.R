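mk_stage <- function(coef, se, n = 500, r2 = NA, stage = "second") {
  lipidmr:::stage_estimate(coefficient = coef, se = se, n = n,
                           p_value = 2 * pnorm(-abs(coef / se)), stage = stage,
                           r_squared = r2, df = c(1, n - 2))
}

test_that("a noise-free unit instrument returns the second stage unchanged", {
  st1 <- mk_stage(1, 0, r2 = 0.5, stage = "first")
  st2 <- mk_stage(0.3, 0.1)
  iv <- ratio_iv(st2, st1)
  expect_equal(iv$log_or_per_unit, 0.3)
  expect_equal(iv$se, 0.1)
  expect_true(iv$gate_passed)
})

test_that("delta-method SE matches hand evaluation and Monte-Carlo propagation", {
  iv <- ratio_iv(mk_stage(0.1, 0.05), mk_stage(0.2, 0.04, r2 = 0.04, stage = "first"))
  expect_equal(iv$log_or_per_unit, 0.5)
  expect_equal(iv$se, sqrt(0.0625 + 0.01), tolerance = 1e-10)

  # MC propagation, 1e6 draws, se1/b1 = 0.1 < 0.2 regime
  withr::with_seed(99, {
    b1 <- 1; se1 <- 0.1; b2 <- 0.2; se2 <- 0.05
    draws <- rnorm(1e6, b2, se2) / rnorm(1e6, b1, se1)
    mc_sd <- sd(draws)
  })
  delta <- ratio_iv(mk_stage(0.2, 0.05), mk_stage(1, 0.1, r2 = 0.1, stage = "first"))
  expect_lt(abs(delta$se - mc_sd) / mc_sd, 0.02)
})

test_that("weak instruments error out or fail the gate", {
  expect_error(ratio_iv(mk_stage(0.1, 0.05),
                        mk_stage(1e-10, 0.04, r2 = 0.001, stage = "first")),
               "weak-instrument")
  iv <- ratio_iv(mk_stage(0.1, 0.05), mk_stage(0.05, 0.04, r2 = 0.005, stage = "first"))
  expect_false(iv$gate_passed)
})

test_that("method selection gates on first-stage R^2 with inclusive threshold", {
  expect_equal(select_iv_method(mk_stage(0.2, 0.04, r2 = 0.0419, stage = "first")), "ratio")
  expect_equal(select_iv_method(mk_stage(0.2, 0.04, r2 = 0.005, stage = "first")), "ivw")
  expect_equal(select_iv_method(mk_stage(0.2, 0.04, r2 = 0.015, stage = "first")), "ratio")
})

test_that("IVW closed forms: single SNP, symmetry, WLS and meta identities", {
  one <- ivw_summary(
    data.frame(snp_id = "a", log_or = 0.06, se = 0.02),
    data.frame(snp_id = "a", effect_on_trait = 0.1, se_beta = 0.01))
  expect_equal(one$log_or_per_unit, 0.6)
  expect_equal(one$se, 0.02 / 0.1)

  sym <- ivw_summary(
    data.frame(snp_id = c("a", "b"), log_or = c(0.02, -0.02), se = c(0.05, 0.05)),
    data.frame(snp_id = c("a", "b"), effect_on_trait = c(0.1, 0.1), se_beta = 0.01))
  expect_equal(sym$log_or_per_unit, 0, tolerance = 1e-14)

  withr::with_seed(17, {
    k <- 40
    b1 <- runif(k, 0.02, 0.2)
    se2 <- runif(k, 0.02, 0.1)
    b2 <- 0.2 * b1 + rnorm(k, sd = se2)
    sd_df <- data.frame(snp_id = paste0("s", 1:k), log_or = b2, se = se2)
    tr_df <- data.frame(snp_id = paste0("s", 1:k), effect_on_trait = b1,
                        se_beta = 0.01)
    ivw <- ivw_summary(sd_df, tr_df)
    # within 2 SE of the generating slope
    expect_lt(abs(ivw$log_or_per_unit - 0.2), 2 * ivw$se)
    # identical to weighted least squares through the origin
    wls <- lm(b2 ~ 0 + b1, weights = 1 / se2^2)
    expect_equal(ivw$log_or_per_unit, unname(coef(wls)), tolerance = 1e-10)
    # identical to fixed-effects pooling of per-SNP ratios
    fe <- meta_fixed(b2 / b1, se2 / abs(b1))
    expect_equal(ivw$log_or_per_unit, fe$pooled_log_estimate, tolerance = 1e-10)
    expect_equal(ivw$se, fe$se, tolerance = 1e-10)
    # scaling all trait effects by c scales the estimate by 1/c
    tr2 <- tr_df; tr2$effect_on_trait <- tr2$effect_on_trait * 3
    expect_equal(ivw_summary(sd_df, tr2)$log_or_per_unit,
                 ivw$log_or_per_unit / 3, tolerance = 1e-12)
  })
})

test_that("IVW rejects empty overlap and mismatched orientation", {
  expect_error(ivw_summary(
    data.frame(snp_id = "a", log_or = 0.1, se = 0.05),
    data.frame(snp_id = "b", effect_on_trait = 0.1, se_beta = 0.01)),
    "overlap")
  expect_error(ivw_summary(
    data.frame(snp_id = "a", log_or = 0.1, se = 0.05,
               risk_allele = "A", other_allele = "G"),
    data.frame(snp_id = "a", effect_on_trait = 0.1, se_beta = 0.01,
               risk_allele = "G", other_allele = "A")),
    "orientation mismatch")
})

test_that("simulated causal effect is recovered by the ratio estimator", {
  # moderate-n spot check of estimator consistency (the full 200-replicate
  # recovery suite lives in the acceptance tests)
  ivs <- vapply(1:20, function(i) ratio_iv_replicate(0.25, seed = 4000 + i)$log_or_per_unit,
                numeric(1))
  expect_lt(abs(median(ivs) - 0.25), 0.15)
})
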