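raw_weights_fixture <- function() {
  data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    trait = c("LDL", "LDL", "HDL"),
    risk_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    beta = c(-0.1, 0.2, 0.2),   # rs1 needs flipping; rs3 raises HDL -> flip
    se_beta = c(0.01, 0.01, 0.02),
    stringsAsFactors = FALSE)
}

test_that("orientation flips alleles to the risk-raising (HDL-lowering) convention", {
  w <- orient_weights(raw_weights_fixture())
  expect_true(all(w$beta > 0))
  # LDL row with negative beta: alleles swapped, weight positive
  expect_equal(w$risk_allele[w$snp_id == "rs1"], "G")
  expect_equal(w$other_allele[w$snp_id == "rs1"], "A")
  expect_equal(w$beta[w$snp_id == "rs1"], 0.1)
  expect_equal(w$effect_on_trait[w$snp_id == "rs1"], 0.1)
  # already-consistent LDL row untouched
  expect_equal(w$risk_allele[w$snp_id == "rs2"], "C")
  # HDL row oriented to the HDL-lowering allele with positive weight
  expect_equal(w$risk_allele[w$snp_id == "rs3"], "A")
  expect_equal(w$beta[w$snp_id == "rs3"], 0.2)
  expect_lt(w$effect_on_trait[w$snp_id == "rs3"], 0)
  # idempotence
  expect_identical(orient_weights(w), w)
})

test_that("orientation rejects undefined and duplicated rows", {
  bad <- raw_weights_fixture(); bad$beta[2] <- 0
  expect_error(orient_weights(bad), "zero effect")
  dup <- rbind(raw_weights_fixture(), raw_weights_fixture()[1, ])
  expect_error(orient_weights(dup), "duplicate")
})

test_that("raw score is the weighted dosage sum per non-missing SNP", {
  w <- orient_weights(data.frame(
    snp_id = c("s1", "s2"), trait = "TC",
    risk_allele = c("A", "A"), other_allele = c("G", "G"),
    beta = c(0.5, 0.5), se_beta = 0.01, stringsAsFactors = FALSE))

  d1 <- matrix(2, 1, 1, dimnames = list("i1", "s1"))
  expect_warning(g1 <- compute_grs(d1, w, "TC", max_missing = 1),
                 "absent")  # s2 not in matrix
  expect_equal(g1$raw, 1.0)  # 0.5*2 / 1 non-missing

  d2 <- matrix(c(2, NA), 1, 2, dimnames = list("i1", c("s1", "s2")))
  g2 <- compute_grs(d2, w, "TC", max_missing = 1)
  expect_equal(g2$raw, 1.0)
  expect_equal(g2$n_missing, 1L)
})

test_that("individuals missing >= 5% of a score's SNPs are excluded", {
  p <- 20
  w <- orient_weights(data.frame(
    snp_id = paste0("s", 1:p), trait = "TC", risk_allele = "A",
    other_allele = "G", beta = 0.1, se_beta = 0.01, stringsAsFactors = FALSE))
  D <- matrix(1, 3, p, dimnames = list(c("full", "miss1", "miss2"),
                                       paste0("s", 1:p)))
  D["miss1", 1] <- NA      # 1/20 = 5% -> excluded (inclusive threshold)
  D["miss2", 1:2] <- NA    # 10% -> excluded
  g <- compute_grs(D, w, "TC")
  expect_equal(g$excluded, c(FALSE, TRUE, TRUE))
  expect_true(all(is.na(g$standardized[g$excluded])))
})

test_that("scoring matches a direct loop oracle on complete data", {
  withr::with_seed(2, {
    D <- matrix(sample(0:2, 15, replace = TRUE), 5, 3,
                dimnames = list(paste0("i", 1:5), c("a", "b", "c")))
    w <- orient_weights(data.frame(
      snp_id = c("a", "b", "c"), trait = "TC", risk_allele = "A",
      other_allele = "G", beta = c(0.2, 0.5, 0.9), se_beta = 0.01,
      stringsAsFactors = FALSE))
    g <- compute_grs(D, w, "TC")
    oracle <- vapply(1:5, function(i) sum(D[i, ] * c(0.2, 0.5, 0.9)) / 3,
                     numeric(1))
    expect_equal(g$raw, oracle, tolerance = 1e-14)
  })
})

test_that("standardization is exact, permutation-invariant and scale-stable", {
  withr::with_seed(3, {
    p <- 10; n <- 80
    D <- matrix(sample(0:2, n * p, replace = TRUE), n, p,
                dimnames = list(sprintf("i%02d", 1:n), paste0("s", 1:p)))
    w <- orient_weights(data.frame(
      snp_id = paste0("s", 1:p), trait = "HDL", risk_allele = "A",
      other_allele = "G", beta = runif(p, 0.05, 0.3), se_beta = 0.01,
      stringsAsFactors = FALSE))
    g <- compute_grs(D, w, "HDL")
    incl <- !g$excluded
    expect_lt(abs(mean(g$standardized[incl])), 1e-10)
    expect_lt(abs(sd(g$standardized[incl]) - 1), 1e-10)

    # column permutation leaves scores unchanged
    perm <- sample(p)
    g_perm <- compute_grs(D[, perm], w, "HDL")
    expect_equal(g_perm$raw, g$raw, tolerance = 1e-14)

    # doubling betas doubles raw scores, standardized unchanged
    w2 <- w; w2$beta <- w$beta * 2
    g2 <- compute_grs(D, w2, "HDL")
    expect_equal(g2$raw, 2 * g$raw, tolerance = 1e-12)
    expect_equal(g2$standardized, g$standardized, tolerance = 1e-12)
  })
})

test_that("PLINK-style allele-suffixed columns are matched and flipped", {
  w <- orient_weights(data.frame(
    snp_id = c("rs10", "rs20"), trait = "TC", risk_allele = c("A", "C"),
    other_allele = c("G", "T"), beta = c(0.4, 0.4), se_beta = 0.01,
    stringsAsFactors = FALSE))
  # rs20 counted on the other allele T -> dosage must be flipped to 2-d
  D <- matrix(c(1, 2,
                0, 2), 2, 2, byrow = FALSE,
              dimnames = list(c("i1", "i2"), c("rs10_A", "rs20_T")))
  g <- compute_grs(D, w, "TC")
  expect_equal(g$raw, c((0.4 * 1 + 0.4 * 2) / 2, (0.4 * 2 + 0.4 * 0) / 2))
  # allele that matches neither listed allele is an error
  colnames(D) <- c("rs10_A", "rs20_G")
  expect_error(compute_grs(D, w, "TC"), "allele mismatch")
})
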