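test_that("simulated weights reproduce the study's SNP set structure", {
  cfg <- sim_config(seed = 11)
  w <- simulate_weights(cfg)

  counts_full <- table(w$trait)
  expect_equal(unname(c(counts_full[c("HDL", "LDL", "TG", "TC")])),
               c(69, 55, 40, 70), ignore_attr = TRUE)
  counts_spec <- table(w$trait[w$trait_specific])
  expect_equal(unname(counts_spec[c("HDL", "LDL", "TG", "TC")]),
               c(45, 9, 16, 18), ignore_attr = TRUE)

  # trait-specific SNPs appear for exactly one trait
  spec_ids <- w$snp_id[w$trait_specific]
  expect_true(all(table(w$snp_id[w$snp_id %in% spec_ids]) == 1))
  # shared (non-specific) SNPs create overlap between full sets
  shared_ids <- unique(w$snp_id[!w$trait_specific])
  expect_true(all(table(w$snp_id)[shared_ids] >= 2))

  expect_true(all(w$beta > 0))
  expect_true(all(w$maf > 0.01 & w$maf <= 0.5))
  expect_true(all(w$effect_on_trait[w$trait == "HDL"] < 0))
  expect_true(all(w$effect_on_trait[w$trait != "HDL"] > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_snps_specific = c(HDL = 80, LDL = 9, TG = 16, TC = 18)),
               "trait-specific")
  expect_error(sim_config(missing_rate = 0.2), "missing_rate")
  expect_error(sim_config(maf_range = c(0.001, 0.5)), "maf_range")
  expect_error(sim_config(base_prevalence = 1.2), "base_prevalence")
})

test_that("fixed seed gives identical output; different seeds differ", {
  cfg1 <- sim_config(traits = "TC", n_snps_full = c(TC = 8),
                     n_snps_specific = c(TC = 2), trait_r2_target = c(TC = 0.04),
                     cohort_sizes = list(a = c(cases = 60, controls = 60, population = 0)),
                     lipid_cohort = 1, n_mci = 0, lipid_subset_fraction = 1,
                     seed = 5)
  w1 <- simulate_weights(cfg1); w2 <- simulate_weights(cfg1)
  expect_identical(w1, w2)
  s1 <- simulate_cohorts(cfg1, w1); s2 <- simulate_cohorts(cfg1, w1)
  expect_identical(s1$cohorts, s2$cohorts)

  cfg2 <- cfg1; cfg2$seed <- 6L
  w3 <- simulate_weights(cfg2)
  expect_false(isTRUE(all.equal(w1$beta, w3$beta)))
})

test_that("null genetic architecture produces constant raw scores", {
  cfg <- sim_config(traits = "TC", n_snps_full = c(TC = 6),
                    n_snps_specific = c(TC = 2), trait_r2_target = c(TC = 0.04),
                    cohort_sizes = list(a = c(cases = 40, controls = 40, population = 0)),
                    lipid_cohort = 1, n_mci = 0, lipid_subset_fraction = 1,
                    missing_rate = 0, seed = 3)
  w <- simulate_weights(cfg)
  w$beta <- rep(0.2, nrow(w))  # equal weights
  w$effect_on_trait <- rep(0, nrow(w))  # no genetic effect on the trait
  sim <- simulate_cohorts(cfg, w)
  g <- compute_grs(sim$cohorts[[1]]$dosages, w, "TC", "full")
  st <- first_stage(sim$cohorts[[1]]$phenotypes$latent_TC, g)
  # score varies (dosages do) but carries no trait signal
  expect_lt(st$r_squared, 0.08)
})

test_that("dosage means and realized first-stage R^2 match the generating model", {
  # large unconditional sample: population controls only
  cfg <- sim_config(traits = "TC", n_snps_full = c(TC = 12),
                    n_snps_specific = c(TC = 3), trait_r2_target = c(TC = 0.04),
                    cohort_sizes = list(a = c(cases = 30, controls = 30, population = 50000)),
                    lipid_cohort = 1, n_mci = 0, lipid_subset_fraction = 0,
                    missing_rate = 0, seed = 21)
  w <- simulate_weights(cfg)
  sim <- simulate_cohorts(cfg, w)
  co <- sim$cohorts[[1]]
  pop <- co$phenotypes$status == "population"
  X <- co$dosages[pop, ]
  n <- sum(pop)

  # binomial closed form: mean dosage = 2*maf +/- 3 SE
  maf <- w$maf[match(colnames(X), w$snp_id)]
  se <- sqrt(2 * maf * (1 - maf) / n)
  expect_true(all(abs(colMeans(X) - 2 * maf) < 3 * se + 1e-12))

  # regression of the latent trait on the true-weight score
  score <- as.vector(X %*% sim$truth$snp_effects[colnames(X), "TC"])
  r2 <- summary(lm(co$phenotypes$latent_TC[pop] ~ score))$r.squared
  expect_lt(abs(r2 - 0.04), 0.01)
  expect_lt(abs(sim$truth$realized_r2[["TC"]] - 0.04), 0.015)
})

test_that("under the causal null, per-SNP disease associations centre on zero", {
  # 500 disjoint SNPs across traits, no causal or pleiotropic effects
  cfg <- sim_config(traits = c("HDL", "LDL"),
                    n_snps_full = c(HDL = 250, LDL = 250),
                    n_snps_specific = c(HDL = 250, LDL = 250),
                    trait_r2_target = c(HDL = 0.1, LDL = 0.1),
                    causal_log_or_per_unit = 0,
                    cohort_sizes = list(a = c(cases = 700, controls = 700, population = 0)),
                    lipid_cohort = 1, n_mci = 0, lipid_subset_fraction = 0,
                    missing_rate = 0, seed = 31)
  w <- simulate_weights(cfg)
  sim <- simulate_cohorts(cfg, w)
  co <- sim$cohorts[[1]]
  scan <- per_snp_associations(co$phenotypes$status, co$dosages)
  z <- scan$log_or / scan$se
  expect_true(all(!scan$failed))
  # mean z over 500 independent null SNPs ~ N(0, 1/sqrt(500))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)) + 0.05)
  # ~5% nominal significance (binomial 99.7% band)
  prop <- mean(scan$p_value < 0.05)
  expect_lt(abs(prop - 0.05), 3 * sqrt(0.05 * 0.95 / length(z)))
})

test_that("simulated study round-trips through the plain-text writers", {
  cfg <- sim_config(traits = "TC", n_snps_full = c(TC = 5),
                    n_snps_specific = c(TC = 2), trait_r2_target = c(TC = 0.04),
                    cohort_sizes = list(a = c(cases = 25, controls = 25, population = 0)),
                    lipid_cohort = 1, n_mci = 0, lipid_subset_fraction = 1,
                    missing_rate = 0.03, seed = 9)
  w <- simulate_weights(cfg)
  sim <- simulate_cohorts(cfg, w)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  m <- read_dosages_raw(file.path(dir, "a.raw"))
  expect_equal(dim(m), dim(sim$cohorts[[1]]$dosages))
  expect_equal(unname(m), unname(sim$cohorts[[1]]$dosages), ignore_attr = TRUE)
  w2 <- read_weights_csv(file.path(dir, "weights.csv"))
  expect_equal(w2$snp_id, w$snp_id)
  expect_equal(w2$beta, w$beta, tolerance = 1e-12)
  # scoring from the re-read files matches scoring in memory
  g_mem <- compute_grs(sim$cohorts[[1]]$dosages, w, "TC", "full")
  g_file <- compute_grs(m, w2, "TC", "full")
  expect_equal(g_file$raw, g_mem$raw, tolerance = 1e-12)
})
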