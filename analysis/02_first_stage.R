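#!/usr/bin/env Rscript
# Step 2: instrument strength.
#
# Prepares the lipid outcomes in the lipid-measured cohort (mmol/l -> mg/dl,
# residualization on age, age^2, sex, rank inverse-normal transform) and
# fits the first-stage trait ~ GRS regressions for every trait and SNP set.
# The R^2 decides, per trait and set, whether individual-level ratio IV
# estimation is justified (gate: R^2 >= 1.5%) or only summary-data IVW.

suppressPackageStartupMessages(library(lipidmr))

sim <- readRDS("scratch/sim.rds")
cfg <- sim$config
lip <- sim$cohorts[[cfg$lipid_cohort]]
ph <- convert_units(lip$phenotypes)

rows <- list()
for (t in cfg$traits) {
  trans <- residualize_inverse_normal(ph[[paste0("lipid_", t)]], ph$age, ph$sex)
  for (s in c("full", "specific")) {
    g <- compute_grs(lip$dosages, sim$weights, t, s)
    st <- first_stage(trans, g)
    rows[[paste(t, s)]] <- data.frame(
      trait = t, set = s, n = st$n, beta = round(st$coefficient, 3),
      se = round(st$se, 3), r_squared_pct = round(100 * st$r_squared, 2),
      f_statistic = round(st$f_statistic, 1), p_value = signif(st$p_value, 3),
      gate = select_iv_method(st))
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/first_stage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("First-stage instrument strength (lipid-measured subset incl. MCI):\n\n")
print(tab, row.names = FALSE)
cat("\nTraits/sets gated to 'ratio' use individual-level IV; 'ivw' fall back",
    "\nto summary statistics. Written to results/first_stage.tsv.\n")
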