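#!/usr/bin/env Rscript
# Step 3: the full Mendelian-randomization analysis.
#
# Runs the end-to-end pipeline on the simulated study: GRS per cohort,
# second-stage logistic GRS-disease fits (4 PCs; batch in the lipid cohort;
# population controls coded as controls), per-cohort ratio-IV estimates with
# delta-method SEs, summary-data IVW estimates from per-SNP scans, and
# fixed-effects meta-analysis across the three cohorts with I^2. Because the
# study was simulated under the causal null, the pooled IV confidence
# intervals are expected to cover OR = 1.

suppressPackageStartupMessages(library(lipidmr))

sim <- readRDS("scratch/sim.rds")
run <- run_mr_pipeline(sim, out_dir = "results/pipeline")
print(run)
cat("\nTables written under results/pipeline/ (first_stage.tsv, grs_load.tsv,",
    "\niv.tsv, meta.tsv, summary.json).\n")

covered <- with(run$meta[run$meta$headline, ], ci_low <= 1 & 1 <= ci_high)
cat(sprintf("\n%d of %d headline pooled IV intervals cover OR = 1 (truth: null).\n",
            sum(covered), length(covered)))
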