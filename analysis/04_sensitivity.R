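#!/usr/bin/env Rscript
# Step 4: sensitivity analysis excluding population controls.
#
# Population controls (unscreened, some below the disease's onset age) could
# dilute or distort the second stage. Re-runs the pipeline with them dropped
# from the disease models; first-stage estimates are untouched by
# construction. Compares the pooled headline estimates of the two runs.

suppressPackageStartupMessages(library(lipidmr))

sim <- readRDS("scratch/sim.rds")
main <- run_mr_pipeline(sim, compute_ivw = FALSE)
sens <- run_mr_pipeline(sim, include_population_controls = FALSE,
                        compute_ivw = FALSE,
                        out_dir = "results/pipeline_no_popctrl")

stopifnot(identical(main$first_stage, sens$first_stage))
cmp <- merge(main$meta[main$meta$method == "ratio",
                       c("trait", "set", "or", "ci_low", "ci_high")],
             sens$meta[sens$meta$method == "ratio",
                       c("trait", "set", "or", "ci_low", "ci_high")],
             by = c("trait", "set"), suffixes = c("_all", "_no_pop"))
cmp[, -(1:2)] <- round(cmp[, -(1:2)], 3)
write.table(cmp, "results/sensitivity_popctrl.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Pooled ratio-IV ORs with and without population controls:\n\n")
print(cmp, row.names = FALSE)
cat("\nFirst-stage estimates are identical across the two runs (checked).\n")
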