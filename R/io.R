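#' Write a dosage matrix as a PLINK-.raw-style TSV
#'
#' Columns are `FID`, `IID`, then one column per SNP named `rsID_riskallele`
#' with dosages 0/1/2 (or fractional) and `NA` for missing.
#'
#' @param dosages individuals x SNPs matrix, row names = IID, column names =
#'   SNP ids.
#' @param weights oriented weights table supplying each SNP's risk allele.
#' @param path output file.
#' @export
write_dosages_raw <- function(dosages, weights, path) {
  allele <- weights$risk_allele[match(colnames(dosages),
                                      weights$snp_id)]
  cn <- ifelse(is.na(allele), colnames(dosages),
               paste0(colnames(dosages), "_", allele))
  df <- data.frame(FID = rownames(dosages), IID = rownames(dosages),
                   dosages, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("FID", "IID", cn)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PLINK-.raw-style TSV dosage file
#'
#' @param path file written by [write_dosages_raw()] or PLINK `--recode A`.
#' @return numeric matrix (individuals x SNPs) with IID row names; column
#'   names keep the `rsID_allele` form so downstream scoring can check the
#'   counted allele.
#' @export
read_dosages_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  drop <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    names(df))
  m <- as.matrix(df[, setdiff(names(df), drop), drop = FALSE])
  rownames(m) <- df$IID
  storage.mode(m) <- "double"
  m
}

#' Write / read a weights table as CSV
#' @param weights oriented weights table.
#' @param path file path.
#' @export
write_weights_csv <- function(weights, path) {
  utils::write.csv(as.data.frame(weights), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(w, "oriented") <- "effect_on_trait" %in% names(w)
  class(w) <- c("weights_table", "data.frame")
  w
}

#' Write a simulated study to disk
#'
#' Per cohort: a `<name>.raw` dosage TSV and `<name>_pheno.tsv`; plus
#' `weights.csv` and a `truth.txt` key-value sidecar recording the generative
#' parameters.
#'
#' @param sim a [simulate_cohorts()] result.
#' @param dir output directory (created if needed).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (co in sim$cohorts) {
    write_dosages_raw(co$dosages, sim$weights,
                      file.path(dir, paste0(co$name, ".raw")))
    utils::write.table(co$phenotypes,
                       file.path(dir, paste0(co$name, "_pheno.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_weights_csv(sim$weights, file.path(dir, "weights.csv"))
  tr <- sim$truth
  lines <- c(
    paste0("causal_log_or_per_unit.", names(tr$causal_log_or_per_unit), "=",
           tr$causal_log_or_per_unit),
    paste0("realized_r2.", names(tr$realized_r2), "=",
           signif(tr$realized_r2, 6)),
    paste0("seed=", sim$config$seed))
  writeLines(lines, file.path(dir, "truth.txt"))
  invisible(dir)
}
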