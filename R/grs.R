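#' Orient a weights table to the risk-allele convention
#'
#' The "risk" allele is the one that raises LDL-c, TC and TG and lowers
#' HDL-c. Rows whose effect-allele sign is inconsistent with that convention
#' have their alleles swapped and the effect negated. The returned table
#' stores `beta` as the positive scoring weight and `effect_on_trait` as the
#' signed per-risk-allele effect on the trait (negative for HDL rows), and
#' carries attribute `oriented = TRUE`; re-orienting an oriented table is a
#' no-op.
#'
#' @param raw_weights data frame with columns `snp_id`, `trait` (HDL / LDL /
#'   TC / TG), `risk_allele` (the effect allele of the incoming table),
#'   `other_allele`, `beta` (signed effect of that allele on the trait) and
#'   `se_beta`; optionally `trait_specific`, `excluded`, `maf`.
#' @return oriented `weights_table`.
#' @export
orient_weights <- function(raw_weights) {
  if (isTRUE(attr(raw_weights, "oriented"))) return(raw_weights)
  w <- as.data.frame(raw_weights)
  if (anyDuplicated(w[, c("snp_id", "trait")]))
    stop("duplicate (snp_id, trait) rows in weights table", call. = FALSE)
  if (any(w$beta == 0))
    stop("zero effect size: risk direction undefined for ",
         paste(w$snp_id[w$beta == 0], collapse = ", "), call. = FALSE)
  # desired sign of the risk-allele effect on each trait
  desired <- ifelse(w$trait == "HDL", -1, 1)
  flip <- sign(w$beta) != desired
  tmp <- w$risk_allele[flip]
  w$risk_allele[flip] <- w$other_allele[flip]
  w$other_allele[flip] <- tmp
  w$effect_on_trait <- ifelse(flip, -w$beta, w$beta)
  w$beta <- abs(w$beta)
  if (is.null(w$trait_specific)) w$trait_specific <- FALSE
  if (is.null(w$excluded)) w$excluded <- FALSE
  attr(w, "oriented") <- TRUE
  class(w) <- c("weights_table", "data.frame")
  w
}

# Align a dosage matrix to a weight set: match columns by snp_id (PLINK
# .raw-style "rsID_ALLELE" names are understood), flip dosages counted on the
# other allele, and pad SNPs absent from the matrix with all-missing columns.
align_dosages <- function(dosages, wt) {
  cn <- colnames(dosages)
  snp_of_col <- sub("_[ACGT]$", "", cn)
  allele_of_col <- ifelse(grepl("_[ACGT]$", cn), sub("^.*_", "", cn), NA)
  out <- matrix(NA_real_, nrow(dosages), nrow(wt),
                dimnames = list(rownames(dosages), wt$snp_id))
  absent <- character(0)
  for (j in seq_len(nrow(wt))) {
    hit <- which(snp_of_col == wt$snp_id[j])
    if (length(hit) == 0) { absent <- c(absent, wt$snp_id[j]); next }
    d <- dosages[, hit[1]]
    a <- allele_of_col[hit[1]]
    if (!is.na(a) && a != wt$risk_allele[j]) {
      if (a != wt$other_allele[j])
        stop("allele mismatch for ", wt$snp_id[j], ": dosage counted on '", a,
             "' but weights list ", wt$risk_allele[j], "/", wt$other_allele[j],
             call. = FALSE)
      d <- 2 - d
    }
    out[, j] <- d
  }
  if (length(absent) > 0)
    warning("SNPs absent from dosage matrix, treated as missing for all ",
            "individuals: ", paste(absent, collapse = ", "), call. = FALSE)
  out
}

#' Compute a weighted genotype risk score
#'
#' The raw score of an individual is the weighted sum of risk-allele dosages
#' over the SNPs of the chosen set, divided by that individual's number of
#' non-missing SNPs (a score per non-missing SNP). Individuals missing at
#' least `max_missing` of the set's SNPs are flagged `excluded` and receive
#' no standardized score; standardization (mean 0, SD 1) is computed within
#' the cohort over included individuals only.
#'
#' @param dosages numeric matrix, individuals x SNPs, risk-allele counts in
#'   [0, 2] (fractional imputed dosages allowed) with `NA` for missing;
#'   columns named by SNP id, optionally PLINK-style `rsID_ALLELE` (dosages
#'   counted on the other allele are flipped).
#' @param weights oriented `weights_table` (see [orient_weights()]).
#' @param trait which lipid trait's score to build.
#' @param set `"full"` (all SNPs for the trait) or `"specific"` (SNPs
#'   exclusively associated with it).
#' @param max_missing exclusion threshold on the missing-SNP fraction
#'   (inclusive; default 0.05).
#' @return data frame of class `"grs_vector"`: `iid`, `raw`, `standardized`,
#'   `n_missing`, `excluded`.
#' @export
compute_grs <- function(dosages, weights, trait, set = c("full", "specific"),
                        max_missing = 0.05) {
  set <- match.arg(set)
  if (!isTRUE(attr(weights, "oriented")))
    stop("weights must be oriented first (see orient_weights())", call. = FALSE)
  wt <- weights[weights$trait == trait & !weights$excluded, , drop = FALSE]
  if (set == "specific") wt <- wt[wt$trait_specific, , drop = FALSE]
  if (nrow(wt) == 0) stop("no SNPs for trait ", trait, " (set ", set, ")",
                          call. = FALSE)
  D <- align_dosages(dosages, wt)
  if (any(D < 0 | D > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  p <- nrow(wt)
  non_missing <- rowSums(!is.na(D))
  n_missing <- p - non_missing
  wsum <- as.vector((ifelse(is.na(D), 0, D)) %*% wt$beta)
  raw <- ifelse(non_missing > 0, wsum / non_missing, NA_real_)
  excluded <- (n_missing / p) >= max_missing | non_missing == 0
  std <- rep(NA_real_, length(raw))
  incl <- which(!excluded)
  if (length(incl) > 1) {
    mu <- mean(raw[incl]); sdv <- stats::sd(raw[incl])
    if (sdv > 0) std[incl] <- (raw[incl] - mu) / sdv
  }
  out <- data.frame(iid = rownames(dosages) %||% as.character(seq_along(raw)),
                    raw = raw, standardized = std,
                    n_missing = n_missing, excluded = excluded,
                    stringsAsFactors = FALSE)
  class(out) <- c("grs_vector", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
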