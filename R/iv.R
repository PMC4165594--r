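#' Instrumental-variable estimate container
#' @keywords internal
iv_estimate <- function(log_or, se, method, first_stage_r2 = NA_real_,
                        gate_passed = NA, n_snps = NA_integer_,
                        per_snp = NULL) {
  structure(list(log_or_per_unit = log_or, se = se,
                 or = exp(log_or),
                 ci = exp(log_or + c(-1, 1) * 1.96 * se),
                 p_value = 2 * stats::pnorm(-abs(log_or / se)),
                 method = method, first_stage_r2 = first_stage_r2,
                 gate_passed = gate_passed, n_snps = n_snps,
                 per_snp = per_snp),
            class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat(sprintf("IV estimate (%s): OR %.3f (95%% CI %.2f-%.2f) per trait unit\n",
              x$method, x$or, x$ci[1], x$ci[2]))
  cat(sprintf("  log OR %.4f (SE %.4f), p = %.3g\n", x$log_or_per_unit, x$se,
              x$p_value))
  if (!is.na(x$first_stage_r2))
    cat(sprintf("  first-stage R^2 = %.4f (gate %s)\n", x$first_stage_r2,
                if (isTRUE(x$gate_passed)) "passed" else "NOT passed"))
  invisible(x)
}

#' Ratio (Wald) instrumental-variable estimator with delta-method SE
#'
#' Divides the second-stage log OR per GRS SD by the first-stage slope
#' (trait units per GRS SD), giving the causal disease log OR per 1 unit of
#' the trait. The standard error propagates uncertainty from both stages by
#' the first-order delta method, treating the stages as independent (the
#' first stage comes from a distinct subsample):
#' `se^2 = se2^2/b1^2 + b2^2 se1^2 / b1^4`.
#'
#' @param stage2 second-stage `stage_estimate` (log OR per GRS SD).
#' @param stage1 first-stage `stage_estimate` (trait units per GRS SD).
#' @param gate_threshold first-stage R-squared below which the instrument is
#'   flagged weak (`gate_passed = FALSE`); inclusive, default 0.015.
#' @return `iv_estimate` with `method = "ratio"`.
#' @export
ratio_iv <- function(stage2, stage1, gate_threshold = 0.015) {
  b1 <- stage1$coefficient; se1 <- stage1$se
  b2 <- stage2$coefficient; se2 <- stage2$se
  if (abs(b1) < 1e-8)
    stop("weak-instrument error: first-stage coefficient is numerically zero",
         call. = FALSE)
  log_or <- b2 / b1
  se <- sqrt(se2^2 / b1^2 + b2^2 * se1^2 / b1^4)
  iv_estimate(log_or, se, method = "ratio",
              first_stage_r2 = stage1$r_squared,
              gate_passed = !is.na(stage1$r_squared) &&
                stage1$r_squared >= gate_threshold)
}

#' Summary-data IVW instrumental-variable estimator
#'
#' Combines per-SNP disease log ORs with external per-SNP trait effects in an
#' inverse-variance weighted meta-analysis of the per-SNP ratio estimates:
#' `log_or = sum(b1 b2 / se2^2) / sum(b1^2 / se2^2)`,
#' `se = 1 / sqrt(sum(b1^2 / se2^2))` (first-order; the trait-effect SEs are
#' ignored, as is standard). Per-SNP ratio estimates `b2/b1` with SE
#' `se2/|b1|` are returned for diagnostics.
#'
#' @param snp_disease data frame from [per_snp_associations()] (columns
#'   `snp_id`, `log_or`, `se`; failed SNPs are dropped with a message).
#' @param snp_trait oriented weights rows for one trait: columns `snp_id`,
#'   `effect_on_trait` (signed per-risk-allele trait effect), `se_beta`, and
#'   optionally alleles for an orientation check against `snp_disease`.
#' @return `iv_estimate` with `method = "ivw"`.
#' @export
ivw_summary <- function(snp_disease, snp_trait) {
  sd_ <- snp_disease[!is.na(snp_disease$log_or) & !is.na(snp_disease$se), ]
  m <- merge(sd_[, c("snp_id", "log_or", "se")],
             snp_trait[, c("snp_id", "effect_on_trait")], by = "snp_id")
  if (nrow(m) == 0)
    stop("no overlapping SNPs between disease and trait summary statistics",
         call. = FALSE)
  if (all(c("risk_allele", "other_allele") %in% names(snp_disease)) &&
      all(c("risk_allele", "other_allele") %in% names(snp_trait))) {
    a <- merge(snp_disease[, c("snp_id", "risk_allele")],
               snp_trait[, c("snp_id", "risk_allele")], by = "snp_id")
    if (any(a$risk_allele.x != a$risk_allele.y))
      stop("orientation mismatch: risk alleles differ for ",
           paste(a$snp_id[a$risk_allele.x != a$risk_allele.y], collapse = ", "),
           call. = FALSE)
  }
  b1 <- m$effect_on_trait; b2 <- m$log_or; se2 <- m$se
  w <- b1^2 / se2^2
  log_or <- sum(b1 * b2 / se2^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  per_snp <- data.frame(snp_id = m$snp_id, ratio = b2 / b1,
                        se = se2 / abs(b1), stringsAsFactors = FALSE)
  iv_estimate(log_or, se, method = "ivw", n_snps = nrow(m),
              per_snp = per_snp)
}

#' Choose the headline IV method from instrument strength
#'
#' Individual-level ratio estimation is used when the first-stage R-squared
#' is at least the gate threshold (inclusive); otherwise the summary-data
#' IVW estimator is the headline method. Both can still be computed; the tag
#' only marks which one leads.
#'
#' @param stage1 first-stage `stage_estimate`.
#' @param gate_threshold inclusive R-squared threshold, default 0.015.
#' @return `"ratio"` or `"ivw"`.
#' @export
select_iv_method <- function(stage1, gate_threshold = 0.015) {
  if (is.na(stage1$r_squared)) stop("first stage carries no R^2", call. = FALSE)
  if (stage1$r_squared >= gate_threshold) "ratio" else "ivw"
}
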