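#' Stage estimate container
#'
#' @param coefficient,se,n core estimate.
#' @param r_squared,f_statistic,df first-stage instrument-strength metadata.
#' @param p_value two-sided p.
#' @param covariates_used character vector.
#' @param stage `"first"`, `"second"` or `"per_snp"`.
#' @return list of class `"stage_estimate"`.
#' @keywords internal
stage_estimate <- function(coefficient, se, n, p_value, stage,
                           r_squared = NA_real_, f_statistic = NA_real_,
                           df = c(NA_real_, NA_real_),
                           covariates_used = character(0)) {
  structure(list(coefficient = coefficient, se = se, n = n,
                 r_squared = r_squared, f_statistic = f_statistic, df = df,
                 p_value = p_value, covariates_used = covariates_used,
                 stage = stage),
            class = "stage_estimate")
}

#' @export
print.stage_estimate <- function(x, ...) {
  cat(sprintf("Stage estimate (%s): coef %.4f (SE %.4f), n=%d, p=%.3g\n",
              x$stage, x$coefficient, x$se, x$n, x$p_value))
  if (!is.na(x$r_squared))
    cat(sprintf("  R^2 = %.4f, F(%d,%d) = %.2f\n", x$r_squared,
                x$df[1], x$df[2], x$f_statistic))
  invisible(x)
}

#' First-stage regression: lipid trait on genotype risk score
#'
#' Ordinary least squares of the (inverse-normal transformed) trait on the
#' standardized GRS, with no further covariates: the trait is residualized
#' upstream. The R-squared and F(1, n-2) statistic quantify instrument
#' strength.
#'
#' @param trait_values transformed trait (one per individual).
#' @param grs standardized score: either a numeric vector or a
#'   [compute_grs()] result (its `standardized` column is used; excluded
#'   individuals drop out as `NA`).
#' @return `stage_estimate` with slope in trait units per GRS SD.
#' @export
first_stage <- function(trait_values, grs) {
  g <- if (inherits(grs, "grs_vector")) grs$standardized else grs
  ok <- !is.na(trait_values) & !is.na(g)
  y <- trait_values[ok]; x <- g[ok]
  n <- length(y)
  if (n < 30) stop("first stage needs n >= 30 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance GRS", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients["x", ]
  r2 <- sm$r.squared
  f <- unname(sm$fstatistic[1])
  stage_estimate(coefficient = unname(co["Estimate"]),
                 se = unname(co["Std. Error"]), n = n,
                 p_value = unname(co["Pr(>|t|)"]), stage = "first",
                 r_squared = r2, f_statistic = f, df = c(1, n - 2))
}

check_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cv <- as.data.frame(covariates)
  stopifnot(nrow(cv) == n)
  mm <- stats::model.matrix(~ ., cv)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("singular covariate matrix; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cv
}

fit_logistic <- function(y, x, covariates, xname = "x") {
  df <- data.frame(y = y, x = x)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  warn <- NULL
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      warn <<- conditionMessage(w); invokeRestart("muffleWarning")
    })
  if (!fit$converged || (!is.null(warn) && grepl("fitted probabilities", warn)))
    stop("logistic fit failed to converge (possible perfect separation)",
         call. = FALSE)
  co <- summary(fit)$coefficients
  if (!"x" %in% rownames(co))
    stop("predictor dropped from logistic fit (aliased)", call. = FALSE)
  co["x", ]
}

#' Second-stage regression: disease status on genotype risk score
#'
#' Maximum-likelihood logistic regression of case/control status on the
#' standardized GRS, adjusted for the supplied covariates (typically the
#' first four ancestry principal components, plus a genotyping-batch
#' indicator where applicable). Population controls are coded as controls
#' when present; MCI individuals must be removed by the caller (they enter
#' the first stage only).
#'
#' @param status character or factor with values among `"case"`,
#'   `"control"`, `"population"` (coded as control).
#' @param grs standardized score (vector or [compute_grs()] result).
#' @param covariates optional data frame of covariates (full rank required).
#' @return `stage_estimate` with the log OR per GRS SD.
#' @export
second_stage <- function(status, grs, covariates = NULL) {
  g <- if (inherits(grs, "grs_vector")) grs$standardized else grs
  status <- as.character(status)
  if (any(status == "mci"))
    stop("MCI individuals must not enter the second stage", call. = FALSE)
  y <- ifelse(status == "case", 1L, 0L)
  ok <- !is.na(g) & !is.na(y)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  y <- y[ok]; g2 <- g[ok]
  cv <- if (is.null(covariates)) NULL else check_covariates(as.data.frame(covariates)[ok, , drop = FALSE], sum(ok))
  if (length(unique(y)) < 2)
    stop("both cases and controls are required", call. = FALSE)
  co <- fit_logistic(y, g2, cv)
  stage_estimate(coefficient = unname(co["Estimate"]),
                 se = unname(co["Std. Error"]), n = length(y),
                 p_value = unname(co["Pr(>|z|)"]), stage = "second",
                 covariates_used = if (is.null(cv)) character(0) else names(cv))
}

#' Per-SNP disease association scan
#'
#' Logistic regression of case/control status on each SNP's risk-allele
#' dosage, adjusted for covariates, yielding the summary statistics consumed
#' by the IVW estimator. SNPs whose fit fails (monomorphic, separation) are
#' flagged with `NA` estimates and a reason rather than dropped.
#'
#' @param status as in [second_stage()].
#' @param dosages individuals x SNPs risk-allele dosage matrix (`NA` allowed).
#' @param covariates optional covariate data frame.
#' @return data frame with one row per SNP: `snp_id`, `log_or`, `se`, `n`,
#'   `p_value`, `failed`, `reason`.
#' @export
per_snp_associations <- function(status, dosages, covariates = NULL) {
  status <- as.character(status)
  if (any(status == "mci"))
    stop("MCI individuals must not enter disease association fits", call. = FALSE)
  y_all <- ifelse(status == "case", 1L, 0L)
  res <- lapply(colnames(dosages), function(s) {
    d <- dosages[, s]
    ok <- !is.na(d) & !is.na(y_all)
    if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
    d2 <- d[ok]; y <- y_all[ok]
    if (length(unique(d2)) < 2)
      return(data.frame(snp_id = s, log_or = NA_real_, se = NA_real_,
                        n = length(y), p_value = NA_real_, failed = TRUE,
                        reason = "monomorphic", stringsAsFactors = FALSE))
    cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)[ok, , drop = FALSE]
    co <- tryCatch(fit_logistic(y, d2, cv), error = function(e) e)
    if (inherits(co, "error"))
      return(data.frame(snp_id = s, log_or = NA_real_, se = NA_real_,
                        n = length(y), p_value = NA_real_, failed = TRUE,
                        reason = conditionMessage(co), stringsAsFactors = FALSE))
    data.frame(snp_id = s, log_or = unname(co["Estimate"]),
               se = unname(co["Std. Error"]), n = length(y),
               p_value = unname(co["Pr(>|z|)"]), failed = FALSE, reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
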