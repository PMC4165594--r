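meta_result <- function(pooled, se, q, i2, model, k, tau2 = NA_real_) {
  structure(list(pooled_log_estimate = pooled, se = se,
                 or = exp(pooled), ci = exp(pooled + c(-1, 1) * 1.96 * se),
                 p_value = 2 * stats::pnorm(-abs(pooled / se)),
                 q_statistic = q, i_squared = i2, tau2 = tau2,
                 model = model, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effects meta-analysis (k=%d): OR %.3f (95%% CI %.2f-%.2f), p=%.3g\n",
              x$model, x$k, x$or, x$ci[1], x$ci[2], x$p_value))
  cat(sprintf("  Q = %.2f, I^2 = %.0f%%\n", x$q_statistic, x$i_squared))
  invisible(x)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools log-scale estimates with weights `1/se^2`; reports Cochran's Q and
#' `I^2 = max(0, (Q - (k-1))/Q) * 100` (truncated at zero).
#'
#' @param estimates numeric vector of log-scale estimates (log ORs).
#' @param se their standard errors (all positive).
#' @return `meta_result` with `model = "fixed"`.
#' @export
meta_fixed <- function(estimates, se) {
  k <- length(estimates)
  if (k == 0) stop("no studies to pool", call. = FALSE)
  if (length(se) != k || any(se <= 0)) stop("need one positive SE per study",
                                            call. = FALSE)
  w <- 1 / se^2
  pooled <- sum(w * estimates) / sum(w)
  pse <- 1 / sqrt(sum(w))
  q <- sum(w * (estimates - pooled)^2)
  i2 <- if (k > 1 && q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  meta_result(pooled, pse, q, i2, model = "fixed", k = k)
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Estimates the between-study variance as
#' `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effects weights `w = 1/se^2`, then pools with weights
#' `1/(se^2 + tau^2)`. Under homogeneity (`Q <= k-1`) the result equals the
#' fixed-effects pool exactly.
#'
#' @inheritParams meta_fixed
#' @return `meta_result` with `model = "random"`.
#' @export
meta_random <- function(estimates, se) {
  k <- length(estimates)
  if (k < 2) stop("random-effects pooling needs k >= 2 studies", call. = FALSE)
  if (length(se) != k || any(se <= 0)) stop("need one positive SE per study",
                                            call. = FALSE)
  w <- 1 / se^2
  fixed_pool <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - fixed_pool)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * estimates) / sum(wr)
  pse <- 1 / sqrt(sum(wr))
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  meta_result(pooled, pse, q, i2, model = "random", k = k, tau2 = tau2)
}

#' Reconstruct a log-scale SE from a printed OR and 95% CI
#'
#' Assumes the CI is symmetric on the log scale:
#' `se = (ln(upper) - ln(lower)) / (2 * 1.96)`. A warning is issued when the
#' printed OR is off the CI midpoint by more than 0.02 on the log scale
#' (rounded or internally inconsistent interval).
#'
#' @param or point estimate (odds ratio).
#' @param lower,upper 95% CI bounds, `0 < lower <= or <= upper`.
#' @return the log-scale standard error.
#' @export
se_from_ci <- function(or, lower, upper) {
  if (any(lower <= 0) || any(lower > or) || any(or > upper))
    stop("require 0 < lower <= or <= upper", call. = FALSE)
  mid <- (log(lower) + log(upper)) / 2
  off <- abs(log(or) - mid)
  if (any(off > 0.02))
    warning(sprintf("OR %.3f is not the log-midpoint of (%.3g, %.3g); CI may be rounded or asymmetric",
                    or[which.max(off)], lower[which.max(off)], upper[which.max(off)]),
            call. = FALSE)
  (log(upper) - log(lower)) / (2 * 1.96)
}
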