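#' Convert serum lipid values from mmol/l to mg/dl
#'
#' Cholesterol fractions (HDL-c, LDL-c, TC) are multiplied by 38.67 and
#' triglycerides by 88.57, the standard molar-mass conversion factors.
#'
#' @param x numeric vector of lipid values in mmol/l (strictly positive;
#'   `NA` allowed).
#' @param lipid one of `"HDL"`, `"LDL"`, `"TC"`, `"TG"`.
#' @return values in mg/dl.
#' @export
mmol_to_mgdl <- function(x, lipid = c("HDL", "LDL", "TC", "TG")) {
  lipid <- match.arg(lipid)
  if (any(x <= 0, na.rm = TRUE))
    stop("validation error: lipid values must be strictly positive", call. = FALSE)
  factor <- if (lipid == "TG") 88.57 else 38.67
  x * factor
}

#' Convert a lipid panel from mmol/l to mg/dl
#'
#' @param panel data frame with columns `lipid_HDL`, `lipid_LDL`, `lipid_TC`,
#'   `lipid_TG` (any subset) and a `lipid_unit` attribute; values strictly
#'   positive where present.
#' @return the panel with converted values and `lipid_unit` set to `"mg/dl"`.
#'   Converting a panel already in mg/dl is an error (no silent
#'   double-conversion).
#' @export
convert_units <- function(panel) {
  unit <- attr(panel, "lipid_unit")
  if (is.null(unit)) stop("panel has no lipid_unit attribute", call. = FALSE)
  if (unit == "mg/dl")
    stop("panel is already in mg/dl; refusing to convert twice", call. = FALSE)
  if (unit != "mmol/l") stop("unknown lipid unit: ", unit, call. = FALSE)
  for (t in c("HDL", "LDL", "TC", "TG")) {
    col <- paste0("lipid_", t)
    if (col %in% names(panel)) panel[[col]] <- mmol_to_mgdl(panel[[col]], t)
  }
  attr(panel, "lipid_unit") <- "mg/dl"
  panel
}

#' Rank-based inverse-normal transform (Blom offsets)
#'
#' Maps values to normal quantiles via `qnorm((rank - 3/8) / (n + 1/4))`;
#' ties receive average ranks, `NA`s are preserved.
#'
#' @param x numeric vector.
#' @return transformed vector, approximately standard normal, same order.
#' @export
rank_inverse_normal <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0)
    stop("inverse-normal transform undefined for constant input", call. = FALSE)
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 0.375) / (sum(ok) + 0.25))
  attr(out, "transformed") <- TRUE
  out
}

#' Residualize a lipid trait on age, age-squared and sex, then inverse-normal
#' transform
#'
#' The trait is regressed on `age + age^2 + sex` by ordinary least squares and
#' the residuals are rank-based inverse-normal transformed, yielding an
#' approximately standard-normal, covariate-free exposure variable for the
#' first-stage regression. Individuals with a missing trait value get `NA`;
#' age and sex must be non-missing for individuals with a trait value.
#'
#' @param values numeric trait vector (any units).
#' @param age,sex covariates (years; 0/1 coding).
#' @param residualize set `FALSE` to skip the regression and rank-transform
#'   the raw values (pure-rank mode).
#' @return transformed vector with attribute `transformed = TRUE`.
#' @export
residualize_inverse_normal <- function(values, age, sex, residualize = TRUE) {
  ok <- !is.na(values)
  if (sum(ok) < 10)
    stop("need at least 10 non-missing values", call. = FALSE)
  if (residualize) {
    if (any(is.na(age[ok])) || any(is.na(sex[ok])))
      stop("age and sex must be non-missing for measured individuals",
           call. = FALSE)
    fit <- stats::lm(values ~ age + I(age^2) + sex,
                     data = data.frame(values, age, sex), na.action = stats::na.exclude)
    res <- stats::residuals(fit)
  } else {
    res <- values
  }
  rank_inverse_normal(res)
}
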