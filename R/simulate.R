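#' Simulation configuration for multi-cohort lipid MR studies
#'
#' Builds and validates the parameter set for the synthetic-cohort generator.
#' Defaults reproduce the structure of a three-cohort late-onset Alzheimer
#' disease (LOAD) case-control study: cohort sizes 3,234/1,175/4,989 (cases /
#' screened controls / population controls), 350/313 and 330/187; a lipid
#' measured subset of roughly 550 individuals (including 127 with mild
#' cognitive impairment, MCI) inside the second cohort; full genotype risk
#' score (GRS) SNP sets of sizes 69/55/40/70 and trait-specific sets of
#' 45/9/16/18 for HDL/LDL/TG/TC; and first-stage variance-explained targets
#' matching the full-score instrument strengths observed in such data
#' (roughly 1.8--4.3%).
#'
#' @param traits character vector of lipid traits simulated.
#' @param n_snps_full named integer vector, SNPs in each full score.
#' @param n_snps_specific named integer vector, SNPs exclusively associated
#'   with each trait (trait-specific score); must not exceed `n_snps_full`.
#' @param maf_range minor-allele-frequency sampling range, inside (0.01, 0.5).
#' @param trait_r2_target named vector, fraction of trait variance explained
#'   by the true-weight score (per trait).
#' @param confounder_effect_trait,confounder_effect_disease effect of the
#'   shared standard-normal confounder U on each trait (trait SD units) and
#'   on the disease log-odds.
#' @param causal_log_or_per_unit named vector (or scalar, recycled) of the
#'   causal disease log OR per 1 SD unit of each trait.
#' @param pleiotropy_log_or per-SNP direct effect on the disease log-odds
#'   (scalar recycled over SNPs, or a vector named by SNP id); default 0.
#' @param cohort_sizes list of named vectors `c(cases=, controls=, population=)`.
#' @param lipid_cohort index of the cohort carrying measured serum lipids.
#' @param lipid_subset_fraction fraction of the lipid cohort's cases+controls
#'   with measured lipids.
#' @param n_mci number of extra MCI individuals (lipid cohort only, all with
#'   measured lipids; they enter first-stage fits only).
#' @param missing_rate genotype missingness probability, in [0, 0.05].
#' @param base_prevalence disease prevalence in the base population from
#'   which cases and screened controls are rejection-sampled.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(traits = c("HDL", "LDL", "TG", "TC"),
                       n_snps_full = c(HDL = 69, LDL = 55, TG = 40, TC = 70),
                       n_snps_specific = c(HDL = 45, LDL = 9, TG = 16, TC = 18),
                       maf_range = c(0.05, 0.5),
                       trait_r2_target = c(HDL = 0.0419, LDL = 0.0183,
                                           TG = 0.0434, TC = 0.0359),
                       confounder_effect_trait = 0.3,
                       confounder_effect_disease = 0.3,
                       causal_log_or_per_unit = 0,
                       pleiotropy_log_or = 0,
                       cohort_sizes = list(
                         mrc  = c(cases = 3234, controls = 1175, population = 4989),
                         iop  = c(cases = 350,  controls = 313,  population = 0),
                         adni = c(cases = 330,  controls = 187,  population = 0)),
                       lipid_cohort = 2,
                       lipid_subset_fraction = 0.64,
                       n_mci = 127,
                       missing_rate = 0.01,
                       base_prevalence = 0.15,
                       seed = 1) {
  traits <- as.character(traits)
  n_snps_full <- n_snps_full[traits]
  n_snps_specific <- n_snps_specific[traits]
  trait_r2_target <- trait_r2_target[traits]
  if (length(causal_log_or_per_unit) == 1L && is.null(names(causal_log_or_per_unit))) {
    causal_log_or_per_unit <- stats::setNames(rep(causal_log_or_per_unit, length(traits)), traits)
  } else {
    missing_t <- setdiff(traits, names(causal_log_or_per_unit))
    causal_log_or_per_unit[missing_t] <- 0
    causal_log_or_per_unit <- causal_log_or_per_unit[traits]
  }
  cfg <- list(traits = traits, n_snps_full = n_snps_full,
              n_snps_specific = n_snps_specific, maf_range = maf_range,
              trait_r2_target = trait_r2_target,
              confounder_effect_trait = confounder_effect_trait,
              confounder_effect_disease = confounder_effect_disease,
              causal_log_or_per_unit = causal_log_or_per_unit,
              pleiotropy_log_or = pleiotropy_log_or,
              cohort_sizes = cohort_sizes, lipid_cohort = lipid_cohort,
              lipid_subset_fraction = lipid_subset_fraction, n_mci = n_mci,
              missing_rate = missing_rate, base_prevalence = base_prevalence,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(is.na(cfg$n_snps_full)) || any(is.na(cfg$n_snps_specific)))
    stop("SNP counts must be named for every trait", call. = FALSE)
  if (any(cfg$n_snps_specific > cfg$n_snps_full))
    stop("configuration error: trait-specific SNP count exceeds full count for: ",
         paste(cfg$traits[cfg$n_snps_specific > cfg$n_snps_full], collapse = ", "),
         call. = FALSE)
  if (any(cfg$n_snps_full < 1))
    stop("configuration error: each full score needs at least one SNP", call. = FALSE)
  if (cfg$maf_range[1] <= 0.01 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] >= cfg$maf_range[2])
    stop("maf_range must lie inside (0.01, 0.5]", call. = FALSE)
  if (any(cfg$trait_r2_target <= 0 | cfg$trait_r2_target >= 1))
    stop("trait_r2_target must be in (0, 1)", call. = FALSE)
  sizes <- unlist(cfg$cohort_sizes)
  if (any(sizes < 0) || any(vapply(cfg$cohort_sizes, function(s) s["cases"] + s["controls"], 1) <= 0))
    stop("cohort sizes must be non-negative with cases+controls > 0", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.05)
    stop("missing_rate must be in [0, 0.05]", call. = FALSE)
  if (cfg$base_prevalence <= 0 || cfg$base_prevalence >= 1)
    stop("base_prevalence must be in (0, 1)", call. = FALSE)
  if (cfg$lipid_subset_fraction < 0 || cfg$lipid_subset_fraction > 1)
    stop("lipid_subset_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$lipid_cohort < 1 || cfg$lipid_cohort > length(cfg$cohort_sizes))
    stop("lipid_cohort out of range", call. = FALSE)
  invisible(cfg)
}

#' Simulate an external-GWAS SNP weights table
#'
#' Draws a per-SNP weights table with the trait-membership structure of the
#' published lipid GWAS panels: trait-specific SNPs belong to exactly one
#' trait, while the remaining SNPs of each full set are shared between at
#' least two traits (full sets overlap, trait-specific sets are disjoint).
#' Effect sizes are drawn on the trait-SD scale and oriented so that the risk
#' allele raises LDL/TC/TG and lowers HDL; the `beta` column is the positive
#' scoring weight and `effect_on_trait` the signed per-risk-allele effect
#' (negative for HDL).
#'
#' @param config a [sim_config()] object.
#' @return data frame of class `"weights_table"`, one row per (SNP, trait),
#'   with columns `snp_id`, `trait`, `risk_allele`, `other_allele`, `beta`,
#'   `se_beta`, `effect_on_trait`, `trait_specific`, `excluded`, `maf`; the
#'   `oriented` attribute is `TRUE`.
#' @export
simulate_weights <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 101L, {
    traits <- config$traits
    n_shared_needed <- config$n_snps_full - config$n_snps_specific

    memberships <- list()
    # Trait-specific SNPs: one membership each.
    for (t in traits) {
      memberships <- c(memberships,
                       replicate(config$n_snps_specific[[t]], t, simplify = FALSE))
    }
    n_specific_total <- length(memberships)
    # Shared SNPs: repeatedly pair the two traits with largest remaining need,
    # guaranteeing every shared SNP belongs to >= 2 traits where feasible.
    need <- n_shared_needed
    while (sum(need) > 0) {
      ord <- order(need, decreasing = TRUE)
      if (length(need) == 1 || need[ord[2]] == 0) {
        # One trait left over: its remaining SNPs join an arbitrary other
        # trait's full set too where one exists (keeps the >=2 membership
        # property); with a single simulated trait they stand alone.
        lead <- names(need)[ord[1]]
        other <- traits[traits != lead]
        member <- if (length(other) > 0) c(lead, other[1]) else lead
        memberships <- c(memberships,
                         replicate(need[ord[1]], member, simplify = FALSE))
        need[ord[1]] <- 0
      } else {
        pair <- names(need)[ord[1:2]]
        memberships <- c(memberships, list(pair))
        need[ord[1]] <- need[ord[1]] - 1
        need[ord[2]] <- need[ord[2]] - 1
      }
    }

    n_snps <- length(memberships)
    snp_id <- sprintf("rs%06d", sample.int(999999L, n_snps))
    maf <- stats::runif(n_snps, config$maf_range[1], config$maf_range[2])
    alleles <- t(vapply(seq_len(n_snps),
                        function(i) sample(c("A", "C", "G", "T"), 2),
                        character(2)))

    rows <- list()
    for (i in seq_len(n_snps)) {
      for (t in memberships[[i]]) {
        b <- stats::rgamma(1, shape = 1.2, rate = 15) + 0.01
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = snp_id[i], trait = t,
          risk_allele = alleles[i, 1], other_allele = alleles[i, 2],
          beta = b, se_beta = b / 10 + 0.002,
          effect_on_trait = if (t == "HDL") -b else b,
          trait_specific = (i <= n_specific_total),
          excluded = FALSE, maf = maf[i],
          stringsAsFactors = FALSE)
      }
    }
    w <- do.call(rbind, rows)
    rownames(w) <- NULL
    attr(w, "oriented") <- TRUE
    class(w) <- c("weights_table", "data.frame")
    w
  })
}

# Analytic noise scale so the true-weight score explains trait_r2_target of
# the trait variance under HWE: Var(g) = sum 2p(1-p)beta^2, total variance
# V = Var(g)/r2, residual noise sd^2 = V - Var(g) - c_U^2.
trait_scale_params <- function(config, weights) {
  traits <- config$traits
  out <- list()
  for (t in traits) {
    wt <- weights[weights$trait == t & !weights$excluded, ]
    var_g <- sum(2 * wt$maf * (1 - wt$maf) * wt$effect_on_trait^2)
    if (var_g == 0) {
      # null architecture: trait is confounder plus unit noise
      out[[t]] <- list(var_g = 0, v_total = config$confounder_effect_trait^2 + 1,
                       sd_noise = 1)
      next
    }
    v_total <- var_g / config$trait_r2_target[[t]]
    var_noise <- v_total - var_g - config$confounder_effect_trait^2
    if (var_noise <= 0)
      stop("trait_r2_target for ", t, " unattainable: genetic + confounder ",
           "variance already exceeds the implied total", call. = FALSE)
    out[[t]] <- list(var_g = var_g, v_total = v_total, sd_noise = sqrt(var_noise))
  }
  out
}

# Draw one unconditional block of the base population: genotypes, confounder,
# unit-variance latent traits and disease status.
draw_base_block <- function(n, snp, effects, scale_par, config) {
  s <- nrow(snp)
  X <- matrix(stats::rbinom(n * s, 2L, rep(snp$maf, each = n)), nrow = n)
  colnames(X) <- snp$snp_id
  U <- stats::rnorm(n)
  G <- X %*% effects  # n x traits, signed genetic values
  traitmat <- matrix(0, n, length(config$traits),
                     dimnames = list(NULL, config$traits))
  for (t in config$traits) {
    p <- scale_par[[t]]
    traitmat[, t] <- (G[, t] + config$confounder_effect_trait * U +
                        stats::rnorm(n, sd = p$sd_noise)) / sqrt(p$v_total)
  }
  logit <- stats::qlogis(config$base_prevalence) +
    drop(traitmat %*% config$causal_log_or_per_unit[config$traits]) +
    config$confounder_effect_disease * U
  pl <- config$pleiotropy_log_or
  if (any(pl != 0)) {
    plv <- if (length(pl) == 1L) rep(pl, s) else pl[snp$snp_id]
    logit <- logit + drop(X %*% plv)
  }
  disease <- stats::rbinom(n, 1L, stats::plogis(logit))
  list(X = X, U = U, traits = traitmat, disease = disease)
}

subset_block <- function(block, idx) {
  list(X = block$X[idx, , drop = FALSE], U = block$U[idx],
       traits = block$traits[idx, , drop = FALSE], disease = block$disease[idx])
}

bind_blocks <- function(a, b) {
  list(X = rbind(a$X, b$X), U = c(a$U, b$U),
       traits = rbind(a$traits, b$traits), disease = c(a$disease, b$disease))
}

# Serum lipid observation model: mmol/l location-scale transform of the
# latent unit-variance trait with additive age and sex effects, matching the
# linear covariate model the downstream residualization assumes. Values are
# floored just above zero (sub-0.1 mmol/l serum lipids do not occur; the
# floor only ties the extreme lower tail, which average ranks absorb).
lipid_observation <- function(traitmat, age, sex) {
  mu <- c(HDL = 1.6, LDL = 3.2, TG = 1.4, TC = 5.6)
  sc <- c(HDL = 0.30, LDL = 0.75, TG = 0.45, TC = 1.0)
  out <- matrix(NA_real_, nrow(traitmat), ncol(traitmat),
                dimnames = dimnames(traitmat))
  for (t in colnames(traitmat)) {
    m <- if (t %in% names(mu)) mu[[t]] else 3
    s <- if (t %in% names(sc)) sc[[t]] else 0.5
    out[, t] <- pmax(0.1, m + s * traitmat[, t] +
                       0.03 * (age - 74) + 0.05 * sex)
  }
  out
}

#' Simulate multi-cohort case-control data with known causal truth
#'
#' Generates genotype dosages, latent lipid traits, observed serum lipids
#' (mmol/l, for the designated subset), covariates, and case/control status
#' for each configured cohort. Genotypes are binomial(2, MAF) under
#' Hardy-Weinberg equilibrium; each trait is the weighted sum of risk-allele
#' dosages plus a shared confounder and Gaussian noise scaled analytically so
#' the true-weight score explains `trait_r2_target` of the unit trait
#' variance; disease arises from a logistic liability with a configurable
#' causal effect of each trait, the confounder, and optional direct
#' (pleiotropic) SNP effects. Cases and screened controls are
#' rejection-sampled from the base population; population controls and MCI
#' individuals are sampled unconditionally. Missing dosages are inserted
#' completely at random.
#'
#' @param config a [sim_config()].
#' @param weights a weights table from [simulate_weights()] (or compatible).
#' @return list of class `"lipidmr_sim"` with elements `cohorts` (each a list
#'   with `name`, `dosages` matrix in risk-allele counts with `NA`s, and a
#'   `phenotypes` data frame with status/age/sex/PCs/batch/apoe4/lipids and
#'   oracle `latent_<trait>` columns), `weights`, `config`, and `truth` (the
#'   causal parameters plus realized first-stage R-squared per trait).
#' @export
simulate_cohorts <- function(config, weights) {
  validate_sim_config(config)
  snp <- unique(weights[, c("snp_id", "maf")])
  effects <- matrix(0, nrow(snp), length(config$traits),
                    dimnames = list(snp$snp_id, config$traits))
  for (r in seq_len(nrow(weights))) {
    effects[weights$snp_id[r], weights$trait[r]] <- weights$effect_on_trait[r]
  }
  scale_par <- trait_scale_params(config, weights)

  withr::with_seed(config$seed + 202L, {
    cohorts <- vector("list", length(config$cohort_sizes))
    for (k in seq_along(config$cohort_sizes)) {
      sz <- config$cohort_sizes[[k]]
      name <- names(config$cohort_sizes)[k]
      if (is.null(name) || name == "") name <- paste0("cohort", k)

      acc <- NULL
      n_cases <- 0; n_ctrl <- 0; tries <- 0
      target_cases <- sz[["cases"]]; target_ctrl <- sz[["controls"]]
      block_n <- max(1000L, ceiling(2 * (target_cases / config$base_prevalence)))
      while (n_cases < target_cases || n_ctrl < target_ctrl) {
        tries <- tries + 1
        if (tries > 50)
          stop("sampling error: could not reach requested case/control counts ",
               "after 50 blocks (cohort ", name, ")", call. = FALSE)
        b <- draw_base_block(block_n, snp, effects, scale_par, config)
        keep_case <- which(b$disease == 1L)[seq_len(min(sum(b$disease == 1L),
                                                        target_cases - n_cases))]
        keep_ctrl <- which(b$disease == 0L)[seq_len(min(sum(b$disease == 0L),
                                                        target_ctrl - n_ctrl))]
        kept <- subset_block(b, c(keep_case, keep_ctrl))
        acc <- if (is.null(acc)) kept else bind_blocks(acc, kept)
        n_cases <- n_cases + length(keep_case)
        n_ctrl <- n_ctrl + length(keep_ctrl)
      }
      status <- ifelse(acc$disease == 1L, "case", "control")

      if (sz[["population"]] > 0) {
        pop <- draw_base_block(sz[["population"]], snp, effects, scale_par, config)
        acc <- bind_blocks(acc, pop)
        status <- c(status, rep("population", sz[["population"]]))
      }
      if (k == config$lipid_cohort && config$n_mci > 0) {
        mci <- draw_base_block(config$n_mci, snp, effects, scale_par, config)
        acc <- bind_blocks(acc, mci)
        status <- c(status, rep("mci", config$n_mci))
      }

      n <- length(status)
      age <- round(stats::rnorm(n, mean = c(case = 76, control = 74,
                                            population = 62, mci = 75)[status],
                                sd = 7), 1)
      sex <- stats::rbinom(n, 1L, 0.45)
      pcs <- matrix(stats::rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("PC", 1:4)))
      batch <- if (k == config$lipid_cohort) stats::rbinom(n, 1L, 0.5) + 1L
               else rep(1L, n)
      apoe4 <- stats::rbinom(n, 2L, ifelse(status == "case", 0.35, 0.14))

      # Lipid measurement subset: a fraction of cases+controls plus all MCI.
      has_lipid <- rep(FALSE, n)
      if (k == config$lipid_cohort) {
        cc <- which(status %in% c("case", "control"))
        n_meas <- round(config$lipid_subset_fraction * length(cc))
        has_lipid[sample(cc, n_meas)] <- TRUE
        has_lipid[status == "mci"] <- TRUE
      }
      lip <- lipid_observation(acc$traits, age, sex)
      lip[!has_lipid, ] <- NA_real_

      X <- acc$X
      if (config$missing_rate > 0) {
        miss <- matrix(stats::runif(length(X)) < config$missing_rate,
                       nrow(X), ncol(X))
        X[miss] <- NA_integer_
      }
      iid <- sprintf("%s_%05d", name, seq_len(n))
      rownames(X) <- iid

      ph <- data.frame(fid = iid, iid = iid, status = status, age = age,
                       sex = sex, pcs, batch = batch, apoe4 = apoe4,
                       stringsAsFactors = FALSE)
      for (t in config$traits) {
        ph[[paste0("lipid_", t)]] <- lip[, t]
        ph[[paste0("latent_", t)]] <- acc$traits[, t]
      }
      attr(ph, "lipid_unit") <- "mmol/l"
      cohorts[[k]] <- list(name = name, dosages = X, phenotypes = ph)
    }

    # Realized first-stage R^2: regress latent trait on the true-weight score
    # in an independent unconditional evaluation sample.
    ev <- draw_base_block(5000L, snp, effects, scale_par, config)
    realized_r2 <- vapply(config$traits, function(t) {
      score <- drop(ev$X %*% effects[, t])
      summary(stats::lm(ev$traits[, t] ~ score))$r.squared
    }, numeric(1))

    truth <- list(causal_log_or_per_unit = config$causal_log_or_per_unit,
                  snp_effects = effects,
                  pleiotropy_log_or = config$pleiotropy_log_or,
                  realized_r2 = realized_r2)
    structure(list(cohorts = cohorts, weights = weights, config = config,
                   truth = truth),
              class = "lipidmr_sim")
  })
}

#' @export
print.lipidmr_sim <- function(x, ...) {
  cat("Simulated lipid MR study:", length(x$cohorts), "cohorts\n")
  for (co in x$cohorts) {
    cat(sprintf("  %s: n=%d (%s), %d SNPs\n", co$name, nrow(co$phenotypes),
                paste(names(table(co$phenotypes$status)),
                      table(co$phenotypes$status), sep = "=", collapse = ", "),
                ncol(co$dosages)))
  }
  cat("Causal log OR per trait unit:",
      paste(names(x$truth$causal_log_or_per_unit),
            signif(x$truth$causal_log_or_per_unit, 3), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
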