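---
title: "Methods: Mendelian randomization of lipid genotype risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization of lipid genotype risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmr)
```

## The question and the design

Observational associations between blood lipid levels and late-onset
Alzheimer disease (LOAD) are vulnerable to confounding and reverse
causation: lipid levels drift with age, comorbidity and pre-clinical
disease. Mendelian randomization (MR) sidesteps both by using genetic
variants as instruments: alleles are assigned at meiosis independently of
lifestyle confounders, and disease cannot alter germline genotype. If a
weighted genotype risk score (GRS) built from lipid-associated SNPs is
associated with disease, and the only path from those SNPs to disease runs
through lipid levels, the score-disease association measures the causal
effect of the lipid.

`lipidmr` implements that design as a reusable, tested pipeline over four
lipid exposures — HDL cholesterol, LDL cholesterol, total cholesterol (TC)
and triglycerides (TG) — with a binary disease outcome, multiple
case-control cohorts, and a simulator with known causal truth to validate
every estimator.

## Genotype risk scores

For each trait we build two weighted scores from external GWAS weights:
a *full* score over all SNPs associated with the trait (the default panel
sizes are 69/55/40/70 for HDL/LDL/TG/TC) and a *trait-specific* score
restricted to SNPs associated with only that trait (45/9/16/18), which
trades instrument strength for robustness to pleiotropy. (The panel counts
are configurable; published descriptions of such panels are not fully
consistent — one source text says 18 TG-specific SNPs where its own summary
tables say 16 — so the counts are parameters, with the table values as
defaults.)

The raw score of individual $i$ is a score per non-missing SNP,

$$\mathrm{GRS}_i = \frac{\sum_j \beta_j d_{ij}}{\#\{j : d_{ij}\
\text{observed}\}},$$

with $d_{ij}$ the dosage of the risk allele (0–2, fractional dosages from
imputation are accepted) and $\beta_j$ the positive per-allele weight. The
"risk" allele is defined as the allele that raises LDL/TC/TG or *lowers*
HDL; `orient_weights()` flips incoming rows to that convention and keeps
the signed trait effect alongside the positive weight (an oriented table is
marked and re-orientation is a no-op, so the HDL sign convention cannot be
applied twice). Individuals missing at least 5% of a score's SNPs are
excluded *for that score only*; missing dosages are handled by the
denominator, never by imputing the mean. Scores are standardized to mean 0,
SD 1 within cohort over included individuals — standardization across pooled
cohorts would let cohort-level dosage differences leak into the per-cohort
regressions, and all downstream models are fit per cohort.

## Phenotype preparation

Serum lipids arrive in mmol/l and are converted to mg/dl (×38.67 for the
cholesterol fractions, ×88.57 for TG); the conversion refuses to run twice.
Each lipid is regressed on age, age² and sex by OLS and the residuals are
rank inverse-normal transformed using Blom offsets,
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, with average ranks for ties.
Blom is the common epidemiological default; no variant is canonical, and
any offset choice differs only in the extreme tails. The transform is fit
within the lipid-measured subset only, never across cohorts, to avoid rank
leakage. Individuals with mild cognitive impairment (MCI) who have lipid
measurements are included in this subset to increase first-stage precision;
they never enter disease models.

## Two-stage estimation

**First stage** (instrument strength): OLS of the transformed lipid on the
standardized GRS, with no further covariates — the trait is already
residualized. We report the slope $\hat\beta_1$ (trait units per GRS SD),
its SE, $R^2$, and $F(1, n-2)$; for a simple regression these satisfy
$F = R^2 (n-2)/(1-R^2)$ exactly, which the tests assert.

**Second stage**: maximum-likelihood logistic regression of case/control
status on the standardized GRS giving $\hat\beta_2$, a log OR per GRS SD.
Covariates follow the per-cohort policy: four ancestry principal components
everywhere, a genotyping-batch indicator in the cohort that has batches,
and (in sensitivity runs) age, sex and APOE ε4 count. Population controls
are coded as controls in the main analysis and dropped in a named
sensitivity run. Perfect separation and singular covariate matrices fail
loudly, naming the offending column; there is no silent penalized fallback.

**Ratio (Wald) IV estimator**: the causal disease log OR per unit of the
lipid trait is $\hat\beta_2/\hat\beta_1$, with the first-order delta-method
standard error

$$\mathrm{se} = \sqrt{\frac{\mathrm{se}_2^2}{\beta_1^2} +
\frac{\beta_2^2\,\mathrm{se}_1^2}{\beta_1^4}},$$

which carries uncertainty from *both* stages with zero covariance — the
appropriate form when the first stage comes from a subsample or an
independent sample, as here. Monte-Carlo error propagation (10⁶ paired
normal draws) agrees with this formula to within 2% when
$\mathrm{se}_1/\beta_1 \le 0.1$; the approximation degrades quadratically
in $\mathrm{se}_1/\beta_1$ (at 0.15 the deviation already slightly exceeds
2%), which is one more reason to gate on instrument strength.

**Summary-data IVW estimator**: when only per-SNP summary statistics are
trusted (or the GRS instrument is weak), the per-SNP disease log ORs
$\hat\beta_{2j}$ are combined with the external per-SNP trait effects
$\beta_{1j}$ as

$$\widehat{\log\mathrm{OR}} =
\frac{\sum_j \beta_{1j}\hat\beta_{2j}/\mathrm{se}_{2j}^2}
     {\sum_j \beta_{1j}^2/\mathrm{se}_{2j}^2},
\qquad
\mathrm{se} = \Big(\textstyle\sum_j
\beta_{1j}^2/\mathrm{se}_{2j}^2\Big)^{-1/2}.$$

This is algebraically identical to (a) weighted least squares through the
origin of $\hat\beta_{2j}$ on $\beta_{1j}$ with weights
$1/\mathrm{se}_{2j}^2$ and (b) fixed-effects pooling of the per-SNP ratio
estimates $\hat\beta_{2j}/\beta_{1j}$ with SEs
$\mathrm{se}_{2j}/|\beta_{1j}|$; both identities are asserted to $10^{-10}$
in the tests. The trait-effect SEs are ignored (standard first-order IVW).

**Instrument gate**: the ratio estimator is the headline method when the
first-stage $R^2 \ge 1.5\%$ (inclusive), IVW otherwise. The threshold is
configurable; 1.5% is the point at which subsample-derived first stages are
known to retain essentially full power.

## Meta-analysis

Per-cohort estimates are pooled by fixed-effects inverse variance:
$w_i = 1/\mathrm{se}_i^2$, pooled $= \sum w_i x_i / \sum w_i$,
$\mathrm{se} = (\sum w_i)^{-1/2}$, with Cochran's
$Q = \sum w_i (x_i - \bar x)^2$ and $I^2 = \max(0, (Q - (k-1))/Q) \times
100$ (truncated at zero). A DerSimonian–Laird random-effects check uses
$\tau^2 = \max(0, (Q-(k-1))/(\sum w - \sum w^2/\sum w))$ and reduces to the
fixed-effects result exactly under homogeneity. To pool estimates published
only as OR with 95% CI, `se_from_ci()` reconstructs
$\mathrm{se} = (\ln U - \ln L)/3.92$ assuming a log-symmetric interval and
warns when the printed OR sits more than 0.02 log-units off the interval
midpoint (a sign of rounding or a typo in the source; pooled values
recomputed from printed tables are therefore reproducible only to rounding
error, and ±0.005 on the pooled OR is the tolerance the tests use). The
implementations are cross-checked against `metafor` in the test suite;
`metafor` is never used as the computational path because the IVW estimator
and the pooling step must satisfy the exact cross-module identity above.

## Study-design calculators

`expected_or(or_a, or_b)` combines a score→high-lipid association with a
published high-lipid→disease association as
$\exp(\ln \mathrm{OR}_a \cdot \ln \mathrm{OR}_b)$, bounds pairwise
(lower×lower, upper×upper). This form is symmetric in its arguments, has
OR = 1 as a fixed point, and reproduces all six worked values printed for
the two published input pairs (1.19/1.06–1.46 and 1.73/1.06–4.48) to
±0.01. `power_logistic()` gives two-sided normal-approximation power for a
standard-normal predictor in unmatched case-control logistic regression,
$z = \ln(\mathrm{OR})\sqrt{n\varphi(1-\varphi)}$ with $\varphi$ the case
fraction; a simulation mode (repeated logistic fits) agrees within 2%.

## The simulator and what it does (and does not) emulate

`simulate_weights()` draws a weights table with the trait-membership
structure of the real panels: trait-specific SNPs belong to one trait;
remaining full-set SNPs are shared between the two traits with the largest
unmet need (greedy pairing), so full sets overlap and specific sets are
disjoint. MAFs are uniform on (0.05, 0.5); effect magnitudes are
gamma-distributed (shape 1.2, rate 15, shifted by 0.01), giving the
many-small/few-large profile of GWAS lipid loci on the trait-SD scale.

`simulate_cohorts()` draws genotypes binomial(2, MAF) under HWE with no LD
(the panels are independent loci), a single shared standard-normal
confounder $U$, and unit-variance latent traits
$T = (G + c_T U + \varepsilon)/\sqrt{V}$ where $G$ is the signed
true-weight score. The noise scale is computed analytically from
$\mathrm{Var}(G) = \sum_j 2p_j(1-p_j)\beta_j^2$ so the true score explains
exactly the target $R^2$ of the trait variance — no iterative calibration.
Default $R^2$ targets (4.19/1.83/4.34/3.59% for the full scores) match the
instrument strengths reported for such panels. Disease follows a logistic
liability with intercept at a base prevalence of 0.15 (a plausible LOAD
prevalence in an elderly sampling frame), configurable causal effects per
trait, confounder effect $c_D$, and optional per-SNP direct (pleiotropic)
effects. Cases and screened controls are rejection-sampled from the base
population (mirroring case-control ascertainment); population controls and
MCI individuals are drawn unconditionally. Observed serum lipids are an
additive location-scale transform of the latent trait plus linear age and
sex effects — deliberately the model the residualization step assumes —
floored at 0.1 mmol/l; genotype missingness is completely at random.

The defaults reproduce the analysed study's structure: cohorts of
3,234/1,175/4,989 (cases/controls/population controls), 350/313 and
330/187, with the lipid-measured subset (~423 of the second cohort plus
127 MCI, ≈550 total) and the confounder linking lipids and disease
(`confounder_effect_trait` = `confounder_effect_disease` = 0.3), so the
naive trait-disease regression is biased while IV estimation is not.

What the simulator does *not* emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium between instruments,
imputation-dosage uncertainty, population stratification (the PCs supplied
to the disease models are pure noise covariates), genuinely pleiotropic
architectures unless requested, differential missingness, and the empirical
weakness of real trait-specific scores (simulated specific SNPs draw
effects from the same distribution as shared ones, so a 45-SNP specific
score can be a strong instrument here while its real counterpart was not).

A `TruthRecord` stored with every dataset carries the causal parameters and
the realized first-stage $R^2$, measured by regressing the latent trait on
the true-weight score in an internal unconditional sample of 5,000 (its
Monte-Carlo error is ~0.005 at $R^2 \approx 4\%$; validation tests that
need tighter error regress on larger simulated samples directly).

## Numerical and testing choices

- **Determinism**: all randomness flows from one integer seed through
  `withr::with_seed`, with fixed small offsets separating the weights and
  cohort streams; the same seed gives byte-identical output, and analysis
  reruns on written files reproduce in-memory results exactly.
- **Degenerate inputs**: zero-variance scores, constant lipid vectors,
  zero first-stage slopes (|β₁| < 10⁻⁸), monomorphic SNPs, perfect
  separation, singular covariates, degenerate CIs (se = 0) and mismatched
  allele orientations all raise explicit errors or flags rather than
  propagating silently.
- **Calibration suite**: under the causal null the ratio-IV 95% CI covers
  OR = 1 in 95% ± 2% of 1,000 replicates, run on a scaled-down single-trait
  study (20 SNPs, 500/500 case-control cohort, first-stage subset of 550 at
  $R^2 = 4\%$) so the suite completes in about a minute.
- **Recovery suite**: causal log ORs {0, 0.1, 0.25} are recovered with
  median bias below 10% over 200 replicates. The recovery cohort is
  2,500/2,500: with the delta formula, the per-replicate ratio SE is
  ≈ se₂/β₁ ≈ 0.14, so the median's Monte-Carlo error
  (≈ 1.25 · se/√200 ≈ 0.012) resolves the tolerance band, which a
  1,000-person cohort cannot at any bias level. The 10% band is given an
  absolute floor of 0.025 (10% of the largest simulated effect), without
  which the null case would demand an exact zero.
- **Known estimand subtlety**: the logistic second stage targets a
  marginal (population-averaged) log OR, which differs from the
  conditional causal parameter by non-collapsibility — an attenuation of
  roughly 2–3% at the default confounder strength and effect sizes, well
  inside the recovery tolerance but not zero. Larger confounder effects on
  disease would widen it.

## Limitations

Beyond the simulator gaps listed above: the ratio estimator assumes all
instrument-disease effect flows through the measured trait (no pleiotropy
check such as MR-Egger is provided — deliberately, as the implemented
method set matches the original analysis period); cross-cohort first-stage
transport is assumed (one lipid-measured subset weights all cohorts); and
the power calculator covers unmatched designs with a standardized predictor
only.
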