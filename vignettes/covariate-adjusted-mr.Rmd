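---
title: "Covariate-adjusted GWAS summary statistics in Mendelian randomisation: models, bias and the MVMR correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-adjusted GWAS summary statistics in Mendelian randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two-sample Mendelian randomisation (MR) estimates the causal effect of an
exposure $X$ on an outcome $Y$ by combining per-variant summary
associations from two GWAS: $\hat\pi_{X,j}$ (variant $j$ on the exposure)
and $\hat\Gamma_j$ (variant $j$ on the outcome). Many published GWAS,
however, were run *conditional on a covariate* $C$ — blood pressure
adjusted for BMI, lung function adjusted for height and smoking — because
conditioning increases power. When $X$ and $C$ share an unmeasured cause,
the covariate is a collider on the path from a variant to the exposure,
and the adjusted association is no longer $\hat\pi_{X,j}$ but
approximately

$$\hat\pi_{A,j} \;=\; \hat\pi_{X,j} - \rho_{CX}\,\hat\pi_{C,j},$$

where $\hat\pi_{C,j}$ is the variant's association with the covariate and
$\rho_{CX}$ the exposure–covariate correlation (the identity is exact for
jointly normal standardised traits up to a term of order
$\mathrm{cov}(g, C)^2$; `adjusted_association()` implements it).
Substituting $\hat\pi_A$ into the inverse-variance-weighted (IVW)
estimating equation
$\hat\Gamma_j = \beta_t \hat\pi_{X,j} + \epsilon_j$ shows that
univariable MR from adjusted summary statistics is biased whenever
variants with $\hat\pi_C \neq 0$ enter the instrument set and
$\rho_{CX} \neq 0$, with the bias directed *against* the covariate's
direct effect on the outcome.

The correction this package implements and studies: include the covariate
as a second exposure in a multivariable MR (MVMR). Rewriting the MVMR
regression under the substitution,

$$\hat\Gamma_j = \beta_1 \hat\pi_{A,j} + \beta_2 \hat\pi_{C,j} + \epsilon_j
 \;=\; \beta_1 \hat\pi_{X,j} + (\beta_2 - \beta_1\rho_{CX})\,\hat\pi_{C,j} + \epsilon_j,$$

so the **exposure coefficient is identical whether the adjusted or
unadjusted GWAS is used** — MVMR recovers the direct effect $\beta_1$ —
while the **covariate coefficient converges to the biased value
$\beta_2 + \beta_1\rho_{CX}$** and must not be interpreted
(`predicted_mvmr_covariate_estimate()`). This is an exact linear
reparameterisation of the design matrix, and the package tests assert it
to $10^{-10}$ on the estimators themselves.

## The simulated causal structures

`build_model()` parameterises three linear structural equation models over
an exposure $X_1$, a heritable covariate $X_2$, an outcome $Y$ and an
unmeasured standard-normal confounder $U$ loading on all three. 250
biallelic SNPs (MAF 0.3, Binomial(2, MAF) dosages) split into two sets of
125: $G_1$ SNPs act directly on $X_1$, $G_2$ SNPs on $X_2$. The scenarios
differ only in the trait–trait path:

* **confounded** — $X_2 \to X_1$ (path 0.25): the covariate confounds the
  exposure–outcome relation, so $G_2$ variants reach $X_1$ and enter the
  instrument set as pleiotropic instruments;
* **correlated** — no path: $X_1, X_2$ correlate only through $U$;
* **mediated** — $X_1 \to X_2$ (path 0.25): the covariate mediates part of
  the exposure's effect, so total (0.6) and direct (0.4) effects differ.

Direct effects on the outcome are $\beta_{X_1} = 0.4$ and
$\beta_{X_2} = 0.8$ throughout, giving total effects
(0.4, 0.9), (0.4, 0.8) and (0.6, 0.8) by path tracing
(`total_effects()`), and the `overrides` argument supports the
supplementary variants (null effects, opposite directions).

### Calibration of the free parameters

The reference simulation tables pin down the structural coefficients, the
exposure–covariate correlations and the instrument strengths, but not the
raw variance components, so the generator solves for them:

* **Per-SNP effect scale.** Mean single-SNP F for a unit-variance trait at
  $n$ individuals is $\approx 1 + n \cdot 2p(1-p) \cdot E[\pi^2]$. The
  reference study's instrument strengths (about 300 for $X_1$, about 265 for
  $X_2$ at $n = 10^5$) give $E[\pi^2] = 7.14\times10^{-3}$ and
  $E[\gamma^2] = 6.32\times10^{-3}$.
* **Effect dispersion.** The mean square fixes only the second moment of
  the normal effect distributions. Their SDs govern how many
  covariate-associated SNPs leak through genome-wide selection for the
  exposure — exactly the mechanism that biases univariable MR — and were
  set by pilot simulation against the selection-driven univariable MR
  cells: `sd = 0.02` for $G_1$ (which keeps the $X_1$ instrument F at its
  reference value) and `sd = 0.05` for $G_2$; means are
  $\sqrt{E[\cdot^2] - \mathrm{sd}^2}$. Negative draws are permitted (IVW
  is invariant to per-SNP sign flips); a `positive_effects` switch
  truncates if monotone instruments are wanted.
* **Confounder loadings.** $u_{x_1} = u_{x_2} = \sqrt{\rho_U}$ with
  $\rho_U = 0.275$ (confounded, correlated) or $0.15$ (mediated), so that
  the total correlation — confounder part plus direct path — is
  $\rho_{CX} = 0.525 / 0.275 / 0.40$ by scenario. These are the values
  backed out of the reference study's MVMR covariate coefficients
  ($1.01 = 0.8 + 0.4\times0.525$, $0.91$, $0.96$).
* **Residual SDs.** Solved per scenario so that
  $\mathrm{Var}(X_1) = \mathrm{Var}(X_2) = 1$, making loadings
  interpretable as correlations. Overriding any field re-solves the
  others unless they are overridden too. The outcome keeps $u_y = 0.5$
  and $\sigma_y = 1$ (moderate unmeasured confounding of the
  exposure–outcome relation, the situation MR exists for); with these
  values the unadjusted IVW model SE in the correlated scenario is
  $\approx 0.009$, matching the reference study's scale.

Per-SNP effects are **redrawn each replication** and shared by the two
samples of the two-sample design: the effect vector is part of the
stochastic design, not a fixed truth (pass `effects =` to
`simulate_sample()` to fix it).

## The estimation pipeline

`gwas_scan()` fits every single-SNP regression
(`trait ~ dosage` or `trait ~ dosage + covariate`) in closed form from
per-SNP sufficient statistics; two small C++ kernels generate dosages and
accumulate those statistics so that a full replication — two samples of
100,000, five scans, all estimators — costs about a second.
P-values use the normal reference (at $n = 10^5$ the t correction is
irrelevant and this matches GWAS convention). Instruments are selected at
the genome-wide threshold $p < 5\times10^{-8}$; the reference protocol
says only "strongly associated", and the genome-wide level used in its
applied analyses is adopted for consistency (configurable). Selection
happens **in the same sample as the exposure associations**, deliberately
reproducing the winner's-curse component of the study design.

Estimators (`mr_ivw`, `mvmr_ivw`, `mr_egger`, `mr_weighted_median`,
`mr_weighted_mode`, `wald_ratio`) follow the standard summary-data
formulations: weighted least squares with weights
$1/\mathrm{se}(\hat\Gamma)^2$, fixed-effect SEs by default with a
multiplicative random-effects switch
($\mathrm{se} \times \max(1, \sqrt{Q/(L-k)})$), and normal 95% intervals
($\pm 1.96\,\mathrm{se}$) throughout. The Monte Carlo driver applies the
random-effects SE to its **MVMR** fits: selecting instruments in the
exposure sample induces conditional heterogeneity that the fixed-effect
MVMR interval ignores, leaving it anti-conservative (empirical SDs about
30% above the fixed-effect SE and coverage near 0.82 where the reference study
reports 0.88–0.91), while the residual-scaled SE restores near-nominal
coverage — and matches the behaviour of the lm-based MVMR estimation in
the field's standard packages. Univariable IVW keeps fixed-effect SEs in
the driver, under which the adjusted-exposure analyses are diagnosed as
decisively biased (zero coverage), again matching the reference tables;
residual scaling there would absorb the contamination heterogeneity into
the interval and hide part of the bias. Weighted median and mode use seeded
parametric bootstrap SEs (1000 draws by default). Instrument strength is
the mean single-SNP F (`mean_f_statistic`) for univariable MR and the
two-exposure heterogeneity-Q conditional F (`conditional_f`) for MVMR:
$Q(\delta)$ is minimised over a dense grid with local refinement —
deterministic and immune to the occasional non-convexity of the profile.

## The Monte Carlo study

`run_replication()` simulates an exposure sample and an independent
outcome sample (same population draw), scans, selects, and runs the
requested analyses under the four adjustment schemes (none / exposure /
outcome / both). For MVMR the instrument set is the union of
exposure-selected and covariate-selected SNPs. `run_scenario()` loops
replications with seeds derived from a master seed by a documented
counter (`replication_seed(master, r) = (master + 7919 r) mod (2^31-1)`),
so any subset of replications can be recomputed independently;
`aggregate_replications()` produces the table cells (mean estimate, mean
model SE, empirical SD, 95% coverage, mean F) and `render_table()` the
study-style layout. Coverage is judged against the **total** effect for
univariable MR and the **direct** effect for MVMR, matching the
reference study's table notes; both the mean model SE and the empirical SD are
reported because a printed "Std. error" can mean either.

The default reduced profile is $n = 10^5$ with 200 replications per
scenario (the full study profile of 1000 sits behind `n_reps`): at 200
replications the Monte Carlo error of a mean-estimate cell is below
0.005, smaller than the two-decimal rounding of the reference tables,
and a three-scenario run completes in minutes on one CPU. The same
profile backs `scripts/acceptance.R` and the heavyweight test in
`tests/testthat/test-acceptance.R`.

What the generator deliberately does *not* emulate: linkage
disequilibrium between variants (inputs to the applied mode are assumed
pre-clumped, and the CLI refuses applied runs without `--assume-clumped`),
non-linear or interaction effects, binary traits, and sample overlap
beyond the two-sample default. Passing tests therefore demonstrate
correctness of the estimators and the adjustment algebra under a clean
linear DGP — not robustness to LD structure, allele-frequency estimation
error, or pervasive horizontal pleiotropy in real data.

## Numerical and design notes

* **Unidentified MVMR columns.** An exposure column of exact zeros leaves
  that coefficient unidentified; it is reported `NA` and the other
  exposure's fit reduces to univariable IVW, rather than erroring, so the
  orthogonal-block limit behaves continuously. Genuinely collinear
  designs raise an error naming the problem.
* **Degenerate genotype columns** (monomorphic after sampling) are
  excluded from scans with a warning naming the SNPs.
* **Weighted median** uses the interpolated cumulative-weight rule
  (midpoint convention); **weighted mode** a normal kernel with modified
  Silverman bandwidth $0.9 \min(\mathrm{sd}, \mathrm{mad}) L^{-1/5}$,
  grid argmax plus golden-section refinement. Ties and flat stretches are
  resolved deterministically by the grid.
* **Outcome-adjusted bias prediction.** The printed derivation for an
  adjusted *outcome* GWAS reuses the exposure–covariate correlation,
  predicting a covariate coefficient of $\beta_2 - \rho_{CX}$; simulation
  (and the reference study's own tables) show outcome-adjusted covariate
  estimates close to $\beta_2$, because instruments are selected on the
  exposure and the relevant correlation parameter is the
  covariate–outcome partial correlation. The function implements the
  formula as printed and its documentation flags the outcome scheme as
  approximate; the simulation, not this formula, is the package's
  authority for that scheme.
* **Harmonisation.** Variants are matched by id only; effect alleles are
  aligned allowing swaps and strand flips; palindromic (A/T, C/G)
  variants are dropped when the effect-allele frequency is within 0.08 of
  0.5 in any study (no reference value exists; (0.42, 0.58) is the
  conventional window and it is configurable) and otherwise oriented by
  frequency concordance. The per-variant audit trail partitions the
  intersection exactly, and harmonisation is idempotent.

## Worked example

```{r, eval = FALSE}
library(covadjMR)

model <- build_model("confounded")
rep1 <- run_replication(model, n = 1e5, seed = replication_seed(1, 1),
                        schemes = c("none", "exposure"))
rep1[, c("scheme", "analysis", "exposure", "estimate", "se", "n_snps")]

# the covariate coefficient converges to beta2 + beta1 * rho
predicted_mvmr_covariate_estimate(0.4, 0.8, attr(rep1, "rho_cx"),
                                  "exposure")

# full (reduced-profile) reproduction of the simulation tables
tabs <- reproduce_tables(seed = 1, n_reps = 200)
tabs$table_mr
tabs$table_mvmr
```

## Known limitations

The covariate coefficient from the corrected MVMR is biased by
construction and must not be interpreted; only the exposure's direct
effect is recovered, which differs from the total effect when the
covariate mediates. The correction needs covariate GWAS summary
statistics and conditionally strong instruments — with weak conditional
instruments (low `conditional_f`) the MVMR model cannot be reliably
estimated, and no correction is attempted here for that regime.
Covariance-aware MVMR for overlapping samples, correlated-instrument
(LD-matrix) estimation and outlier-removal estimators are out of scope.
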