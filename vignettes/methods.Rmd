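---
title: "Models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, and the
numerical and design choices made where the methodology left room. It states
no empirical result that the test suite does not itself compute.

## 1. The Scaled Subprofile Model pattern

**Model.** Let $V$ be an $n \times p$ matrix of strictly positive regional
volumes (here $p = 14$ bilateral subcortical structures, in mL). The SSM
operates on $x_{ij} = \log v_{ij}$; the log makes multiplicative global
scaling additive, so a subject-level size factor becomes a row offset.
Double centering,
$$\mathrm{srp}_{ij} = x_{ij} - \bar x_{i\cdot} - \bar x_{\cdot j} + \bar x,$$
removes each subject's mean profile and the group mean regional profile,
leaving the subject *residual* profiles whose covariance the SVD
$\mathrm{srp} = U D W^\top$ decomposes into orthonormal regional loadings
(GIS, columns of $W$) and subject scores (SSF, $\mathrm{srp}\,W$).

**Biomarker-driven component selection.** Candidate models regress the
biomarker (plasma homocysteine) on the first $k$ scores, $k = 1, \dots,
k_{\max}$; the retained set is the sequential prefix minimizing the Gaussian
OLS AIC $n \ln(\mathrm{RSS}/n) + 2(k + 2)$, counting slopes, intercept and
error variance as parameters (the method names AIC but no formula; this is
the standard likelihood form). Ties go to the smallest $k$. The combined
pattern $w \propto W_{[,1:k]}\hat\gamma$ is rescaled to unit norm — the
scale is absorbed into expression — and signed so that expression correlates
non-negatively with the biomarker.

**Expression and out-of-sample scoring.** A subject's expression is the
projection of their centered residual profile onto $w$, z-scored with the
derivation sample's mean and SD, which are frozen into the model; new
subjects are preprocessed with the stored per-region log-TIV slopes and
scored on the derivation scale.

**Tunables.**

| parameter | default | why |
|---|---|---|
| preprocessing `mode` | `log_tiv_residual` | every downstream model adjusts for TIV; residualizing the log volumes on log TIV removes head-size covariance from the pattern itself. `log_only` is retained because the upstream convention is not fixed. |
| `max_k` | min(8, components reaching 90% variance) | keeps candidate sets sequential and small relative to $p = 14$. |
| RSS floor | $10^{-12}\,\mathrm{var}(y)\,n$ | keeps AIC finite on exact fits. |
| `log_biomarker` | `FALSE` | whether the biomarker is logged before the AIC regression is not fixed by the method; exposed as a flag. |
| hemispheres | 14 bilateral regions | averaging to 7 is available (`average_hemispheres()`); bilateral is the default because left/right asymmetries are informative. |

**Bootstrap reliability.** Subjects are resampled with replacement and the
*entire* derivation re-run per replicate (selection included); replicate
weight vectors are aligned to the point estimate by the sign of their dot
product. This absorbs component-order instability by re-deriving the
combined pattern rather than matching components. Reported per region:
bootstrap SD, $Z = w/\mathrm{SD}$, percentile CIs. No $|Z|$ threshold is
applied by default — the reliability table reports, the analyst decides.
Degenerate replicates are skipped and counted; more than 5% failures aborts.

A caveat the test suite documents: because combining coefficients are raw
regression slopes on component scores, low-variance noise components that
slip through AIC selection enter the combined weights with inflated slopes.
Under weak biomarker coupling this makes replicate weights genuinely
unstable — reliability Z values are then honest about the instability. The
"strong planted pattern" reliability test therefore uses a strong regime
(biomarker loading 0.9, pattern scale 0.1, region noise 0.01), not the
generator defaults.

## 2. Block-wise regression and FDR

Cumulative OLS per covariate block (the focal predictor is present in every
block; block $k$ contains all earlier blocks), fitted once on the shared
complete-case sample. Standardized coefficients are $\beta = B\,
\mathrm{sd}(x)/\mathrm{sd}(y)$ with SDs from that sample; binary covariates
are standardized by the same ratio (matching the telescoping identity used
in mediation). Inference is exact Student-t; the residual df convention is
$n - (\text{parameters incl. intercept})$, e.g. $160 - 6 = 154$ for a
four-covariate final block. The family of final-block p-values across the
four lobar outcomes is adjusted by the Benjamini–Hochberg step-up rule
$\tilde p_{(i)} = \min_{j \ge i} \{ p_{(j)} m / j \} \wedge 1$ with stable
ties. Missingness is handled by listwise deletion (the design reports no
imputation strategy). A zero-residual fit is rejected as an error — it
almost always means the outcome leaked into the predictors.

## 3. Serial mediation

For mediators $M_1, \dots, M_k$ ($k \le 3$) the package fits, on one shared
complete-case sample with the same covariates in every equation:
$M_i \sim X + M_{<i} + C$, $\;Y \sim X + M_{1..k} + C$, and the total model
$Y \sim X + C$. Indirect effects are products of coefficients along each of
the $2^k - 1$ order-respecting paths. The completely standardized effect is
$\mathrm{raw}\cdot\mathrm{sd}(X)/\mathrm{sd}(Y)$, which telescopes into the
product of standardized path coefficients — this identity is what makes
published standardized indirect effects recomputable from published path
coefficients, and it is asserted to $10^{-10}$ in the tests. The OLS
identity $c = c' + \sum \text{indirects}$ is verified by
`decompose_total()`; violation signals inconsistent samples across
submodels.

**Bootstrap.** Percentile (not bias-corrected) intervals, per the stated
procedure: cases are resampled whole (preserving the covariate joint
distribution), every submodel refitted, and each path's effect collected.
CI endpoints are order statistics at ranks $\lfloor B\alpha/2 \rfloor$
(clamped to $\ge 1$) and the mirrored rank; `floor` rather than `round`
because rounding at exact .5 is floating-point-representation dependent
(B = 500 put $B\alpha$ exactly on .5). Inside the bootstrap, standardized
effects use each replicate's own SDs; the point estimate uses full-sample
SDs; both raw and standardized CIs are reported because the macro
convention is ambiguous. Each replicate draws from its own deterministic
seed substream, so growing `n_boot` never changes earlier replicates.
Rank-deficient replicates are skipped and counted (>5% aborts). The default
is 10,000 iterations for release runs; the test suite scales down to
100–500 and says so.

A calibration fact the acceptance suite documents deliberately: under the
*complete* null (all chain paths zero) the percentile CI of a
product-of-coefficients estimator is far more conservative than nominal —
measured 0.5% exclusion of zero at the 95% level over 200 simulated
cohorts of $n = 160$ — because the replicate product distribution
concentrates around zero from both sides. The corresponding acceptance
criterion expects ≈5% and is left failing with this explanation rather than
being widened; power against the planted-strength chain (exclusion in the
majority of runs) is met.

## 4. The synthetic cohort generator

**What it emulates.** A linear-Gaussian structural-equation system over the
hypothesized chain (age → log WMH → latent pattern expression → parietal
GMV → log TMT-A) plus direct age edges, TIV loadings on the lobar volumes,
weaker expression loadings on the non-focal lobes, and age-only equations
for the memory and executive scores. Equations operate on population-
standardized parents; each endogenous residual variance is set from the
model-implied parent covariance so every variable has unit population
variance — the configured path coefficients are then *exactly* the
population standardized betas, which is what makes planted values
comparable to published standardized coefficients. Each variable is finally
rescaled affinely to its marginal (mean, SD); binary covariates (sex 86/160
female, APOE ε4 0.25, hypertension 0.30, smoking 0.30) are Bernoulli and
independent of the chain by default. WMH and TMT-A are simulated normal on
the log scale with log-moments matched to the published raw-scale mean/SD
under a log-normal assumption. Default chain strengths are the published
standardized paths (0.526, 0.241, −0.186; −0.409 into processing speed);
remaining defaults a practitioner would call typical for healthy older
cohorts: TIV 1400 ± 130 mL, VO2max 22 ± 5, B12 500 ± 200, GDS 1.5 ± 2, and
— because the source cohort publishes no homocysteine marginal — Hcy
10 ± 3 µmol/L, exposed as a free parameter rather than guessed silently.

The subcortical volume matrix is a TIV-proportional regional baseline
(typical per-hemisphere volumes) with the unit-norm pattern planted on the
log scale at `pattern_scale` (default 0.05) scaled by the latent expression,
plus i.i.d. log-scale region noise (default SD 0.02, i.e. 2% volumetric
noise). Homocysteine loads on the latent expression at `hcy_loading`
(default 0.5). The latent `true_expression` column is retained for
recovery tests.

**Seeding.** One master seed drives per-equation substreams
(`(seed·1009 + index·7919) mod (2^31−19)`), so adding a variable does not
perturb existing ones and output is byte-identical per configuration.

**What it does not emulate, hence what a green test does not establish.**
No measurement non-normality, floor/ceiling effects in cognitive scores, no
missing data (unless configured), no nonlinear age effects, no spatial
correlation in region noise beyond the planted rank-1 pattern, no
covariate–chain confounding (risk factors are independent of the chain, so
follow-up regressions are null by construction). Recovery of planted
parameters demonstrates the estimators are correct, not that the scientific
model is.

## 5. Degenerate inputs and tie-breaks

* Constant TIV in `log_tiv_residual` mode falls back to `log_only`
  (zero slopes) rather than erroring.
* An all-zero residual matrix yields an empty decomposition with a warning.
* AIC ties select the smallest component set.
* `residualize()` on an exactly linear pair returns zeros with a warning
  instead of dividing by a zero SD.
* BH adjustment requires p ∈ (0, 1]; zeros are rejected, not clamped.
* The FDR gate in the pipeline (adjusted p < 0.05) can be overridden
  (`gate = FALSE`) for exploratory runs; with no gated lobes the mediation
  stages are skipped and the report says so.

## 6. Known limitations

AIC prefix selection overfits with the usual ~16% per-candidate
probability; with noisy biomarkers the selected set, and hence bootstrap
reliability, inherit that variability (see §1). The three-path bootstrap
test is conservative under complete nulls (§3), so non-significant
full-chain findings at small $n$ are weak evidence of absence. Sample sizes
below ~20 are rejected outright because the largest submodel would exhaust
residual degrees of freedom. Only serial (not parallel) multiple-mediator
models are implemented, and only up to three mediators.
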