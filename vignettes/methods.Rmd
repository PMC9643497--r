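---
title: "Methods: polygenic-score Mendelian randomization for adiponectin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic-score Mendelian randomization for adiponectin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The design

`adipomr` implements a one-sample Mendelian randomization (MR) study of
circulating adiponectin against nine cardiometabolic outcomes (HOMA-IR, HDL,
LDL, total cholesterol, triglycerides, SBP, DBP, type 2 diabetes,
hypertension). The instrument is a polygenic risk score (PRS) built by
clumping and thresholding (C+T) from external GWAS summary statistics of
adiponectin, scored in the target cohort, and validated for instrument
strength and confounder balance. Causal effects per 1 SD of
log-adiponectin are estimated by two-stage least squares (2SLS) for
continuous outcomes and a two-stage logistic estimator for binary outcomes,
with generalized-method-of-moments (GMM) counterparts as sensitivity
analyses, stratified by weight status (BMI < 25 vs >= 25 kg/m^2) and sex.

Individual-level cohorts of this kind are not publicly shareable, so the
package carries a synthetic-data generator with known causal architecture.
Every estimator-level claim the test suite makes (parameter recovery,
confidence-interval coverage, type-I error, directional recovery for
protective odds ratios) is made against that ground truth.

# The synthetic cohort

The generator follows a structural equation model. With $G$ the dosage
matrix, $U \sim N(0,1)$ a latent (unobserved) confounder, and covariates
age, sex, and BMI:

$$X = \sum_j b_j g_j + a_x U + b_{\mathrm{bmi}}\,\mathrm{bmi}^\ast +
  b_{\mathrm{sex}} (\mathrm{sex} - 0.62) + s_{\mathrm{pop}} + \varepsilon_x,$$

where $X$ is standardized log-adiponectin and adiponectin is reported as
$\exp(\mu + \sigma X)$ ng/ml ($\mu = \log 7549$, $\sigma = 1.05$, matching
the skewed ng/ml distributions seen in African cohort data). The $b_j$
are scaled so the instrument variants explain `instrument_variance_fraction`
of $\mathrm{var}(X) = 1$. Each continuous outcome is

$$Y_k = \beta_k X + a_y U + 0.1\,\mathrm{age}^\ast + 0.1\,(\mathrm{sex}-0.62)
 + 0.1\,\mathrm{bmi}^\ast + \text{(pleiotropy)} + \varepsilon_k,$$

with the residual variance chosen so that $\mathrm{var}(Y_k) = 1$
*including* the covariance contributions that flow through $X$ (which itself
carries $U$, BMI and sex loadings). This bookkeeping matters: without the
$2\beta_k a_y a_x$ cross-term the outcome SD exceeds 1 and `causal_beta`
would no longer be the effect per outcome SD, which is the scale on which
all estimates are reported. Outcomes are then mapped to natural units
(mg/dl, mmHg) with anchors taken from published descriptive statistics for
sub-Saharan African adults; HOMA-IR and triglycerides are log-normal.

Choices worth recording:

* **LD model.** Haplotypes are generated blockwise by an allele-copying
  Markov chain: variant $j$ copies the variant $j-1$ allele with probability
  $c$ and redraws otherwise, giving adjacent-genotype correlation exactly
  $c$; setting $c = \sqrt{r^2_{\mathrm{target}}}$ hits the target adjacent
  $r^2$ without any attenuation correction. Blocks are independent, so
  clumping is nontrivial within blocks and exact across them. Frequencies
  are drawn per block, and subpopulations diverge by a Balding–Nichols beta
  model so genetic PCs carry real structure. This is far simpler than human
  LD maps, which is all the C+T machinery needs.
* **T2D and ascertainment.** T2D follows a logistic liability in $X$ and
  $U$ with the intercept solved for a base population prevalence of 25%;
  fasting glucose is then simulated consistently with the diagnostic rule
  (untreated cases >= 7.0 mmol/L, controls below), so `t2d ==
  (glucose >= 7 | glucose_med)` holds by construction. The case-control
  design is emulated by simulating a larger source population and keeping
  all cases plus a control subsample until the case share reaches
  `case_fraction` (default 0.48).
* **Hypertension** is defined by its rule (SBP >= 130 or DBP >= 80 or
  antihypertensive medication), so its association with the exposure is
  *induced* by the SBP/DBP effects rather than set by a direct logistic
  coefficient. A `causal_beta` entry for hypertension is accepted but the
  definitional rule wins; tests of binary-estimator calibration therefore
  use T2D, whose log-odds effect is directly specified.
* **HOMA-IR** is drawn log-normal with its specified loading on $X$, and
  fasting insulin is back-derived as `homa * 22.5 / glucose`, so the index
  formula holds exactly and the "exclude T2D cases from HOMA-IR analyses"
  rule has real structure to act on.
* **Instrument share.** The default `instrument_variance_fraction` is 0.03.
  The emulated study reports only F statistics (35.6 crude, 116.7 adjusted
  at n ~ 3350), not the PRS $R^2$; 0.03 reproduces F statistics of that
  order at comparable sample sizes and is typical for an adipokine PRS.
  This is a modelling choice, set once.
* **Defaults for causal effects** mirror the direction and rough magnitude
  of the observational pattern being emulated (negative for HOMA-IR,
  triglycerides and T2D; positive for HDL, LDL, total cholesterol and blood
  pressure), with LDL at 0.55 SD per SD — the scenario of a true LDL
  effect the study design is centred on.
* About 5% of simulated base-GWAS records are reported on the opposite
  strand, and target INFO scores are skewed high with ~12% below 0.8, so
  harmonization's flip path and the INFO filter both do real work without
  gutting the panel. Base-GWAS INFO is uniform on [0.3, 1].

What the generator does *not* emulate: realistic human LD maps and allele
frequency spectra, imputation error structure, sex chromosomes,
batch/array effects, or hidden relatedness beyond the explicit
duplicate/parent-offspring constructions used in tests. Passing tests
demonstrate that the *estimators and algorithms* behave as claimed under a
controlled data-generating process, not that any particular real-data
result is reproduced.

# Quality control

Filters run in a fixed, reported order: marker missingness (> 0.01) →
MAF (< 0.01) → Hardy–Weinberg exact test (p < 1e-6) → INFO (< 0.8), then
sample missingness (> 0.01) → heterozygosity F (|F - mean| > 3 SD) →
relatedness. Marker metrics must exist before sample metrics; the rest of
the order is conventional. Boundary values survive (INFO = 0.8 passes a
"< 0.8 removed" rule). The HWE test is the exact conditional test computed
by the standard recurrence over heterozygote counts, with a relative
tolerance of 1e-7 when comparing configuration probabilities so exact
symmetric ties are not broken by floating-point noise.

Harmonization classifies every shared variant id: duplicates dropped
entirely, palindromic (A/T, C/G) variants dropped unconditionally (no
frequency-based rescue — allele-frequency alignment is unreliable across
ancestries, and the emulated protocol removed ambiguous variants outright),
exact matches kept, complement matches kept as strand flips, effect alleles
re-expressed on the target a1 allele with the beta sign flipped and EAF
complemented when needed. The five counts sum to the number of shared ids.

Kinship uses the robust identity-by-state moment estimator
$\varphi = (N_{\mathrm{het,het}} - 2N_{\mathrm{opp\,hom}}) /
(N_{\mathrm{het},i} + N_{\mathrm{het},j})$, which gives 0.5 for duplicates,
~0.25 for parent-offspring, ~0 for unrelated pairs, and needs no allele
frequencies. Pairs above 0.0884 (the conventional second-degree cutoff,
$2^{-3.5}$) are resolved greedily: remove the member with more flagged
pairs, ties by lower call rate then id. The estimator's variance scales
with the effective number of independent markers, so the pipeline computes
it on at most 2000 (thinned) variants and skips the stage entirely below
200 variants — at desk-scale panel sizes of a few thousand variants the
null distribution is tight enough that false flags stay below ~1%.
Missing dosages are mean-imputed for PCA only and left missing elsewhere;
PRS scoring imputes a missing dosage as twice the effect-allele frequency.

An optional pre-clumping r²-window pruning pass exists in spirit in the
clumping routine itself; a separate pruning stage is deliberately not run
by default, since pruning followed by clumping would discard index SNPs
arbitrarily.

# Instrument construction

Clumping is greedy by ascending p (ties: position, then id), removing
unprocessed same-chromosome variants within 250 kb at $r^2 > 0.1$ —
standard C+T defaults, configurable. Threshold selection fits
`exposure ~ score + covariates` per grid threshold and keeps the threshold
with the best incremental $R^2$ over the covariate-only model (ties go to
the smaller threshold; thresholds retaining no SNP are skipped). The
default grid is {5e-8, 1e-6, 1e-5, 1e-4, 5e-4, 1e-3, 0.01, 0.05, 0.1, 0.5,
1}; any numeric grid (e.g. a fine grid) can be supplied.

The empirical p permutes the exposure only — covariates and genotypes stay
fixed — re-runs the full grid optimization per permutation, and reports
$(1 + \#\{R^2_{\mathrm{perm}} \ge R^2_{\mathrm{obs}}\})/(n_{\mathrm{perm}}+1)$.
Because scores per threshold do not change under exposure permutation, the
implementation residualizes the scores on the covariates once and reduces
each permutation to a set of correlations, which is what makes
10,000-permutation runs (and the uniformity tests at 1000 permutations)
cheap. The algebra is exact, not an approximation.

# Estimators

All 95% intervals are `estimate ± 1.96·SE` and p-values are two-sided
normal — the reporting convention of the applied literature this mirrors.

* **2SLS** (just-identified, single PRS instrument): the point estimate
  equals the covariate-residualized Wald ratio
  $\mathrm{cov}(\tilde z, \tilde y)/\mathrm{cov}(\tilde z, \tilde x)$; the
  SE uses structural residuals $y - \hat\beta x - \hat\gamma'C$, not
  second-stage residuals, with a $n - k$ degrees-of-freedom divisor.
* **GMM (continuous)**: identical point estimate by the just-identified
  algebraic identity; heteroskedasticity-robust sandwich SE
  $(Z'X)^{-1} \left(\sum_i z_i z_i' \hat u_i^2\right) (X'Z)^{-1}$.
* **Two-stage logistic** (binary): stage 1 regresses the exposure on
  instrument + covariates over all samples (cases and controls — the
  case-control ascertainment caveat is real and testable in the simulator);
  stage 2 is logistic on the fitted exposure. The default SE is the
  second-stage model SE, mirroring the common applied practice; a
  nonparametric bootstrap over individuals (default 1000 resamples) is
  available because two-stage SEs understate uncertainty.
* **GMM logistic**: solves
  $E[(y - \mathrm{expit}(\alpha + \beta x + \gamma'C))\,(1, C', z)'] = 0$
  by damped Newton iteration. The system is just-identified, so two-step
  weighting cannot move the root; the SE is the GMM sandwich. This
  logistic-mean moment condition is one faithful reading of the published
  two-step GMM approach for binary outcomes; a multiplicative structural
  mean model is a documented alternative that is not implemented.
  Non-convergence (including separation, detected by fitted probabilities
  at machine bounds or diverging coefficients) is returned as an explicit
  diagnostic, never silently.

First-stage strength is the squared t of the instrument coefficient,
reported crude and covariate-adjusted; estimates carry a weak-instrument
flag when F < 10. Exposure and outcome standardization is computed on the
full analysis sample *before* stratification so stratum effects stay on a
common per-SD scale; sex strata drop sex from the covariates. SBP/DBP
models add blood-pressure-medication use to both adjustment sets;
lipid-lowering-medication users are excluded from all models and T2D cases
from HOMA-IR models.

Sensitivity analyses: per-covariate regressions of the PRS on age, sex,
BMI, alcohol and smoking (no multiplicity adjustment, mirroring the
reporting convention); and the per-SNP scatter of exposure betas against
outcome betas from PC-adjusted single-SNP regressions — a deliberate
simplification of a mixed-model association scan, defensible because the
synthetic cohort has no hidden relatedness after QC. The published check is
visual ("no outliers"); here it is formalized as |studentized residual| > 3
from the inverse-variance-weighted through-origin fit, with the threshold
configurable.

# Numerical and scale choices

Problem sizes are chosen so the full validation battery runs on one CPU at
desk scale: the bundled end-to-end fixture uses 2000 samples × 5000
variants in 200 LD blocks with 1000 permutations (~30 s); recovery and
coverage use 200 replicates at n = 2000; type-I error uses 1000 replicates
at n = 1000; permutation uniformity uses 200 datasets × 1000 permutations.
The permutation count for a real analysis would be 10,000 (the default in
`pipeline_config`).

Degenerate inputs are handled explicitly: zero-variance instruments,
constant covariates (dropped), constant fitted exposures, monomorphic
scatter SNPs (dropped with a warning), empty strata (reported unavailable
with a reason, other strata still computed), and logistic separation
(diagnostic, not a crash). Determinism: every stage derives its seed from
the single pipeline seed, and identical config + seed reproduces estimate
tables byte-for-byte.

# Known limitations

One-sample MR with a PRS instrument cannot separate horizontal pleiotropy
from the causal path; the balance and scatter checks detect gross
violations only. MR-Egger, weighted-median and multivariable MR are out of
scope (they need per-SNP instruments with genome-wide-significant effects,
which this design lacks by construction). The binary two-stage estimator
inherits non-collapsibility and case-control ascertainment caveats; the
simulator exists precisely so those can be quantified rather than assumed
away.
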