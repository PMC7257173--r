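---
title: "Targeted PRM quantification of CSF biomarker panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted PRM quantification of CSF biomarker panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfprm)
```

## The measurement model

Parallel reaction monitoring quantifies a peptide from the summed
chromatographic peak areas of its monitored product ions (transitions).
Peak areas are positive and their technical variation is proportional to
signal, so the whole pipeline treats areas as multiplicative quantities:
systematic effects are factors, noise is lognormal, and precision is
reported as the coefficient of variation (CV% = 100·sd/mean) on the linear
scale.

For injection $j$ and peptide $p$, the modelled area is

$$A_{pj} = \underbrace{\exp\!\big(\mu_{\pi(p)} + \beta_{g(j)}\log 2 +
  \gamma_a (\text{age}_j - 70) + \gamma_s\,\text{sex}_j\big)}_{\text{biology}}
  \cdot r_p \cdot d(b_j, t_j) \cdot \varepsilon_{pj},$$

where $\pi(p)$ is the parent protein, $\beta_g$ the diagnostic-group log2
fold change, $r_p$ a peptide ionization response, $d$ a multiplicative
drift term depending on batch $b_j$ and within-batch injection position
$t_j$, and $\varepsilon$ lognormal measurement noise. Transition areas
split $A_{pj}$ by a per-peptide intensity-share simplex. Three label
channels exist: the endogenous **light** signal; **heavy** stable-isotope
standards spiked at a constant nominal amount for a subset of peptides; and
spiked **reference**-mix peptides present in every injection. Standards
share the injection's drift and noise but carry no biology — which is what
makes drift estimable.

The analysis cascade inverts this model stage by stage:

| Stage | Operation | Removes / estimates |
|---|---|---|
| 1 | `sum_transitions()` | transition → peptide areas |
| 2 | `drift_factors()` + `apply_drift_correction()` | $d(b, t)$ per injection |
| 3 | `rollup_protein()` | peptide → protein (sum of observed peptides) |
| 4 | `gis_normalize()` | batch scale, via pooled-replicate anchors |
| 5 | `regress_covariates()` | age/sex, on log2 ratios, centered to 0 |
| 6 | `diff_test()`, `correlate_traits()`, `classify_proteins()` | $\beta$, trait couplings, discrimination |

## Drift correction

The factor for injection $j$ is the geometric mean over reference peptides
$r$ of the median-scaled area, $f_j = \text{geomean}_r\,(a_{rj} /
\text{median}_{j'} a_{rj'})$. The geometric mean keeps one aberrant
standard from dominating; median scaling makes each reference peptide
dimensionless before averaging. Doubling every reference in one injection
yields exactly $f = 2$ there and 1 elsewhere. When reference areas are
purely multiplicative ($a_{rj} = A_r d_j$) a second pass returns factors of
exactly 1; on general data re-derived factors are a constant near 1 —
i.e. no injection-dependent signal remains — which is the sense in which
the stage is idempotent.

## GIS normalization and precision QC

Each GIS injection is a pool of equal aliquots of all biological samples,
so its noise-free expectation is the arithmetic mean of the biological
samples' levels. Dividing each protein value by the mean of its batch's
GIS injections anchors every batch to the same pooled reference; by
construction the GIS ratios then average exactly 1 per batch (the package
asserts this to 1e-12). A `scope = "global"` variant divides by the mean
over all GIS injections instead; per-batch is the default because the
pool's purpose here is cross-batch drift removal.

Precision is the CV of each feature across GIS replicates, computed on
linear-scale values; features at or below 30% CV are flagged high
precision. The 30% cutoff is the conventional boundary for label-free
assays of this type. Differential statistics are computed on log2 ratios,
not on the linear CV scale.

## Covariate regression

Age and sex are regressed out of the log2 ratios per protein by OLS on
biological samples only; the output is the residual, so each protein has
mean exactly zero and zero sample covariance with the fitted covariates
(asserted to 1e-10). A covariate observed at a single level is dropped
with a warning rather than fitted rank-deficiently. Residualizing
residuals is a no-op (OLS projection idempotence).

## Differential abundance and correlation

Per protein: one-way ANOVA across Control/AD/NonAD, Tukey HSD pairwise
contrasts, and BH FDR across the protein family applied to the ANOVA p
values. "AD-specific" requires q < 0.05, both Tukey AD contrasts < 0.05,
and the AD mean strictly the highest or lowest of the three. The phrase
"post hoc FDR" is ambiguous in this field's figure legends; this package
reads it as FDR across the protein family plus Tukey adjustment within
protein, the standard construction for a ~41-protein panel.

The biweight midcorrelation uses Tukey biweights
$w_i = (1-u_i^2)^2\,\mathbf 1[|u_i|<1]$ with
$u_i = (x_i - \text{med})/(9\,\text{MAD})$ and the *unscaled* MAD
(median absolute deviation without the 1.4826 normal-consistency factor),
the form in which the estimator is defined. Observations beyond nine MADs
get zero weight, bounding the influence of gross outliers. Zero MAD (at
least half the values tied) makes the biweight undefined; the function
falls back to Pearson with a warning. Significance uses the Student
transform $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. Trait analyses are
restricted to one immunoassay platform at a time because the platforms
report different absolute scales.

## Classification

Each protein is evaluated alone: logistic regression (intercept + one
feature, no regularization) fitted by IRLS with maxit 100 and deviance
tolerance 1e-8, in stratified five-fold cross-validation with a fixed,
recorded seed. Out-of-fold probabilities are pooled into a single ROC —
pooling is the lower-variance convention when n ≤ 88 — built with one
operating point per distinct score (ties move diagonally in one step) and
integrated by trapezoid, which equals the tie-aware Mann–Whitney
statistic exactly. Complete separation does not abort a fit: iterations
cap, the result is flagged, and the AUC is still computed (AUC depends
only on score ranking). The Aβ42/tTau task labels a sample positive when
the ratio is strictly below 4.6; a ratio exactly at the cutoff is negative
— positivity is defined by the strict inequality, and the boundary rule is
stated rather than left to floating-point chance.

## The synthetic-study generator

`study_design()` defaults encode the emulated study: 20 control, 37 AD and
31 non-AD biological samples plus 10 GIS injections (98 in all) over 4
batches; 94 peptides from 41 proteins (12 proteins carry 3 peptides, 29
carry 2); 6 reference-mix peptides; 7 peptides with heavy partners; 5
transitions per peptide. GIS injections sit at evenly interleaved
positions (first/middle/last) within each batch so pooled replicates
bracket the run.

`ground_truth()` defaults, chosen once as a realistic label-free regime
and not revisited:

* `noise_sd_log = 0.25` — lognormal measurement noise; its closed-form CV
  is $\sqrt{e^{s^2}-1} \approx 25\%$, the technical CV plateau of
  label-free assays.
* `drift_rate = 0.025` per injection with batch scales
  `c(1.45, 0.90, 1.15, 0.70)` — sized from the same closed form so that
  raw pooled-replicate CVs land in the mid-40s and fall to the high 20s
  after drift correction, the precision gain this class of experiment
  reports.
* 25 of 41 proteins carry a +0.8 log2 AD effect; non-AD equals control —
  the replicated-marker pattern the panel is built around.
* Traits: total Tau and phospho-Tau couple positively (and Aβ42
  negatively) to designated proteins at strength 0.9 on the standardized
  log level, with log-scale noise 0.3, on Luminex-like scales (medians
  ~150, ~25 and ~900 pg/mL; the INNOTEST platform reports 2.5× those
  values). 67 of 88 samples are assigned to Luminex, so ratio-task and
  correlation analyses run on n = 67. These scales place AD samples below
  and controls above the 4.6 Aβ42/tTau cutoff.
* Transition noise is **mean-one** lognormal (sd 0.05), so transition
  areas sum to the peptide area exactly in expectation; peptide-level
  noise is plain lognormal so the closed-form CV above is exact.
* Ages are uniform on 55–85 and sex is Bernoulli(1/2) — cohort
  distributions are otherwise unspecified; covariate coefficients default
  to 0.01/year and 0.05 on the natural-log scale.

What the generator does **not** emulate: retention-time structure and
chromatographic interference; missingness beyond a simple detection
threshold (`dropout_threshold`, off by default); correlated peptide-level
noise within a protein — peptide noise is independent, so summing peptides
averages it and simulated *protein*-level GIS CVs run lower than
peptide-level ones, whereas in real data shared sample-prep variation
keeps them comparable. Passing tests therefore demonstrate the pipeline's
arithmetic and statistical calibration, not the full error structure of
real CSF data.

## Numerical and testing choices

* Exact invariants are asserted tightly: GIS batch means to 1e-12,
  residual means/covariances to 1e-10, AUC vs the pair-counting oracle and
  bicor vs its from-definition oracle to 1e-12.
* Zero within-group variance is detected relative to total variance
  (guarding against all-identical inputs) and raised as an error naming
  the protein.
* Calibration checks use sizes chosen for stable Monte-Carlo error on one
  CPU: 10,000 null replicates for the ANOVA type-I rate (expected
  0.05 ± 0.01), 20,000 per class for the AUC-vs-separation check
  ($d = 1.5 \Rightarrow \text{AUC} \approx \Phi(d/\sqrt2) \approx 0.856$),
  and 500 per group for fold-change recovery.
* The fold-change recovery check compares each of the 41 estimates to its
  injected value at ±3 SE. Two refinements make this a well-posed joint
  test. First, drift-factor estimation error is *shared* by every protein
  in a run: it shifts all 41 estimates together by an amount that, at
  n = 500 per group, is comparable to one biological SE, so per-protein
  intervals are checked around the run-level offset, and the offset itself
  is bounded at 3× its technical standard deviation (0.07 log2 units,
  about 9% of the injected 0.8-log2 effect). Second, 41 simultaneous
  3-sigma intervals fail jointly ~11% of the time under perfect
  calibration, so up to 2 exceedances (the chance level) are allowed.

## Limitations

* Charge states are not modelled separately; each peptide entry is one
  precursor.
* The APOE caller uses presence/absence only, so homozygous variant
  carriers are reported as heterozygous with E3; a quantitative allele
  balance would be needed to resolve them.
* Discovery-cohort fold changes are consumed as an input vector (or
  simulated independently); the package does not reprocess discovery-side
  raw data.
* With strong effects and small folds, per-fold logistic fits frequently
  reach complete separation; AUCs remain valid (rank-based) but fitted
  coefficients from such folds should not be interpreted.
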