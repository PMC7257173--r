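# csfprm

Label-free **parallel reaction monitoring (PRM)** analysis of cerebrospinal
fluid (CSF) biomarker panels, as a tidyverse-style R pipeline.

Targeted PRM assays monitor a fixed list of peptides and quantify each one
from the chromatographic peak areas of its product ions (transitions). For a
multi-batch clinical study — here a panel of 41 candidate Alzheimer's disease
(AD) proteins measured via 94 peptides in CSF from control, AD and non-AD
cognitively impaired donors — the raw areas carry large technical structure:
instrument signal drift within and between batches, and sample-loading
variance. `csfprm` implements the full normalization and evaluation cascade
such a study needs, plus a synthetic-study generator with known ground truth
so every stage can be tested end to end:

1. **Quantify** — sum transition areas into peptide areas
   (`sum_transitions()`); spectral-library and light/heavy pattern
   similarities (`dotp()`, `rdotp()`); light/heavy ratios; APOE allele calls
   from variant-specific peptides.
2. **Normalize** — per-injection drift factors from spiked reference
   standards: `factor_j = geomean_r(area_rj / median_j area_rj)`
   (`drift_factors()`); peptide→protein roll-up by summation
   (`rollup_protein()`); division by the per-batch mean of pooled global
   internal standard (GIS) injections (`gis_normalize()`); CV%-based
   precision QC on GIS replicates with the conventional 30% cutoff
   (`gis_cv()`); OLS regression of age and sex out of log2 ratios,
   centered to mean zero (`regress_covariates()`).
3. **Evaluate** — one-way ANOVA across diagnostic groups with Tukey HSD
   post hoc contrasts and Benjamini–Hochberg FDR (`diff_test()`); biweight
   midcorrelation with immunoassay traits (Aβ42, total Tau, phospho-Tau)
   with Student p values (`bicor()`, `correlate_traits()`); cross-cohort
   effect-size concordance (`cohort_concordance()`); and per-protein
   five-fold cross-validated logistic ROC classifiers for AD vs control,
   AD vs non-AD, and Aβ42/tTau-ratio biomarker positivity at the 4.6 cutoff
   (`train_cv_classifier()`, `classify_proteins()`).

Every user-facing function takes a data frame first and returns a tibble, so
stages chain with the pipe; fitted ROC objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

```r
library(csfprm)

study <- simulate_study(seed = 1)   # 20 control / 37 AD / 31 non-AD + 10 GIS
run   <- run_all(study, seed = 1)   # full cascade
run
#> <prm_run> seed 1, config 9df001b8
#>   n_peptides                       94
#>   n_proteins                       41
#>   n_biological_samples             88
#>   n_gis_injections                 10
#>   mean_peptide_gis_cv_raw          45.37
#>   mean_peptide_gis_cv_normalized   26.24
#>   mean_protein_gis_cv              16.16
#>   pct_proteins_high_precision      100
#>   n_significant_proteins           25
#>   top_auc_ad_vs_control            0.9878
#>   top_auc_ad_vs_nonad              0.9669
#>   top_auc_abeta_tau_ratio          0.9741
```

Reading the output: reference-standard drift correction cuts the mean
peptide-level CV across the 10 pooled (GIS) injections from 45% to 26% —
the raw-vs-normalized precision gain the cascade exists to deliver. Of the
41 proteins, exactly the 25 with a nonzero injected AD effect are flagged
AD-specific (FDR < 0.05, both Tukey AD contrasts < 0.05, AD mean extreme),
and the top cross-validated classifiers reach AUCs near 0.97–0.99 on this
simulation's effect sizes.

Downstream pieces are ordinary tibbles:

```r
run$differential |> dplyr::filter(significant)   # per-protein ANOVA table
run$qc                                           # CV QC per feature/stage
fits <- attr(run$roc, "fits")
autoplot(fits$PROT10)                            # ROC curve, best classifier
plot_cv_histogram(run$qc)                        # CV distributions by stage
```

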