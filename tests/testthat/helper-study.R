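# Shared fixtures, built once per suite run.

# The default synthetic study: the 20/37/31 + 10 GIS, 4-batch, 94-peptide
# design with drift and noise on.
default_study <- simulate_study(seed = 42)
default_run <- run_all(default_study, seed = 42)

# A clean study: no noise, no drift, no effects, no covariates. Every
# biological injection then carries identical peptide areas.
clean_truth <- function(design, ...) {
  ground_truth(design,
               effect_ad = 0, effect_nonad = 0,
               noise_sd_log = 0, transition_noise_sd = 0,
               drift_rate = 0, batch_scales = rep(1, design$n_batches),
               age_coef = 0, sex_coef = 0, ...)
}

small_design <- function(...) {
  study_design(n_control = 6, n_ad = 6, n_nonad = 6, n_gis = 4,
               n_batches = 2, n_proteins = 5, n_peptides = 12,
               n_reference_peptides = 3, n_heavy_peptides = 2,
               transitions_per_peptide = 3, ...)
}

# drift factor implied by the ground truth for each injection of a study
true_drift <- function(study) {
  md <- study$metadata
  study$truth$batch_scales[as.integer(sub("B", "", md$batch))] *
    exp(-study$truth$drift_rate * (md$injection_index - 1))
}
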