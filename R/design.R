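#' Define the layout of a PRM study
#'
#' A study design records how many biological samples of each diagnostic group
#' are analyzed, how many pooled global-internal-standard (GIS) injections are
#' interleaved, and how injections are divided over acquisition batches. The
#' defaults reproduce a single-site CSF biomarker panel: 20 controls, 37 AD
#' and 31 non-AD cognitive-impairment cases plus 10 GIS injections (98
#' injections in all) over 4 batches, targeting 94 peptides from 41 proteins
#' with spiked reference standards for drift correction.
#'
#' GIS injections are placed at evenly interleaved positions within each batch
#' (first/middle/last), so pooled replicates bracket the biological samples
#' and capture within-batch signal drift.
#'
#' @param n_control,n_ad,n_nonad Number of biological samples per diagnostic
#'   group.
#' @param n_gis Number of pooled GIS injections, distributed over batches
#'   (every batch receives at least one).
#' @param n_batches Number of acquisition batches.
#' @param n_proteins,n_peptides Size of the target panel. Peptides are
#'   allocated to proteins as evenly as possible (for 94 peptides over 41
#'   proteins: 12 proteins carry 3 peptides, 29 carry 2).
#' @param n_reference_peptides Number of spiked external reference peptides
#'   (a commercial reference mix) present in every injection, used to estimate
#'   per-injection drift factors.
#' @param n_heavy_peptides Number of target peptides that also receive a
#'   stable-isotope-labelled (heavy) standard at constant nominal amount, for
#'   light/heavy ratio checks.
#' @param transitions_per_peptide Number of product ions (transitions)
#'   monitored per peptide.
#'
#' @return An object of class `prm_design`: a list of validated counts plus
#'   the derived batch layout (`batch_sizes`, `gis_per_batch`,
#'   `peptides_per_protein`).
#' @examples
#' design <- study_design()
#' design$batch_sizes
#' @export
study_design <- function(n_control = 20, n_ad = 37, n_nonad = 31,
                         n_gis = 10, n_batches = 4,
                         n_proteins = 41, n_peptides = 94,
                         n_reference_peptides = 6,
                         n_heavy_peptides = 7,
                         transitions_per_peptide = 5) {
  counts <- c(n_control = n_control, n_ad = n_ad, n_nonad = n_nonad,
              n_gis = n_gis, n_batches = n_batches,
              n_proteins = n_proteins, n_peptides = n_peptides,
              n_reference_peptides = n_reference_peptides,
              transitions_per_peptide = transitions_per_peptide)
  if (any(counts < 1)) {
    stop("all design counts must be >= 1 (offending: ",
         paste(names(counts)[counts < 1], collapse = ", "), ")",
         call. = FALSE)
  }
  if (n_gis < n_batches) {
    stop("every batch needs at least one GIS injection: n_gis (", n_gis,
         ") < n_batches (", n_batches, ")", call. = FALSE)
  }
  if (n_peptides < n_proteins) {
    stop("need at least one peptide per protein", call. = FALSE)
  }
  if (n_heavy_peptides > n_peptides) {
    stop("n_heavy_peptides cannot exceed n_peptides", call. = FALSE)
  }

  n_bio <- n_control + n_ad + n_nonad
  n_inj <- n_bio + n_gis
  # near-equal batch sizes; earlier batches take the remainder
  base <- n_inj %/% n_batches
  extra <- n_inj %% n_batches
  batch_sizes <- rep(base, n_batches) + rep(c(1L, 0L), c(extra, n_batches - extra))
  gbase <- n_gis %/% n_batches
  gextra <- n_gis %% n_batches
  gis_per_batch <- rep(gbase, n_batches) +
    rep(c(1L, 0L), c(gextra, n_batches - gextra))

  pbase <- n_peptides %/% n_proteins
  pextra <- n_peptides %% n_proteins
  peptides_per_protein <- rep(pbase, n_proteins) +
    rep(c(1L, 0L), c(pextra, n_proteins - pextra))

  structure(
    list(n_control = n_control, n_ad = n_ad, n_nonad = n_nonad,
         n_gis = n_gis, n_batches = n_batches, n_bio = n_bio,
         n_injections = n_inj,
         n_proteins = n_proteins, n_peptides = n_peptides,
         n_reference_peptides = n_reference_peptides,
         n_heavy_peptides = n_heavy_peptides,
         transitions_per_peptide = transitions_per_peptide,
         batch_sizes = batch_sizes, gis_per_batch = gis_per_batch,
         peptides_per_protein = peptides_per_protein),
    class = "prm_design")
}

#' @export
print.prm_design <- function(x, ...) {
  cat("<prm_design> ", x$n_bio, " biological (",
      x$n_control, " Control / ", x$n_ad, " AD / ", x$n_nonad, " NonAD) + ",
      x$n_gis, " GIS injections in ", x$n_batches, " batches; ",
      x$n_peptides, " peptides / ", x$n_proteins, " proteins, ",
      x$transitions_per_peptide, " transitions each\n", sep = "")
  invisible(x)
}

#' Ground-truth parameters for a simulated PRM study
#'
#' Fixes every generative parameter of [simulate_study()]: protein base
#' abundances, per-group log2 fold changes, peptide ionization response
#' factors, transition intensity shares, within-batch multiplicative drift,
#' log-scale measurement noise, age/sex covariate coefficients, and the
#' model linking immunoassay traits (A-beta-42, total Tau, phospho-Tau) to a
#' subset of proteins. Holding these in one object makes parameter-recovery
#' testing explicit: the pipeline's estimates can be compared against what
#' was injected.
#'
#' Defaults emulate the data-quality regime of a label-free multi-batch PRM
#' experiment: lognormal measurement noise with `noise_sd_log = 0.25`
#' (a coefficient of variation of `sqrt(exp(0.25^2)-1)`, about 25%), plus
#' within-batch exponential signal decay and batch-to-batch scale offsets
#' sized so that raw pooled-replicate CVs are roughly 40-45% and fall to the
#' high 20s after reference-standard drift correction.
#'
#' @param design A [study_design()].
#' @param effect_ad,effect_nonad Per-protein log2 fold change versus control.
#'   Scalars are recycled; `effect_ad = NULL` builds the default pattern:
#'   the first `n_affected` proteins increased by `effect_size` log2 units in
#'   AD, the rest null, and non-AD equal to control.
#' @param n_affected Number of AD-affected proteins in the default pattern
#'   (default: `round(25/41 * n_proteins)`, i.e. 25 of 41).
#' @param effect_size Default AD log2 fold change for affected proteins.
#' @param base_abundance Per-protein expected peak area in control samples
#'   (linear scale). Default spans 2e5 to 5e6.
#' @param peptide_response Per-peptide multiplicative ionization factor.
#' @param drift_rate Within-batch exponential decay rate per injection
#'   position; drift for position j is `batch_scale * exp(-drift_rate*(j-1))`.
#' @param batch_scales Per-batch multiplicative offsets (length `n_batches`).
#' @param noise_sd_log SD of peptide-level measurement noise on the natural
#'   log scale (must be >= 0).
#' @param transition_noise_sd SD of mean-one lognormal noise applied per
#'   transition, on top of the peptide-level value.
#' @param age_coef,sex_coef Per-protein covariate coefficients on the natural
#'   log scale (age centered at 70 years; sex coded 0/1). Scalars recycled.
#' @param trait_proteins Indices of the proteins driving the simulated
#'   immunoassay traits (total Tau, phospho-Tau, A-beta-42 respectively).
#' @param trait_coupling Coupling strength of traits to the standardized log
#'   protein level (A-beta-42 coupled negatively).
#' @param trait_noise_sd Log-scale SD of trait measurement noise.
#' @param heavy_amount Constant nominal spike amount for heavy standards.
#' @param reference_amounts Nominal amounts of the reference-mix peptides.
#' @param dropout_threshold Transition areas below this value are dropped
#'   (simple detection-limit censoring); 0 disables dropout.
#'
#' @return An object of class `prm_truth` (a validated parameter list).
#' @examples
#' truth <- ground_truth(study_design())
#' head(truth$effect_ad)
#' @export
ground_truth <- function(design,
                         effect_ad = NULL, effect_nonad = 0,
                         n_affected = NULL, effect_size = 0.8,
                         base_abundance = NULL,
                         peptide_response = NULL,
                         drift_rate = 0.025,
                         batch_scales = NULL,
                         noise_sd_log = 0.25,
                         transition_noise_sd = 0.05,
                         age_coef = 0.01, sex_coef = 0.05,
                         trait_proteins = c(1L, 2L, 3L),
                         trait_coupling = 0.9,
                         trait_noise_sd = 0.3,
                         heavy_amount = 5e5,
                         reference_amounts = NULL,
                         dropout_threshold = 0) {
  stopifnot(inherits(design, "prm_design"))
  np <- design$n_proteins
  npep <- design$n_peptides

  if (is.null(n_affected)) n_affected <- round(25 / 41 * np)
  if (is.null(effect_ad)) {
    effect_ad <- c(rep(effect_size, n_affected), rep(0, np - n_affected))
  }
  effect_ad <- rep_len(effect_ad, np)
  effect_nonad <- rep_len(effect_nonad, np)

  if (is.null(base_abundance)) {
    base_abundance <- exp(seq(log(2e5), log(5e6), length.out = np))
  }
  if (length(base_abundance) != np || any(base_abundance <= 0)) {
    stop("base_abundance must be ", np, " positive values", call. = FALSE)
  }
  if (is.null(peptide_response)) {
    peptide_response <- exp(seq(-0.7, 0.7, length.out = npep))
  }
  if (length(peptide_response) != npep || any(peptide_response <= 0)) {
    stop("peptide_response must be ", npep, " positive values", call. = FALSE)
  }
  if (is.null(batch_scales)) {
    batch_scales <- if (design$n_batches == 4) {
      c(1.45, 0.90, 1.15, 0.70)
    } else {
      exp(seq(0.37, -0.36, length.out = design$n_batches))
    }
  }
  if (length(batch_scales) != design$n_batches || any(batch_scales <= 0)) {
    stop("batch_scales must be ", design$n_batches, " positive values",
         call. = FALSE)
  }
  if (noise_sd_log < 0 || transition_noise_sd < 0 || trait_noise_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (drift_rate < 0) stop("drift_rate must be non-negative", call. = FALSE)
  if (any(trait_proteins < 1) || any(trait_proteins > np)) {
    stop("trait_proteins out of range 1..", np, call. = FALSE)
  }
  if (is.null(reference_amounts)) {
    reference_amounts <- exp(seq(log(2e5), log(2e6),
                                 length.out = design$n_reference_peptides))
  }
  if (length(reference_amounts) != design$n_reference_peptides ||
      any(reference_amounts <= 0)) {
    stop("reference_amounts must be ", design$n_reference_peptides,
         " positive values", call. = FALSE)
  }

  # transition intensity shares: decreasing simplex, identical per peptide
  tt <- design$transitions_per_peptide
  frac <- rev(seq_len(tt)) / sum(seq_len(tt))

  structure(
    list(effect_ad = effect_ad, effect_nonad = effect_nonad,
         base_abundance = base_abundance,
         peptide_response = peptide_response,
         transition_fractions = frac,
         drift_rate = drift_rate, batch_scales = batch_scales,
         noise_sd_log = noise_sd_log,
         transition_noise_sd = transition_noise_sd,
         age_coef = rep_len(age_coef, np), sex_coef = rep_len(sex_coef, np),
         trait_proteins = as.integer(trait_proteins),
         trait_coupling = trait_coupling, trait_noise_sd = trait_noise_sd,
         heavy_amount = heavy_amount,
         reference_amounts = reference_amounts,
         dropout_threshold = dropout_threshold),
    class = "prm_truth")
}

#' @export
print.prm_truth <- function(x, ...) {
  cat("<prm_truth> ", sum(x$effect_ad != 0), " AD-affected proteins (log2FC ",
      signif(max(abs(x$effect_ad)), 3), "); noise_sd_log = ", x$noise_sd_log,
      ", drift_rate = ", x$drift_rate, "\n", sep = "")
  invisible(x)
}
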