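#' Simulate a multi-batch PRM study with known ground truth
#'
#' Generates a complete label-free PRM experiment: a long-format transition
#' (product-ion) peak-area table, per-injection sample metadata with
#' immunoassay traits, and the [ground_truth()] parameters that produced it.
#' The generative model is multiplicative throughout, matching how targeted
#' MS peak areas behave:
#'
#' \deqn{A_{pep,j} = \exp(\mu_{prot} + \log(2)\,\beta_{group} + covariates)
#'       \times r_{pep} \times d(batch_j, position_j) \times \varepsilon}
#'
#' with lognormal measurement noise \eqn{\varepsilon}, per-peptide ionization
#' response \eqn{r}, and within-batch exponential drift \eqn{d}. Transition
#' areas split each peptide area by the peptide's intensity-share simplex,
#' with additional mean-one lognormal transition noise (so transition areas
#' sum to the peptide area in expectation, and exactly when
#' `transition_noise_sd = 0`). Heavy-labelled standards are spiked at a
#' constant nominal amount and carry the same drift and noise; reference-mix
#' peptides likewise, which is what makes drift estimable downstream. GIS
#' (pooled) injections receive, noise-free, the arithmetic mean of all
#' biological samples' peptide levels — exactly what a pool of equal aliquots
#' measures.
#'
#' @param design A [study_design()].
#' @param truth A [ground_truth()] built from the same design.
#' @param seed Integer seed; output is bit-identical for identical seeds.
#'
#' @return An object of class `prm_study`: a list with
#'   \describe{
#'     \item{transitions}{tibble of transition records: `sample_id`, `batch`,
#'       `injection_index`, `protein`, `peptide`, `charge`, `label`
#'       (light/heavy/reference), `fragment_ion`, `area`.}
#'     \item{metadata}{per-injection tibble: `sample_id`, `group`
#'       (Control/AD/NonAD/GIS), `age`, `sex`, `batch`, `injection_index`,
#'       `is_gis`, `abeta42`, `ttau`, `ptau`, `platform`.}
#'     \item{peptide_areas}{the noise-carrying peptide-level areas the
#'       transitions were split from (useful for conservation checks).}
#'     \item{truth, design}{the inputs, for parameter-recovery tests.}
#'   }
#' @examples
#' study <- simulate_study(seed = 1)
#' dplyr::count(study$metadata, group)
#' @export
simulate_study <- function(design = study_design(),
                           truth = ground_truth(design),
                           seed = 1L) {
  stopifnot(inherits(design, "prm_design"), inherits(truth, "prm_truth"))
  if (length(truth$effect_ad) != design$n_proteins ||
      length(truth$peptide_response) != design$n_peptides ||
      length(truth$batch_scales) != design$n_batches) {
    stop("ground truth dimensions do not match the study design",
         call. = FALSE)
  }
  withr::local_seed(as.integer(seed))

  np <- design$n_proteins
  npep <- design$n_peptides
  n_bio <- design$n_bio

  proteins <- sprintf("PROT%02d", seq_len(np))
  peptides <- tibble(
    peptide = sprintf("PEP%03d", seq_len(npep)),
    protein = rep(proteins, design$peptides_per_protein),
    protein_idx = rep(seq_len(np), design$peptides_per_protein),
    response = truth$peptide_response)

  ## ---- injection layout ----
  groups <- c(rep("Control", design$n_control), rep("AD", design$n_ad),
              rep("NonAD", design$n_nonad))
  bio <- tibble(
    bio_id = sprintf("S%03d", seq_len(n_bio)),
    group = groups,
    age = runif(n_bio, 55, 85),
    sex = rbinom(n_bio, 1, 0.5))
  bio_order <- sample.int(n_bio)            # randomized run order

  layout <- purrr::map(seq_len(design$n_batches), function(b) {
    size <- design$batch_sizes[b]
    g <- design$gis_per_batch[b]
    gis_pos <- unique(round(seq(1, size, length.out = g)))
    while (length(gis_pos) < g) {           # tiny batches: fill remaining slots
      gis_pos <- sort(union(gis_pos, setdiff(seq_len(size), gis_pos)[1]))
    }
    tibble(batch = sprintf("B%d", b), batch_idx = b,
           injection_index = seq_len(size),
           is_gis = seq_len(size) %in% gis_pos)
  })
  layout <- dplyr::bind_rows(layout)
  layout$sample_id <- NA_character_
  layout$sample_id[layout$is_gis] <- sprintf("GIS%02d", seq_len(design$n_gis))
  layout$sample_id[!layout$is_gis] <- bio$bio_id[bio_order]
  layout$drift <- truth$batch_scales[layout$batch_idx] *
    exp(-truth$drift_rate * (layout$injection_index - 1))

  metadata <- dplyr::left_join(layout, bio,
                               by = c(sample_id = "bio_id")) |>
    dplyr::mutate(group = dplyr::if_else(.data$is_gis, "GIS", .data$group)) |>
    dplyr::select("sample_id", "group", "age", "sex", "batch",
                  "injection_index", "is_gis")

  ## ---- noise-free protein levels (natural-log scale), bio samples ----
  E <- t(vapply(bio$group, function(g) {
    switch(g, AD = truth$effect_ad, NonAD = truth$effect_nonad, rep(0, np))
  }, numeric(np)))
  L <- matrix(log(truth$base_abundance), n_bio, np, byrow = TRUE) +
    log(2) * E +
    outer(bio$age - 70, truth$age_coef) + outer(bio$sex, truth$sex_coef)
  rownames(L) <- bio$bio_id
  gis_level <- colMeans(exp(L))             # exact pool property

  ## ---- immunoassay traits ----
  n_lum <- min(n_bio, round(0.76 * n_bio))
  platform <- rep("INNOTEST", n_bio)
  platform[sample.int(n_bio, n_lum)] <- "Luminex"
  zscore <- function(v) (v - mean(v)) / sd(v)
  tp <- truth$trait_proteins
  z <- lapply(seq_along(tp), function(k) zscore(L[, tp[k]]))
  cc <- truth$trait_coupling
  tn <- truth$trait_noise_sd
  ttau <- exp(log(150) + cc * z[[1]] + rnorm(n_bio, 0, tn))
  ptau <- exp(log(25) + cc * z[[min(2, length(z))]] + rnorm(n_bio, 0, tn))
  abeta <- exp(log(900) - cc * z[[min(3, length(z))]] + rnorm(n_bio, 0, tn))
  scale_fac <- ifelse(platform == "INNOTEST", 2.5, 1)
  trait_tbl <- tibble(sample_id = bio$bio_id,
                      abeta42 = abeta * scale_fac,
                      ttau = ttau * scale_fac,
                      ptau = ptau * scale_fac,
                      platform = platform)
  metadata <- dplyr::left_join(metadata, trait_tbl, by = "sample_id") |>
    as_tibble()

  ## ---- peptide-level areas ----
  inj <- metadata |>
    dplyr::select("sample_id", "group", "batch", "injection_index",
                  "is_gis") |>
    dplyr::mutate(drift = layout$drift)

  light <- tidyr::expand_grid(
    inj |> dplyr::select("sample_id", "batch", "injection_index", "is_gis",
                         "drift"),
    peptides |> dplyr::select("peptide", "protein", "protein_idx",
                              "response"))
  lev <- ifelse(light$is_gis, gis_level[light$protein_idx],
                exp(L[cbind(match(light$sample_id, rownames(L)),
                            light$protein_idx)]))
  light$expected <- lev * light$response * light$drift
  light$label <- "light"

  heavy_pep <- peptides[seq_len(design$n_heavy_peptides), ]
  heavy <- tidyr::expand_grid(
    inj |> dplyr::select("sample_id", "batch", "injection_index", "is_gis",
                         "drift"),
    heavy_pep |> dplyr::select("peptide", "protein", "protein_idx",
                               "response"))
  heavy$expected <- truth$heavy_amount * heavy$response * heavy$drift
  heavy$label <- "heavy"

  refs <- tibble(peptide = sprintf("REF%d", seq_len(design$n_reference_peptides)),
                 protein = "REFMIX", protein_idx = NA_integer_,
                 response = 1, amount = truth$reference_amounts)
  ref <- tidyr::expand_grid(
    inj |> dplyr::select("sample_id", "batch", "injection_index", "is_gis",
                         "drift"),
    refs)
  ref$expected <- ref$amount * ref$drift
  ref$label <- "reference"
  ref$amount <- NULL

  pep_areas <- dplyr::bind_rows(light, heavy, ref)
  pep_areas$area <- pep_areas$expected *
    exp(rnorm(nrow(pep_areas), 0, truth$noise_sd_log))

  ## ---- split into transitions ----
  tt <- design$transitions_per_peptide
  frac_tbl <- tibble(fragment_ion = sprintf("y%d", 2 + seq_len(tt)),
                     fraction = truth$transition_fractions)
  transitions <- tidyr::expand_grid(
    pep_areas |> dplyr::select("sample_id", "batch", "injection_index",
                               "protein", "peptide", "label", "area"),
    frac_tbl)
  s <- truth$transition_noise_sd
  tnoise <- if (s > 0) {
    exp(rnorm(nrow(transitions), 0, s) - s^2 / 2)   # mean-one lognormal
  } else 1
  transitions <- transitions |>
    dplyr::mutate(charge = 2L,
                  area = .data$area * .data$fraction * tnoise) |>
    dplyr::select("sample_id", "batch", "injection_index", "protein",
                  "peptide", "charge", "label", "fragment_ion", "area")
  if (truth$dropout_threshold > 0) {
    transitions <- dplyr::filter(transitions,
                                 .data$area >= truth$dropout_threshold)
  }

  structure(
    list(transitions = transitions,
         metadata = metadata,
         peptide_areas = pep_areas |>
           dplyr::select("sample_id", "batch", "injection_index", "protein",
                         "peptide", "label", "area") |> as_tibble(),
         truth = truth, design = design, seed = as.integer(seed)),
    class = "prm_study")
}

#' @export
print.prm_study <- function(x, ...) {
  cat("<prm_study> ", nrow(x$metadata), " injections (",
      sum(!x$metadata$is_gis), " biological + ", sum(x$metadata$is_gis),
      " GIS), ", x$design$n_peptides, " target peptides / ",
      x$design$n_proteins, " proteins, ",
      nrow(x$transitions), " transition records [seed ", x$seed, "]\n",
      sep = "")
  invisible(x)
}

#' Spectral-library relative intensities of the simulated targets
#'
#' Returns the library each simulated peptide was generated from: fragment
#' ions with relative intensities normalized so the strongest ion is 1.
#' Useful as the reference side of [dotp()].
#'
#' @param study A `prm_study` from [simulate_study()].
#' @return Tibble with `peptide`, `fragment_ion`, `rel_intensity`.
#' @export
spectral_library <- function(study) {
  stopifnot(inherits(study, "prm_study"))
  tt <- study$design$transitions_per_peptide
  frac <- study$truth$transition_fractions
  tidyr::expand_grid(
    peptide = sprintf("PEP%03d", seq_len(study$design$n_peptides)),
    tibble(fragment_ion = sprintf("y%d", 2 + seq_len(tt)),
           rel_intensity = frac / max(frac)))
}
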