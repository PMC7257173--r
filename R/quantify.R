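#' Sum product-ion areas into peptide-level quantities
#'
#' The quantification unit of label-free PRM is the transition (product-ion)
#' chromatographic peak area; the peptide-level "raw peak area" is the sum of
#' all its monitored product-ion areas within an injection. Peptides with no
#' observed transitions in an injection are simply absent from the output
#' (missing, never zero-filled): summing observed signal must not invent
#' intensity.
#'
#' @param transitions Tibble of transition records (columns `sample_id`,
#'   `protein`, `peptide`, `label`, `fragment_ion`, `area`; `batch` and
#'   `injection_index` are carried through when present).
#' @param label Which label channel to sum (default `"light"`, the endogenous
#'   signal; use `"reference"` or `"heavy"` for standards).
#'
#' @return Tibble with one row per (sample, peptide): `sample_id`,
#'   (`batch`, `injection_index`,) `protein`, `peptide`, `raw_area`,
#'   `n_transitions`.
#' @examples
#' study <- simulate_study(seed = 1)
#' sum_transitions(study$transitions)
#' @export
sum_transitions <- function(transitions, label = "light") {
  required_columns(transitions, c("sample_id", "protein", "peptide",
                                  "label", "fragment_ion", "area"))
  carry <- intersect(c("batch", "injection_index"), names(transitions))
  transitions |>
    dplyr::filter(.data$label == .env$label, !is.na(.data$area)) |>
    dplyr::summarise(raw_area = sum(.data$area),
                     n_transitions = dplyr::n(),
                     .by = dplyr::all_of(c("sample_id", carry, "protein",
                                           "peptide"))) |>
    as_tibble()
}

#' Spectral-library dot product (dotp) of an observed transition pattern
#'
#' Cosine similarity between the observed product-ion intensity pattern and
#' the spectral-library pattern for the same peptide, computed by default on
#' square-root-transformed intensities (the convention of the mainstream
#' targeted-proteomics software this mirrors; set `transform = "none"` for a
#' plain-intensity cosine). Vectors are aligned on the union of fragment-ion
#' names; an ion present in only one pattern contributes intensity 0 to the
#' other, so disjoint patterns score 0 and proportional patterns score 1.
#'
#' @param observed Named numeric vector of observed transition areas (names
#'   are fragment-ion labels), or a two-column data frame
#'   (`fragment_ion`, `area`).
#' @param library Named numeric vector (or `fragment_ion`/`rel_intensity`
#'   data frame) of library relative intensities.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return A value in \[0, 1\], or `NA` if the observed pattern is all zero.
#' @examples
#' dotp(c(y4 = 8, y5 = 2, y6 = 2), c(y4 = 4, y5 = 1, y6 = 1))  # 1
#' @export
dotp <- function(observed, library, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  obs <- as_ion_vector(observed, c("area", "intensity", "rel_intensity"))
  lib <- as_ion_vector(library, c("rel_intensity", "intensity", "area"))
  ions <- union(names(obs), names(lib))
  x <- ifelse(ions %in% names(obs), obs[ions], 0)
  y <- ifelse(ions %in% names(lib), lib[ions], 0)
  if (all(x == 0)) return(NA_real_)
  if (all(y == 0)) return(NA_real_)
  if (transform == "sqrt") {
    x <- sqrt(x)
    y <- sqrt(y)
  }
  min(1, max(0, sum(x * y) / sqrt(sum(x^2) * sum(y^2))))
}

#' Ratio dot product (rdotp) between light and heavy transition patterns
#'
#' Same cosine-type similarity as [dotp()], but comparing the endogenous
#' (light) product-ion pattern against the co-eluting heavy-standard pattern
#' of the same peptide. Values near 1 indicate the endogenous signal has the
#' fragmentation pattern of the authentic peptide rather than an
#' interference.
#'
#' @param light,heavy Named intensity vectors (or `fragment_ion`/`area`
#'   data frames) for the two label channels.
#' @inheritParams dotp
#' @return A value in \[0, 1\], or `NA` if either pattern is all zero.
#' @export
rdotp <- function(light, heavy, transform = c("sqrt", "none")) {
  dotp(light, heavy, transform = match.arg(transform))
}

as_ion_vector <- function(x, value_cols) {
  if (is.data.frame(x)) {
    vcol <- intersect(value_cols, names(x))[1]
    if (is.na(vcol) || !"fragment_ion" %in% names(x)) {
      stop("data-frame intensity patterns need a 'fragment_ion' column and ",
           "one of: ", paste(value_cols, collapse = ", "), call. = FALSE)
    }
    x <- setNames(x[[vcol]], x$fragment_ion)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("intensity vectors must be named by fragment ion", call. = FALSE)
  }
  if (any(x < 0, na.rm = TRUE)) stop("intensities must be >= 0", call. = FALSE)
  x[!is.na(x)]
}

#' Light/heavy peak-area ratio
#'
#' The endogenous (light) peptide peak area divided by the co-eluting
#' heavy-standard area. With the heavy standard spiked at a known constant
#' amount this is an internally calibrated measure of the endogenous level.
#'
#' @param light_area,heavy_area Numeric vectors of summed peak areas.
#' @return `light_area / heavy_area`; `NA` with a warning where the heavy
#'   area is missing or non-positive.
#' @examples
#' light_heavy_ratio(5e4, 5e4)  # 1
#' @export
light_heavy_ratio <- function(light_area, heavy_area) {
  bad <- is.na(heavy_area) | heavy_area <= 0
  if (any(bad)) {
    warning(sum(bad), " ratio(s) undefined: heavy area missing or <= 0",
            call. = FALSE)
  }
  ifelse(bad, NA_real_, light_area / heavy_area)
}

#' Call APOE genotype from allele-specific peptide signals
#'
#' The E2 and E4 apolipoprotein-E variants each produce a variant-specific
#' tryptic peptide; E3 produces neither. Detection of a variant peptide
#' (area at or above `threshold`) implies at least one copy of that allele;
#' when at most one variant allele is detected the complementary allele is
#' inferred to be E3 (a single-allele assumption: homozygous variant carriers
#' are indistinguishable from heterozygous E3 carriers by presence/absence
#' alone). Both variants detected reports E2/E4.
#'
#' @param e2_area,e4_area Numeric vectors of the APOE2- and APOE4-specific
#'   peptide areas per sample (`NA` treated as not detected).
#' @param threshold Detection threshold on the peak-area scale. No published
#'   convention exists for presence calling here; the default in
#'   [run_all()]-style use is 5x a blank-level area supplied by the caller.
#' @return Character vector of genotype calls:
#'   `"E3/E3"`, `"E2/E3"`, `"E3/E4"` or `"E2/E4"`.
#' @examples
#' apoe_genotype(c(0, 1e5, 0, 1e5), c(0, 0, 1e5, 1e5), threshold = 1e4)
#' @export
apoe_genotype <- function(e2_area, e4_area, threshold) {
  stopifnot(length(threshold) == 1, threshold > 0)
  e2 <- !is.na(e2_area) & e2_area >= threshold
  e4 <- !is.na(e4_area) & e4_area >= threshold
  dplyr::case_when(
    e2 & e4 ~ "E2/E4",
    e2 ~ "E2/E3",
    e4 ~ "E3/E4",
    .default = "E3/E3")
}

required_columns <- function(x, cols) {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
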