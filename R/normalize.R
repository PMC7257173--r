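#' Per-injection drift factors from spiked reference standards
#'
#' Reference peptides are spiked into every digest at the same nominal
#' amount, so any systematic change in their measured areas across
#' injections reflects instrument signal drift and loading variance rather
#' than biology. The factor for injection *j* is the geometric mean, over
#' reference peptides *r*, of `area[r, j] / median_j(area[r, j])`: a
#' median-scaled consensus that is robust to one aberrant standard.
#' Dividing every area in injection *j* by `factor_j` removes the common
#' multiplicative drift.
#'
#' @param reference_quant Tibble of reference-peptide quantities per
#'   injection, e.g. `sum_transitions(transitions, label = "reference")`.
#'   Needs columns `sample_id`, `peptide` and the value column.
#' @param value_col Name of the area column (default `"raw_area"`).
#'
#' @return Tibble with `sample_id` and `drift_factor` (one row per
#'   injection). Errors, naming the injection, if an injection has no
#'   reference peptide measured.
#' @examples
#' study <- simulate_study(seed = 1)
#' refs <- sum_transitions(study$transitions, label = "reference")
#' drift_factors(refs)
#' @export
drift_factors <- function(reference_quant, value_col = "raw_area") {
  required_columns(reference_quant, c("sample_id", "peptide", value_col))
  df <- reference_quant |>
    dplyr::rename(.area = dplyr::all_of(value_col)) |>
    dplyr::filter(!is.na(.data$.area))
  if (any(df$.area <= 0)) {
    stop("reference areas must be positive", call. = FALSE)
  }
  all_inj <- unique(reference_quant$sample_id)
  empty <- setdiff(all_inj, unique(df$sample_id))
  if (length(empty)) {
    stop("no reference peptide measured in injection(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  df |>
    dplyr::mutate(ratio = .data$.area / median(.data$.area),
                  .by = "peptide") |>
    dplyr::summarise(drift_factor = exp(mean(log(.data$ratio))),
                     .by = "sample_id") |>
    as_tibble()
}

#' Apply drift correction to peptide quantities
#'
#' Divides each peptide area by its injection's [drift_factors()] estimate.
#'
#' @param peptide_quant Peptide-level tibble from [sum_transitions()].
#' @param factors Tibble from [drift_factors()].
#' @param value_col Column to correct (default `"raw_area"`).
#' @return Input tibble with an added `norm_area` column (stage:
#'   drift-corrected).
#' @export
apply_drift_correction <- function(peptide_quant, factors,
                                   value_col = "raw_area") {
  required_columns(peptide_quant, c("sample_id", value_col))
  required_columns(factors, c("sample_id", "drift_factor"))
  miss <- setdiff(unique(peptide_quant$sample_id), factors$sample_id)
  if (length(miss)) {
    stop("no drift factor for injection(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- peptide_quant |>
    dplyr::left_join(factors, by = "sample_id") |>
    dplyr::mutate(norm_area = .data[[value_col]] / .data$drift_factor) |>
    dplyr::select(-"drift_factor") |>
    as_tibble()
  attr(out, "stage") <- "drift_corrected"
  out
}

#' Roll peptide quantities up to proteins
#'
#' A protein's abundance is the sum of its observed (drift-corrected)
#' peptide areas within an injection. Peptides missing from an injection are
#' excluded, not zero-filled; a protein appears for an injection only if at
#' least one of its peptides was observed. Targets are assumed proteotypic:
#' a peptide mapping to more than one protein is a configuration error.
#'
#' @param peptide_quant Tibble with `sample_id`, `protein`, `peptide` and a
#'   value column; `batch`/`injection_index` carried through when present.
#' @param value_col Peptide value column to sum (default `"norm_area"`).
#' @return Tibble with one row per (sample, protein): `abundance`,
#'   `n_peptides`.
#' @export
rollup_protein <- function(peptide_quant, value_col = "norm_area") {
  required_columns(peptide_quant, c("sample_id", "protein", "peptide",
                                    value_col))
  multi <- peptide_quant |>
    dplyr::distinct(.data$peptide, .data$protein) |>
    dplyr::count(.data$peptide) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    stop("peptide(s) mapped to more than one protein: ",
         paste(multi$peptide, collapse = ", "), call. = FALSE)
  }
  carry <- intersect(c("batch", "injection_index"), names(peptide_quant))
  out <- peptide_quant |>
    dplyr::filter(!is.na(.data[[value_col]])) |>
    dplyr::summarise(abundance = sum(.data[[value_col]]),
                     n_peptides = dplyr::n_distinct(.data$peptide),
                     .by = dplyr::all_of(c("sample_id", carry, "protein"))) |>
    as_tibble()
  attr(out, "stage") <- "protein"
  out
}

#' Normalize protein abundances against pooled GIS injections
#'
#' Divides each protein value by the mean of the pooled
#' global-internal-standard (GIS) injections of the same batch, turning
#' abundances into ratios-to-pool and removing batch-scale differences. By
#' construction the GIS injections' ratios average exactly 1 per batch for
#' every protein. Set `scope = "global"` to normalize against the mean of
#' all GIS injections instead (a single pool anchor for the whole study).
#'
#' @param protein_quant Tibble from [rollup_protein()] (columns `sample_id`,
#'   `protein`, value column).
#' @param metadata Sample metadata with `sample_id` and `is_gis` (and
#'   `batch` for the default scope).
#' @param value_col Value column to normalize (default `"abundance"`).
#' @param scope `"batch"` (default) or `"global"`.
#' @return Input tibble with an added `ratio` column (stage: GIS ratio).
#'   Errors if a protein has no usable GIS mean in some batch.
#' @export
gis_normalize <- function(protein_quant, metadata, value_col = "abundance",
                          scope = c("batch", "global")) {
  scope <- match.arg(scope)
  required_columns(protein_quant, c("sample_id", "protein", value_col))
  required_columns(metadata, c("sample_id", "is_gis"))
  meta_cols <- c("sample_id", "is_gis", if (scope == "batch") "batch")
  df <- protein_quant |>
    dplyr::left_join(metadata |> dplyr::select(dplyr::all_of(meta_cols)),
                     by = "sample_id",
                     suffix = c("", ".meta"))
  if ("batch.meta" %in% names(df)) {
    df$batch <- df$batch.meta
    df$batch.meta <- NULL
  }
  by <- c("protein", if (scope == "batch") "batch")
  gis_means <- df |>
    dplyr::filter(.data$is_gis, !is.na(.data[[value_col]])) |>
    dplyr::summarise(.gis_mean = mean(.data[[value_col]]),
                     .by = dplyr::all_of(by))
  bad <- dplyr::filter(gis_means, !is.finite(.data$.gis_mean) |
                         .data$.gis_mean <= 0)
  if (nrow(bad)) {
    stop("GIS mean missing or non-positive for: ",
         paste(paste0(bad$protein,
                      if (scope == "batch") paste0(" [", bad$batch, "]")),
               collapse = ", "), call. = FALSE)
  }
  expected <- df |> dplyr::distinct(dplyr::pick(dplyr::all_of(by)))
  missing_b <- dplyr::anti_join(expected, gis_means, by = by)
  if (nrow(missing_b)) {
    stop("no GIS injection observed for: ",
         paste(paste0(missing_b$protein,
                      if (scope == "batch") paste0(" [", missing_b$batch, "]")),
               collapse = ", "), call. = FALSE)
  }
  out <- df |>
    dplyr::left_join(gis_means, by = by) |>
    dplyr::mutate(ratio = .data[[value_col]] / .data$.gis_mean) |>
    dplyr::select(-".gis_mean", -"is_gis") |>
    as_tibble()
  attr(out, "stage") <- "gis_ratio"
  out
}

#' Coefficient of variation of replicate measurements
#'
#' `CV% = 100 * sd(x) / mean(x)` on the linear (unlogged) scale, the
#' conventional precision measure for replicate injections of a pooled
#' standard.
#'
#' @param values Numeric replicate measurements (`NA` dropped).
#' @return CV in percent; `NA` if fewer than 2 replicates remain or the
#'   mean is not positive.
#' @examples
#' compute_cv(c(90, 100, 110))  # 10
#' @export
compute_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  100 * sd(values) / m
}

#' Per-feature CV across pooled GIS injections
#'
#' Computes [compute_cv()] for every peptide (or protein) across the GIS
#' replicate injections, the study's measure of technical precision, and
#' flags features quantified with high precision (CV at or below
#' `precision_threshold`, by convention 30%).
#'
#' @param quant Tibble with `sample_id`, a feature column (`peptide` if
#'   present, else `protein`) and the value column.
#' @param metadata Metadata with `sample_id`, `is_gis`.
#' @param value_col Which value column to assess.
#' @param precision_threshold CV% cutoff separating high from low precision.
#' @return Tibble with the feature column, `n_replicates`, `cv`,
#'   `high_precision`.
#' @export
gis_cv <- function(quant, metadata, value_col, precision_threshold = 30) {
  required_columns(quant, c("sample_id", value_col))
  required_columns(metadata, c("sample_id", "is_gis"))
  feature <- if ("peptide" %in% names(quant)) "peptide" else "protein"
  gis_ids <- metadata$sample_id[metadata$is_gis]
  quant |>
    dplyr::filter(.data$sample_id %in% gis_ids) |>
    dplyr::summarise(n_replicates = sum(!is.na(.data[[value_col]])),
                     cv = compute_cv(.data[[value_col]]),
                     .by = dplyr::all_of(feature)) |>
    dplyr::mutate(high_precision = !is.na(.data$cv) &
                    .data$cv <= precision_threshold) |>
    as_tibble()
}

#' Regress age and sex out of protein log2 ratios
#'
#' Fits, per protein, an ordinary-least-squares model
#' `log2(ratio) ~ age + sex` across the biological samples and returns the
#' residuals, which by construction have mean exactly zero per protein and
#' zero sample covariance with the fitted covariates. GIS injections are
#' excluded. A covariate with a single observed level (e.g. one sex) is
#' dropped with a warning rather than producing a rank-deficient fit.
#'
#' @param protein_ratios Tibble from [gis_normalize()] (columns `sample_id`,
#'   `protein`, value column).
#' @param metadata Metadata with `sample_id`, `is_gis`, `age`, `sex`.
#' @param value_col Ratio column (default `"ratio"`).
#' @param log2_transform Log2-transform values before regression (default
#'   TRUE; set FALSE if the input is already on the log2 scale).
#' @return Tibble `sample_id`, `protein`, `value` — centered, regressed log2
#'   abundances (stage: regressed log2).
#' @export
regress_covariates <- function(protein_ratios, metadata,
                               value_col = "ratio", log2_transform = TRUE) {
  required_columns(protein_ratios, c("sample_id", "protein", value_col))
  required_columns(metadata, c("sample_id", "is_gis", "age", "sex"))
  bio <- metadata |> dplyr::filter(!.data$is_gis)
  df <- protein_ratios |>
    dplyr::inner_join(bio |> dplyr::select("sample_id", "age", "sex"),
                      by = "sample_id")
  if (anyNA(df$age) || anyNA(df$sex)) {
    stop("age/sex missing for included biological samples", call. = FALSE)
  }
  v <- df[[value_col]]
  if (log2_transform) {
    if (any(v <= 0, na.rm = TRUE)) {
      stop("values must be positive for log2 transformation", call. = FALSE)
    }
    v <- log2(v)
  }
  df$.value <- v

  covars <- c("age", "sex")
  degenerate <- covars[vapply(covars,
                              function(cv) length(unique(df[[cv]])) < 2,
                              logical(1))]
  if (length(degenerate)) {
    warning("covariate(s) with a single level dropped from regression: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
    covars <- setdiff(covars, degenerate)
  }
  form <- stats::reformulate(if (length(covars)) covars else "1",
                             response = ".value")
  out <- df |>
    dplyr::filter(!is.na(.data$.value)) |>
    dplyr::mutate(value = unname(resid(lm(form,
                                          data = dplyr::pick(dplyr::everything())))),
                  .by = "protein") |>
    dplyr::select("sample_id", "protein", "value") |>
    as_tibble()
  attr(out, "stage") <- "regressed_log2"
  out
}
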