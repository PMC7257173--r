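#' Pipeline configuration
#'
#' Collects the tunable thresholds of the full analysis in one validated
#' object: the CV precision cutoff (percent), the FDR level for the
#' differential flag, the A-beta/Tau ratio positivity cutoff, the number of
#' cross-validation folds, the immunoassay platform restriction for
#' trait-linked analyses, the GIS normalization scope, and the correlation
#' method.
#'
#' @param cv_threshold CV% above which a feature is low precision
#'   (default 30).
#' @param fdr_alpha FDR level for the differential significance flag
#'   (default 0.05).
#' @param ratio_threshold A-beta-42/total-Tau positivity cutoff
#'   (default 4.6).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed used for fold assignment.
#' @param platform Immunoassay platform for trait correlations and the
#'   ratio task (default `"Luminex"`; `NULL` = all samples).
#' @param gis_scope `"batch"` or `"global"` (see [gis_normalize()]).
#' @param cor_method `"bicor"` or `"pearson"` for trait correlations.
#' @return A list of class `prm_config`.
#' @export
pipeline_config <- function(cv_threshold = 30, fdr_alpha = 0.05,
                            ratio_threshold = 4.6, folds = 5, seed = 1L,
                            platform = "Luminex",
                            gis_scope = c("batch", "global"),
                            cor_method = c("bicor", "pearson")) {
  stopifnot(cv_threshold > 0, fdr_alpha > 0, fdr_alpha < 1,
            ratio_threshold > 0, folds >= 2)
  structure(
    list(cv_threshold = cv_threshold, fdr_alpha = fdr_alpha,
         ratio_threshold = ratio_threshold, folds = as.integer(folds),
         seed = as.integer(seed), platform = platform,
         gis_scope = match.arg(gis_scope),
         cor_method = match.arg(cor_method)),
    class = "prm_config")
}

# small FNV-1a digest so output headers can record which config produced them
# (arithmetic kept in doubles: R integers overflow at 2^31)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((lo * 16777619) %% 2^32 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full PRM analysis pipeline
#'
#' Executes every stage in order on a study (simulated or read from disk):
#' transition summation, reference-standard drift correction, GIS-replicate
#' CV QC (before and after correction), protein roll-up, per-batch GIS
#' normalization, log2 transformation with age/sex regression, differential
#' abundance (ANOVA + Tukey + BH FDR), trait correlations, and per-protein
#' cross-validated ROC analysis for the three classification tasks. A stage
#' failure halts the run with the stage name and cause.
#'
#' @param study A `prm_study` from [simulate_study()], or any list with
#'   `transitions` and `metadata` tibbles (e.g. assembled from
#'   [read_transition_report()] and [read_sample_metadata()]).
#' @param config A [pipeline_config()].
#' @param seed Optional override of `config$seed`.
#' @param tasks Which ROC tasks to run (default all three).
#' @param discovery_log2fc Optional named numeric vector of per-protein
#'   discovery-cohort log2 fold changes; when supplied, replication/
#'   discovery concordance is computed via [cohort_concordance()].
#' @return An object of class `prm_run`: a list of stage outputs
#'   (`peptide_raw`, `drift`, `peptide_norm`, `qc`, `protein`,
#'   `protein_ratio`, `regressed`, `differential`, `correlations`, `roc`,
#'   optionally `concordance`) plus a `summary` tibble and the `config`.
#' @examples
#' run <- simulate_study(seed = 1) |> run_all(seed = 1)
#' run$summary
#' @export
run_all <- function(study, config = pipeline_config(), seed = NULL,
                    tasks = c("ad_vs_control", "ad_vs_nonad",
                              "abeta_tau_ratio"),
                    discovery_log2fc = NULL) {
  stopifnot(inherits(config, "prm_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  tasks <- match.arg(tasks, several.ok = TRUE)
  transitions <- study$transitions
  metadata <- study$metadata
  if (is.null(transitions) || is.null(metadata)) {
    stop("study must provide 'transitions' and 'metadata'", call. = FALSE)
  }
  if (!"is_gis" %in% names(metadata)) {
    metadata$is_gis <- metadata$group == "GIS"
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  peptide_raw <- stage("quantify", sum_transitions(transitions, "light"))
  ref_quant <- stage("quantify",
                     sum_transitions(transitions, "reference"))
  drift <- stage("drift_correction", drift_factors(ref_quant))
  peptide_norm <- stage("drift_correction",
                        apply_drift_correction(peptide_raw, drift))

  qc <- stage("qc", dplyr::bind_rows(
    gis_cv(peptide_raw, metadata, "raw_area", config$cv_threshold) |>
      dplyr::mutate(level = "peptide", stage = "raw"),
    gis_cv(peptide_norm, metadata, "norm_area", config$cv_threshold) |>
      dplyr::mutate(level = "peptide", stage = "normalized")))

  protein <- stage("rollup", rollup_protein(peptide_norm))
  protein_ratio <- stage("gis_normalization",
                         gis_normalize(protein, metadata,
                                       scope = config$gis_scope))
  qc <- dplyr::bind_rows(
    qc,
    stage("qc", gis_cv(protein_ratio |> dplyr::select(-"n_peptides"),
                       metadata, "ratio", config$cv_threshold)) |>
      dplyr::mutate(level = "protein", stage = "normalized"))
  qc <- qc |>
    dplyr::mutate(feature = dplyr::coalesce(.data$peptide, .data$protein)) |>
    dplyr::select("feature", "level", "stage", "n_replicates", "cv",
                  "high_precision")

  regressed <- stage("covariate_regression",
                     regress_covariates(protein_ratio, metadata))
  differential <- stage("differential",
                        diff_test(regressed, metadata,
                                  alpha = config$fdr_alpha))
  correlations <- if (all(c("abeta42", "ttau", "ptau") %in%
                          names(metadata))) {
    stage("trait_correlation",
          correlate_traits(regressed, metadata,
                           method = config$cor_method,
                           platform = config$platform))
  }
  roc <- stage("classification", dplyr::bind_rows(lapply(tasks, function(tk) {
    classify_proteins(regressed, metadata, task = tk,
                      threshold = config$ratio_threshold,
                      platform = config$platform,
                      k = config$folds, seed = config$seed)
  })))

  concordance <- if (!is.null(discovery_log2fc)) {
    stage("concordance", {
      shared <- intersect(differential$protein, names(discovery_log2fc))
      cohort_concordance(
        differential$log2fc_ad_vs_control[match(shared,
                                                differential$protein)],
        discovery_log2fc[shared], proteins = shared)
    })
  }

  top_auc <- roc |>
    dplyr::slice_max(.data$auc, n = 1, by = "task", with_ties = FALSE)
  prot_qc <- qc |> dplyr::filter(.data$level == "protein")
  summary <- tibble(
    metric = c("n_peptides", "n_proteins", "n_biological_samples",
               "n_gis_injections",
               "mean_peptide_gis_cv_raw", "mean_peptide_gis_cv_normalized",
               "mean_protein_gis_cv", "pct_proteins_high_precision",
               "n_significant_proteins",
               paste0("top_auc_", top_auc$task)),
    value = c(dplyr::n_distinct(peptide_raw$peptide),
              dplyr::n_distinct(protein$protein),
              sum(!metadata$is_gis), sum(metadata$is_gis),
              mean(qc$cv[qc$level == "peptide" & qc$stage == "raw"],
                   na.rm = TRUE),
              mean(qc$cv[qc$level == "peptide" & qc$stage == "normalized"],
                   na.rm = TRUE),
              mean(prot_qc$cv, na.rm = TRUE),
              100 * mean(prot_qc$high_precision),
              sum(differential$significant, na.rm = TRUE),
              top_auc$auc))

  structure(
    list(peptide_raw = peptide_raw, drift = drift,
         peptide_norm = peptide_norm, qc = qc, protein = protein,
         protein_ratio = protein_ratio, regressed = regressed,
         differential = differential, correlations = correlations,
         roc = roc, concordance = concordance, summary = summary,
         config = config, seed = config$seed,
         config_hash = config_hash(config)),
    class = "prm_run")
}

#' @export
print.prm_run <- function(x, ...) {
  cat("<prm_run> seed ", x$seed, ", config ", x$config_hash, "\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-32s %s\n", s$metric[i], signif(s$value[i], 4)))
  }
  invisible(x)
}

#' Write all pipeline stage outputs to a directory
#'
#' Mirrors the supplementary-table layout of a targeted-proteomics report:
#' normalized peptide areas, protein ratios, regressed log2 values, QC CVs,
#' differential results, trait correlations and per-protein AUCs, each CSV
#' carrying a provenance header (version, seed, config hash).
#'
#' @param run A `prm_run` from [run_all()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "prm_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) {
    if (!is.null(x)) {
      write_prm_csv(x, file.path(dir, name), seed = run$seed,
                    config_hash = run$config_hash)
    }
  }
  w(run$peptide_norm, "peptide_normalized.csv")
  w(run$protein_ratio, "protein_normalized.csv")
  w(run$regressed, "protein_regressed.csv")
  w(run$qc, "qc_cv.csv")
  w(run$differential, "differential.csv")
  w(run$correlations, "trait_correlations.csv")
  w(run$roc, "roc_auc.csv")
  w(run$summary, "summary.csv")
  invisible(dir)
}
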