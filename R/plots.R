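#' Plot a cross-validated ROC curve
#'
#' @param object A `prm_roc` from [train_cv_classifier()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.prm_roc <- function(object, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%d-fold CV logistic ROC, AUC = %.3f",
                                  object$folds, object$auc)) +
    ggplot2::theme_minimal()
}

#' Histogram of GIS-replicate CVs by stage
#'
#' Recreates the standard precision-QC view: the distribution of per-feature
#' coefficients of variation across pooled GIS injections, faceted by
#' normalization stage, with the precision threshold marked.
#'
#' @param qc QC tibble (e.g. `run$qc` from [run_all()]) with columns
#'   `feature`, `level`, `stage`, `cv`.
#' @param threshold CV% precision cutoff line (default 30).
#' @return A ggplot.
#' @export
plot_cv_histogram <- function(qc, threshold = 30) {
  required_columns(qc, c("level", "stage", "cv"))
  df <- qc |>
    dplyr::filter(!is.na(.data$cv)) |>
    dplyr::mutate(panel = paste(.data$level, .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cv)) +
    ggplot2::geom_histogram(bins = 25, fill = "#74ADD1",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "#B2182B") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "CV across GIS injections (%)", y = "Features") +
    ggplot2::theme_minimal()
}

#' Discovery/replication concordance scatter plot
#'
#' @param concordance A `prm_concordance` from [cohort_concordance()].
#' @return A ggplot of replication versus discovery log2 fold changes with
#'   the fitted line.
#' @export
plot_concordance <- function(concordance) {
  stopifnot(inherits(concordance, "prm_concordance"))
  pts <- attr(concordance, "points")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$discovery,
                                    y = .data$replication)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(colour = "#2166AC", alpha = 0.8) +
    ggplot2::geom_abline(slope = concordance$slope,
                         intercept = concordance$intercept,
                         colour = "#B2182B") +
    ggplot2::labs(x = "Discovery log2 fold change",
                  y = "Replication log2 fold change",
                  title = sprintf("cor = %.2f, p = %.2g",
                                  concordance$cor, concordance$p_value)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential abundance results
#'
#' @param differential Result tibble from [diff_test()].
#' @param alpha Significance level for the horizontal guide (default 0.05).
#' @return A ggplot of AD-vs-control log2 fold change against -log10 ANOVA
#'   p, significant proteins highlighted.
#' @export
plot_volcano <- function(differential, alpha = 0.05) {
  required_columns(differential, c("log2fc_ad_vs_control", "p_anova",
                                   "significant"))
  ggplot2::ggplot(differential,
                  ggplot2::aes(x = .data$log2fc_ad_vs_control,
                               y = -log10(.data$p_anova),
                               colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.85) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#B2182B"),
                                 name = "AD-specific") +
    ggplot2::labs(x = "log2 fold change (AD vs control)",
                  y = "-log10 ANOVA p") +
    ggplot2::theme_minimal()
}
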