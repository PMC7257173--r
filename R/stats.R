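#' Differential abundance across diagnostic groups
#'
#' Per protein: one-way ANOVA across the diagnostic groups on the regressed
#' log2 abundances, Tukey HSD post hoc pairwise comparisons, and
#' Benjamini-Hochberg FDR adjustment of the ANOVA p values across the
#' protein family. A protein is flagged `significant` when its ANOVA q value
#' is below `alpha`, both AD contrasts (AD vs Control and AD vs non-AD) pass
#' Tukey-adjusted `alpha`, and the AD group mean is consistently the highest
#' (or lowest) of the three — the definition of an AD-specific marker.
#'
#' @param data Regressed abundance tibble (`sample_id`, `protein`, `value`),
#'   e.g. from [regress_covariates()].
#' @param metadata Metadata with `sample_id` and `group`; GIS injections are
#'   excluded automatically.
#' @param alpha Significance level for the flag (default 0.05).
#' @return Tibble with one row per protein: group means and standard errors,
#'   `log2fc_ad_vs_control`, `f_statistic`, `p_anova`, `q_anova`,
#'   Tukey-adjusted pairwise p values (`p_ad_vs_control`, `p_ad_vs_nonad`,
#'   `p_nonad_vs_control` when those groups are present), `significant`.
#' @examples
#' res <- simulate_study(seed = 1) |> run_all(seed = 1)
#' head(res$differential)
#' @export
diff_test <- function(data, metadata, alpha = 0.05) {
  required_columns(data, c("sample_id", "protein", "value"))
  required_columns(metadata, c("sample_id", "group"))
  df <- data |>
    dplyr::inner_join(metadata |> dplyr::select("sample_id", "group"),
                      by = "sample_id") |>
    dplyr::filter(.data$group != "GIS", !is.na(.data$value))
  lev <- intersect(c("Control", "AD", "NonAD"), unique(df$group))
  lev <- c(lev, setdiff(sort(unique(df$group)), lev))
  if (length(lev) < 2) stop("need at least two groups", call. = FALSE)
  small <- df |>
    dplyr::count(.data$group) |>
    dplyr::filter(.data$n < 2)
  if (nrow(small)) {
    stop("every group needs >= 2 samples (too small: ",
         paste(small$group, collapse = ", "), ")", call. = FALSE)
  }
  df$group <- factor(df$group, levels = lev)

  one <- function(d, prot) {
    fit <- aov(value ~ group, data = d)
    ss_res <- sum(resid(fit)^2)
    ss_tot <- sum((d$value - mean(d$value))^2)
    if (ss_res <= 1e-12 * max(ss_tot, 1)) {
      stop("zero within-group variance for protein ", prot, call. = FALSE)
    }
    tab <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group[, "p adj", drop = FALSE]
    pair_p <- function(a, b) {
      hit <- rownames(tk) %in% c(paste0(a, "-", b), paste0(b, "-", a))
      if (any(hit)) tk[hit, 1][1] else NA_real_
    }
    gm <- d |>
      dplyr::summarise(mean = mean(.data$value),
                       se = sd(.data$value) / sqrt(dplyr::n()),
                       .by = "group")
    wide <- stats::setNames(
      c(gm$mean, gm$se),
      c(paste0("mean_", tolower(gm$group)), paste0("se_", tolower(gm$group))))
    out <- as_tibble(as.list(wide))
    out$f_statistic <- tab[1, "F value"]
    out$p_anova <- tab[1, "Pr(>F)"]
    if (all(c("AD", "Control") %in% lev)) {
      out$log2fc_ad_vs_control <-
        gm$mean[gm$group == "AD"] - gm$mean[gm$group == "Control"]
      out$p_ad_vs_control <- pair_p("AD", "Control")
    }
    if (all(c("AD", "NonAD") %in% lev)) {
      out$p_ad_vs_nonad <- pair_p("AD", "NonAD")
    }
    if (all(c("NonAD", "Control") %in% lev)) {
      out$p_nonad_vs_control <- pair_p("NonAD", "Control")
    }
    out
  }

  res <- df |>
    tidyr::nest(.by = "protein") |>
    dplyr::mutate(res = purrr::map2(.data$data, .data$protein, one)) |>
    dplyr::select("protein", "res") |>
    tidyr::unnest("res")
  res$q_anova <- p.adjust(res$p_anova, method = "BH")

  if (all(c("Control", "AD", "NonAD") %in% lev)) {
    ad_extreme <- (res$mean_ad > res$mean_control &
                     res$mean_ad > res$mean_nonad) |
      (res$mean_ad < res$mean_control & res$mean_ad < res$mean_nonad)
    res$significant <- res$q_anova < alpha &
      res$p_ad_vs_control < alpha & res$p_ad_vs_nonad < alpha & ad_extreme
  } else {
    res$significant <- res$q_anova < alpha
  }
  dplyr::relocate(res, "q_anova", .after = "p_anova")
}

#' Biweight midcorrelation
#'
#' A robust correlation built on Tukey biweights around the median: each
#' observation is weighted by `(1 - u^2)^2` for `|u| < 1` (0 otherwise),
#' where `u = (x - median(x)) / (9 * mad(x))` and `mad` is the unscaled
#' median absolute deviation. Outliers beyond nine MADs get zero weight, so
#' a single gross outlier perturbs the estimate far less than it perturbs
#' the Pearson correlation. When either variable has `mad = 0` the biweight
#' is undefined and the function falls back to Pearson with a warning.
#'
#' @param x,y Numeric vectors of equal length (pairs with `NA` dropped).
#' @return Correlation in \[-1, 1\].
#' @examples
#' bicor(1:10, -2 * (1:10) + 7)  # -1
#' @export
bicor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4) stop("bicor needs at least 4 complete pairs",
                          call. = FALSE)
  mx <- median(x)
  my <- median(y)
  madx <- median(abs(x - mx))
  mady <- median(abs(y - my))
  if (madx == 0 || mady == 0) {
    warning("zero MAD: falling back to Pearson correlation", call. = FALSE)
    return(cor(x, y))
  }
  ax <- biweight_dev(x, mx, madx)
  ay <- biweight_dev(y, my, mady)
  r <- sum(ax * ay) / sqrt(sum(ax^2) * sum(ay^2))
  max(-1, min(1, r))
}

biweight_dev <- function(v, med, mad0) {
  u <- (v - med) / (9 * mad0)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  w * (v - med)
}

#' Biweight midcorrelation with Student significance
#'
#' [bicor()] plus the Student-t p value
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom — the
#' same significance transform used for Pearson correlations.
#'
#' @inheritParams bicor
#' @return One-row tibble: `estimate`, `statistic`, `p_value`, `n`.
#' @export
bicor_test <- function(x, y) {
  ok <- complete.cases(x, y)
  n <- sum(ok)
  r <- bicor(x, y)
  cor_student(r, n)
}

cor_student <- function(r, n) {
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  tibble(estimate = r, statistic = t, p_value = p, n = n)
}

#' Correlate protein abundances with immunoassay traits
#'
#' For every protein and trait, correlates the regressed log2 abundances
#' with immunoassay values (A-beta-42, total Tau, phospho-Tau, and the
#' total-Tau / A-beta-42 ratio) across biological samples, by biweight
#' midcorrelation (default) or Pearson, with Student p values. Because the
#' two immunoassay platforms report on different absolute scales, the
#' analysis is restricted to one platform (default `"Luminex"`); pass
#' `platform = NULL` to use all samples.
#'
#' @param data Regressed abundance tibble (`sample_id`, `protein`, `value`).
#' @param metadata Metadata with trait columns `abeta42`, `ttau`, `ptau` and
#'   `platform`.
#' @param traits Trait columns to test; `"tau_abeta_ratio"` is derived as
#'   `ttau / abeta42`.
#' @param method `"bicor"` (default) or `"pearson"`.
#' @param platform Keep only samples on this immunoassay platform.
#' @param min_n Minimum complete pairs per correlation (default 4).
#' @return Tibble: `protein`, `trait`, `n`, `estimate`, `statistic`,
#'   `p_value`.
#' @export
correlate_traits <- function(data, metadata,
                             traits = c("abeta42", "ttau", "ptau",
                                        "tau_abeta_ratio"),
                             method = c("bicor", "pearson"),
                             platform = "Luminex", min_n = 4) {
  method <- match.arg(method)
  required_columns(data, c("sample_id", "protein", "value"))
  required_columns(metadata, c("sample_id", "is_gis"))
  meta <- metadata |> dplyr::filter(!.data$is_gis)
  if (!is.null(platform)) {
    required_columns(metadata, "platform")
    meta <- meta |> dplyr::filter(.data$platform == .env$platform)
  }
  if (all(c("ttau", "abeta42") %in% names(meta))) {
    meta$tau_abeta_ratio <- meta$ttau / meta$abeta42
  }
  missing_tr <- setdiff(traits, names(meta))
  if (length(missing_tr)) {
    stop("trait column(s) not found: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  df <- data |>
    dplyr::inner_join(meta |>
                        dplyr::select(dplyr::all_of(c("sample_id", traits))),
                      by = "sample_id")
  grid <- tidyr::expand_grid(protein = unique(df$protein), trait = traits)
  purrr::pmap(grid, function(protein, trait) {
    d <- df[df$protein == protein, ]
    ok <- complete.cases(d$value, d[[trait]])
    if (sum(ok) < max(min_n, 4)) {
      return(tibble(protein = protein, trait = trait, n = sum(ok),
                    estimate = NA_real_, statistic = NA_real_,
                    p_value = NA_real_))
    }
    x <- d$value[ok]
    y <- d[[trait]][ok]
    res <- if (method == "bicor") bicor_test(x, y) else {
      cor_student(cor(x, y), length(x))
    }
    dplyr::bind_cols(tibble(protein = protein, trait = trait), res |>
                       dplyr::relocate("n", .before = "estimate"))
  }) |>
    dplyr::bind_rows()
}

#' Concordance of effect sizes between two cohorts
#'
#' Pearson correlation and ordinary-least-squares line relating per-protein
#' log2 fold changes estimated in a replication cohort to those from a
#' discovery cohort — the standard check that two platforms or studies rank
#' disease effects the same way.
#'
#' @param replication,discovery Numeric vectors of per-protein log2 fold
#'   changes, aligned (same proteins in the same order); pairs with `NA`
#'   dropped.
#' @param proteins Optional protein labels (kept for plotting).
#' @return One-row tibble of class `prm_concordance`: `n`, `cor`,
#'   `p_value`, `slope`, `intercept`. The paired points are attached as the
#'   `"points"` attribute for [plot_concordance()].
#' @examples
#' cohort_concordance(c(1, 0.5, -0.2, 0.8), c(0.9, 0.6, -0.1, 0.7))
#' @export
cohort_concordance <- function(replication, discovery, proteins = NULL) {
  if (length(replication) != length(discovery)) {
    stop("replication and discovery vectors must be the same length",
         call. = FALSE)
  }
  ok <- complete.cases(replication, discovery)
  x <- discovery[ok]
  y <- replication[ok]
  if (length(x) < 3) stop("need at least 3 shared proteins", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y))
  fit <- lm(y ~ x)
  out <- tibble(n = length(x), cor = unname(ct$estimate),
                p_value = ct$p.value,
                slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  attr(out, "points") <- tibble(
    protein = if (is.null(proteins)) NA_character_ else proteins[ok],
    discovery = x, replication = y)
  class(out) <- c("prm_concordance", class(out))
  out
}
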