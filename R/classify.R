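#' Label samples by the A-beta-42 / total-Tau biomarker ratio
#'
#' A biological (rather than clinical) definition of AD status: a sample is
#' biomarker-positive when its CSF A-beta-42 to total-Tau ratio falls below
#' a fixed cutoff (default 4.6) — low amyloid and high tau being the
#' AD-like profile. A ratio exactly at the cutoff is negative (positivity is
#' a strict inequality). Values are platform-specific; use a single
#' immunoassay platform.
#'
#' @param abeta42,ttau Immunoassay values per sample; pairs with `NA` return
#'   `NA` (sample excluded).
#' @param threshold Positivity cutoff on the ratio (default 4.6).
#' @return Integer vector: 1 = positive (AD-like), 0 = negative, `NA` when
#'   either assay is missing. Errors on non-missing `ttau <= 0`.
#' @examples
#' abeta_tau_label(c(500, 920), c(200, 100))  # 1, 0
#' @export
abeta_tau_label <- function(abeta42, ttau, threshold = 4.6) {
  stopifnot(length(threshold) == 1, threshold > 0)
  if (any(ttau <= 0, na.rm = TRUE)) {
    stop("total-Tau values must be positive", call. = FALSE)
  }
  ratio <- abeta42 / ttau
  as.integer(ratio < threshold)
}

#' ROC curve and area under the curve
#'
#' Builds the receiver operating characteristic curve of a score against
#' binary labels, with one operating point per distinct score value (ties
#' grouped, so tied scores move diagonally in a single step), and computes
#' the AUC by the trapezoidal rule. This tie-aware trapezoid equals the
#' Mann-Whitney statistic: the probability that a random positive outranks
#' a random negative, counting ties as one half.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Binary labels (0/1, logical, or two-level factor).
#' @return Tibble of ROC points (`threshold`, `fpr`, `tpr`) from (0,0) to
#'   (1,1), with the AUC and class counts in attributes `auc`, `n_pos`,
#'   `n_neg`.
#' @examples
#' pts <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' attr(pts, "auc")  # 1
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  ok <- complete.cases(scores, y)
  scores <- scores[ok]
  y <- y[ok]
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y[ord]
  # group tied scores into single thresholds
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  pts <- tibble(threshold = c(Inf, s[last_of_tie]),
                fpr = c(0, fp / n_neg),
                tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  attr(pts, "auc") <- auc
  attr(pts, "n_pos") <- n_pos
  attr(pts, "n_neg") <- n_neg
  pts
}

#' @rdname roc_curve
#' @return `roc_auc()` returns the AUC as a single number.
#' @export
roc_auc <- function(scores, labels) {
  attr(roc_curve(scores, labels), "auc")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) {
      stop("factor labels must have exactly 2 levels", call. = FALSE)
    }
    return(as.integer(labels) - 1L)
  }
  u <- unique(labels[!is.na(labels)])
  if (!all(u %in% c(0, 1))) {
    stop("labels must be binary (0/1, logical, or a two-level factor)",
         call. = FALSE)
  }
  as.integer(labels)
}

stratified_folds <- function(labels, k, seed) {
  y <- as_binary_labels(labels)
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated single-protein logistic classifier with ROC
#'
#' Fits a univariate logistic regression (one protein's abundance plus an
#' intercept, no regularization) on each of `k` stratified training folds by
#' iteratively reweighted least squares, predicts the held-out fold, pools
#' the out-of-fold probabilities, and evaluates one ROC/AUC on the pooled
#' predictions. Pooling (rather than averaging per-fold curves) is the
#' lower-variance convention at small n. Fold assignment is stratified by
#' class and deterministic given `seed`. Complete separation does not abort
#' the fit: iterations are capped (maxit 100, deviance tolerance 1e-8), the
#' result is flagged, and the AUC is still computed from the scores.
#'
#' @param x Numeric feature (one protein's regressed abundances).
#' @param labels Binary class labels aligned with `x`; pairs with `NA` are
#'   dropped.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `prm_roc`: list with `predictions` (tibble
#'   `x`, `label`, `fold`, `prob`), `roc` points, `auc`, `n_pos`, `n_neg`,
#'   `folds`, `seed`, `separation`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' set.seed(7)
#' x <- c(rnorm(40), rnorm(40, 2))
#' fit <- train_cv_classifier(x, rep(0:1, each = 40), seed = 1)
#' glance(fit)
#' @export
train_cv_classifier <- function(x, labels, k = 5, seed = 1L) {
  y <- as_binary_labels(labels)
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2 * k) {
    stop("need at least 2k samples for ", k, "-fold cross-validation",
         call. = FALSE)
  }
  if (min(sum(y == 1), sum(y == 0)) < 2) {
    stop("both classes need at least 2 samples", call. = FALSE)
  }
  fold <- stratified_folds(y, k, seed)
  prob <- rep(NA_real_, n)
  separation <- FALSE
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test)) next
    train <- !test
    if (length(unique(y[train])) < 2) {
      stop("training fold ", f, " lost a class; reduce k", call. = FALSE)
    }
    d <- data.frame(x = x[train], y = y[train])
    fit <- withCallingHandlers(
      glm(y ~ x, family = binomial(), data = d,
          control = list(maxit = 100, epsilon = 1e-8)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (!fit$converged ||
        any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)) {
      separation <- TRUE
    }
    prob[test] <- predict(fit, newdata = data.frame(x = x[test]),
                          type = "response")
  }
  roc <- roc_curve(prob, y)
  structure(
    list(predictions = tibble(x = x, label = y, fold = fold, prob = prob),
         roc = roc, auc = attr(roc, "auc"),
         n_pos = sum(y == 1), n_neg = sum(y == 0),
         folds = k, seed = as.integer(seed), separation = separation),
    class = "prm_roc")
}

#' @export
print.prm_roc <- function(x, ...) {
  cat("<prm_roc> ", x$folds, "-fold CV logistic classifier: AUC = ",
      signif(x$auc, 3), " (", x$n_pos, " pos / ", x$n_neg, " neg)",
      if (x$separation) " [separation flagged]", "\n", sep = "")
  invisible(x)
}

#' Tidiers for cross-validated ROC results
#'
#' `tidy()` returns the ROC operating points; `glance()` returns a one-row
#' summary (AUC, class sizes, folds, seed, separation flag).
#'
#' @param x A `prm_roc` object from [train_cv_classifier()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.prm_roc <- function(x, ...) {
  as_tibble(x$roc)
}

#' @rdname tidy.prm_roc
#' @exportS3Method generics::glance
glance.prm_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg, folds = x$folds,
         seed = x$seed, separation = x$separation)
}

#' Cross-validated ROC analysis for every protein
#'
#' Runs [train_cv_classifier()] for each protein on one of three binary
#' tasks: clinical AD versus control, clinical AD versus non-AD cognitive
#' impairment, or A-beta/Tau biomarker-ratio positivity (Luminex samples
#' only, cutoff via [abeta_tau_label()]). Fold assignment depends only on
#' the labels and seed, so every protein is evaluated on identical folds.
#'
#' @param data Regressed abundance tibble (`sample_id`, `protein`, `value`).
#' @param metadata Metadata with `group` (and `abeta42`/`ttau`/`platform`
#'   for the ratio task).
#' @param task `"ad_vs_control"`, `"ad_vs_nonad"` or `"abeta_tau_ratio"`.
#' @param threshold Ratio cutoff for the biomarker task (default 4.6).
#' @param platform Platform restriction for the biomarker task.
#' @param k,seed Cross-validation folds and seed.
#' @return Tibble: `protein`, `task`, `auc`, `n_pos`, `n_neg`,
#'   `separation`, sorted by decreasing AUC. The fitted `prm_roc` objects
#'   are attached as the named list attribute `"fits"`.
#' @export
classify_proteins <- function(data, metadata,
                              task = c("ad_vs_control", "ad_vs_nonad",
                                       "abeta_tau_ratio"),
                              threshold = 4.6, platform = "Luminex",
                              k = 5, seed = 1L) {
  task <- match.arg(task)
  required_columns(data, c("sample_id", "protein", "value"))
  lab <- binary_task(metadata, task, threshold, platform)
  df <- data |> dplyr::inner_join(lab, by = "sample_id")
  fits <- df |>
    tidyr::nest(.by = "protein") |>
    dplyr::mutate(fit = purrr::map(.data$data, function(d) {
      train_cv_classifier(d$value, d$task_label, k = k, seed = seed)
    }))
  out <- fits |>
    dplyr::mutate(res = purrr::map(.data$fit, glance)) |>
    dplyr::select("protein", "res") |>
    tidyr::unnest("res") |>
    dplyr::mutate(task = .env$task, .after = "protein") |>
    dplyr::select(-"seed") |>
    dplyr::arrange(dplyr::desc(.data$auc))
  attr(out, "fits") <- setNames(fits$fit, fits$protein)
  out
}

binary_task <- function(metadata, task, threshold = 4.6,
                        platform = "Luminex") {
  required_columns(metadata, c("sample_id", "group"))
  if (task == "ad_vs_control") {
    lab <- metadata |>
      dplyr::filter(.data$group %in% c("AD", "Control")) |>
      dplyr::mutate(task_label = as.integer(.data$group == "AD"))
  } else if (task == "ad_vs_nonad") {
    lab <- metadata |>
      dplyr::filter(.data$group %in% c("AD", "NonAD")) |>
      dplyr::mutate(task_label = as.integer(.data$group == "AD"))
  } else {
    required_columns(metadata, c("abeta42", "ttau"))
    lab <- metadata |> dplyr::filter(.data$group != "GIS")
    if (!is.null(platform)) {
      required_columns(metadata, "platform")
      lab <- lab |> dplyr::filter(.data$platform == .env$platform)
    }
    lab <- lab |>
      dplyr::filter(!is.na(.data$abeta42), !is.na(.data$ttau)) |>
      dplyr::mutate(task_label = abeta_tau_label(.data$abeta42, .data$ttau,
                                                 threshold))
  }
  if (length(unique(lab$task_label)) < 2) {
    stop("task '", task, "' has only one class", call. = FALSE)
  }
  lab |> dplyr::select("sample_id", "task_label")
}
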