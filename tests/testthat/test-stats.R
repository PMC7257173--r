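group_meta <- function(n_per = 20) {
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(3 * n_per)),
    group = rep(c("Control", "AD", "NonAD"), each = n_per))
}

test_that("a 10-SD shift is detected in the right contrasts only", {
  set.seed(31)
  meta <- group_meta(20)
  dat <- tibble::tibble(
    sample_id = meta$sample_id, protein = "P1",
    value = rnorm(60) + rep(c(0, 10, 0), each = 20))
  res <- diff_test(dat, meta)
  expect_lt(res$p_anova, 1e-6)
  expect_lt(res$p_ad_vs_control, 0.05)
  expect_lt(res$p_ad_vs_nonad, 0.05)
  expect_gt(res$p_nonad_vs_control, 0.05)
  expect_true(res$significant)
  expect_equal(res$log2fc_ad_vs_control,
               res$mean_ad - res$mean_control)
})

test_that("two-group balanced ANOVA equals the squared t-test", {
  set.seed(32)
  meta <- tibble::tibble(sample_id = sprintf("S%02d", 1:20),
                         group = rep(c("Control", "AD"), each = 10))
  dat <- tibble::tibble(sample_id = meta$sample_id, protein = "P1",
                        value = rnorm(20, mean = rep(c(0, 1), each = 10)))
  res <- diff_test(dat, meta)
  tt <- t.test(value ~ group,
               data = dplyr::inner_join(dat, meta, by = "sample_id"),
               var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p_anova, tt$p.value, tolerance = 1e-12)
})

test_that("Tukey-adjusted p is never below the unadjusted contrast p", {
  set.seed(33)
  for (rep_i in 1:5) {
    meta <- group_meta(8)
    dat <- tibble::tibble(sample_id = meta$sample_id, protein = "P1",
                          value = rnorm(24, rep(c(0, 0.8, 0.2), each = 8)))
    res <- diff_test(dat, meta)
    df <- dplyr::inner_join(dat, meta, by = "sample_id")
    fit <- aov(value ~ group, data = df)
    mse <- sum(resid(fit)^2) / fit$df.residual
    gm <- tapply(df$value, df$group, mean)
    se <- sqrt(mse * (1 / 8 + 1 / 8))
    p_unadj <- 2 * pt(-abs((gm[["AD"]] - gm[["Control"]]) / se),
                      fit$df.residual)
    expect_gte(res$p_ad_vs_control + 1e-12, p_unadj)
  }
})

test_that("BH q-values are monotone, bounded below by p, and calibrated", {
  set.seed(34)
  n_prot <- 200
  meta <- group_meta(10)
  dat <- tidyr::expand_grid(protein = sprintf("P%03d", 1:n_prot),
                            sample_id = meta$sample_id)
  dat$value <- rnorm(nrow(dat))
  res <- diff_test(dat, meta)
  ord <- order(res$p_anova)
  expect_true(all(diff(res$q_anova[ord]) >= -1e-12))
  expect_true(all(res$q_anova >= res$p_anova - 1e-12))
  expect_lte(mean(res$q_anova < 0.05), 0.05)
})

test_that("diff_test validates its inputs", {
  meta <- group_meta(2)
  dat <- tibble::tibble(sample_id = meta$sample_id, protein = "P1",
                        value = rep(c(1, 2, 3), each = 2))
  expect_error(diff_test(dat, meta), "zero within-group variance")
  meta_small <- tibble::tibble(sample_id = c("S001", "S002", "S003"),
                               group = c("AD", "AD", "Control"))
  expect_error(diff_test(dat[1:3, ], meta_small), ">= 2 samples")
})

test_that("bicor matches an independently coded definition", {
  # step-by-step oracle written directly from the biweight definition
  bicor_oracle <- function(x, y) {
    num <- 0
    dx2 <- 0
    dy2 <- 0
    ax <- numeric(length(x))
    ay <- numeric(length(y))
    for (i in seq_along(x)) {
      ux <- (x[i] - median(x)) / (9 * median(abs(x - median(x))))
      uy <- (y[i] - median(y)) / (9 * median(abs(y - median(y))))
      wx <- if (abs(ux) < 1) (1 - ux^2)^2 else 0
      wy <- if (abs(uy) < 1) (1 - uy^2)^2 else 0
      ax[i] <- wx * (x[i] - median(x))
      ay[i] <- wy * (y[i] - median(y))
    }
    for (i in seq_along(x)) {
      num <- num + ax[i] * ay[i]
      dx2 <- dx2 + ax[i]^2
      dy2 <- dy2 + ay[i]^2
    }
    num / sqrt(dx2 * dy2)
  }
  set.seed(35)
  for (rep_i in 1:20) {
    x <- rnorm(50)
    y <- 0.5 * x + rnorm(50)
    expect_equal(bicor(x, y), bicor_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("bicor has exact values on affine relations", {
  x <- c(2, 5, 1, 9, 4, 7, 3)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -2 * x + 7), -1)
  # invariant to positive affine transforms, sign-flipped by negative ones
  y <- c(1, 4, 2, 8, 6, 3, 5)
  expect_equal(bicor(3 + 2 * x, y), bicor(x, y), tolerance = 1e-12)
  expect_equal(bicor(-x, y), -bicor(x, y), tolerance = 1e-12)
})

test_that("bicor resists an outlier better than Pearson", {
  x <- 1:20
  y <- as.numeric(1:20)
  y[20] <- 200            # one gross outlier
  base_b <- bicor(x[1:19], y[1:19])
  base_p <- cor(x[1:19], y[1:19])
  expect_lt(abs(bicor(x, y) - base_b), abs(cor(x, y) - base_p))
})

test_that("bicor falls back to Pearson when MAD is zero", {
  x <- c(rep(1, 10), 2, 3)
  y <- rnorm(12)
  expect_warning(r <- bicor(x, y), "Pearson")
  expect_equal(r, cor(x, y))
  expect_error(bicor(1:3, 1:3), "at least 4")
})

test_that("bicor_test applies the Student transform", {
  set.seed(36)
  x <- rnorm(30)
  y <- 0.4 * x + rnorm(30)
  res <- bicor_test(x, y)
  r <- bicor(x, y)
  t_expected <- r * sqrt((30 - 2) / (1 - r^2))
  expect_equal(res$statistic, t_expected, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_expected), 28), tolerance = 1e-12)
  expect_equal(res$n, 30)
})

test_that("trait correlations recover the built-in couplings", {
  res <- default_run$correlations
  # trait-driving proteins: PROT01 -> ttau (+), PROT03 -> abeta42 (-)
  r_tau <- res$estimate[res$protein == "PROT01" & res$trait == "ttau"]
  r_abeta <- res$estimate[res$protein == "PROT03" & res$trait == "abeta42"]
  expect_gt(r_tau, 0.5)
  expect_lt(r_abeta, -0.5)
  # restricted to the Luminex platform
  n_lum <- sum(default_study$metadata$platform == "Luminex", na.rm = TRUE)
  expect_true(all(res$n <= n_lum))
  expect_equal(n_lum, 67)
})

test_that("cohort concordance has exact values on degenerate input", {
  v <- c(1, 0.5, -0.2, 0.8, 0.1)
  same <- cohort_concordance(v, v)
  expect_equal(same$cor, 1)
  expect_equal(same$slope, 1)
  flipped <- cohort_concordance(-v, v)
  expect_equal(flipped$cor, -1)
  expect_error(cohort_concordance(c(1, 2), c(1, 2)), "at least 3")
})

test_that("concordance attenuates as independent noise is added", {
  set.seed(37)
  n <- 2000
  effect <- rnorm(n, 0, 1)
  sigma <- 0.5
  disc <- effect + rnorm(n, 0, sigma)
  repl <- effect + rnorm(n, 0, sigma)
  res <- cohort_concordance(repl, disc)
  expect_equal(res$cor, 1 / (1 + sigma^2), tolerance = 0.03)
})
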