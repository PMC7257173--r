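ref_table <- function(mat) {
  # rows = reference peptides, cols = injections
  tibble::tibble(
    sample_id = rep(colnames(mat), each = nrow(mat)),
    peptide = rep(rownames(mat), ncol(mat)),
    raw_area = as.vector(mat))
}

test_that("drift factors are 1 for constant references and scale exactly", {
  mat <- matrix(100, nrow = 3, ncol = 5,
                dimnames = list(paste0("R", 1:3), paste0("I", 1:5)))
  f <- drift_factors(ref_table(mat))
  expect_equal(f$drift_factor, rep(1, 5))

  # doubling every reference in one injection doubles its factor only
  mat2 <- mat
  mat2[, 3] <- 200
  f2 <- drift_factors(ref_table(mat2))
  expect_equal(f2$drift_factor[f2$sample_id == "I3"], 2)
  expect_equal(f2$drift_factor[f2$sample_id != "I3"], rep(1, 4))
  # and correction halves that injection's areas
  quant <- tibble::tibble(sample_id = paste0("I", 1:5), protein = "P",
                          peptide = "X", raw_area = 10)
  corr <- apply_drift_correction(quant, f2)
  expect_equal(corr$norm_area, c(10, 10, 5, 10, 10))
})

test_that("drift factors error when an injection lacks all references", {
  mat <- matrix(c(100, NA, 100, NA), nrow = 2,
                dimnames = list(c("R1", "R2"), c("I1", "I2")))
  mat[, 2] <- NA
  expect_error(drift_factors(ref_table(mat)), "I2")
  expect_error(drift_factors(ref_table(-mat)), "positive")
})

test_that("drift estimation recovers the injected drift curve", {
  des <- study_design()
  tr <- ground_truth(des, noise_sd_log = 0.2)
  st <- simulate_study(des, tr, seed = 13)
  f <- drift_factors(sum_transitions(st$transitions, "reference"))
  d <- tibble::tibble(sample_id = st$metadata$sample_id,
                      truth = true_drift(st))
  joined <- dplyr::inner_join(f, d, by = "sample_id")
  expect_gt(cor(joined$drift_factor, joined$truth, method = "spearman"),
            0.95)
})

test_that("drift correction is idempotent on multiplicative structure", {
  # areas a_rj = A_r * d_j: one pass removes d exactly, a second finds
  # nothing left to remove
  A <- c(R1 = 50, R2 = 500, R3 = 5000)
  d <- c(1.4, 1.1, 1.0, 0.8, 0.6)
  mat <- outer(A, d)
  colnames(mat) <- paste0("I", 1:5)
  tab <- ref_table(mat)
  f1 <- drift_factors(tab)
  expect_equal(f1$drift_factor, d / median(d), tolerance = 1e-12)
  corrected <- apply_drift_correction(tab, f1)
  f2 <- drift_factors(corrected, value_col = "norm_area")
  expect_equal(f2$drift_factor, rep(1, 5), tolerance = 1e-12)
})

test_that("protein roll-up sums observed peptides only", {
  q <- tibble::tibble(
    sample_id = "S1",
    protein = c("P1", "P2", "P2", "P2"),
    peptide = c("a", "b", "c", "d"),
    norm_area = c(7, 10, 20, 30))
  r <- rollup_protein(q)
  expect_equal(r$abundance[r$protein == "P1"], 7)   # single peptide
  expect_equal(r$abundance[r$protein == "P2"], 60)  # 10 + 20 + 30
  # missing peptides are excluded, not zero-filled
  q$norm_area[3] <- NA
  r2 <- rollup_protein(q)
  expect_equal(r2$abundance[r2$protein == "P2"], 40)
  expect_equal(r2$n_peptides[r2$protein == "P2"], 2L)
  # non-proteotypic mapping is a configuration error
  q_bad <- dplyr::bind_rows(q, tibble::tibble(sample_id = "S1",
                                              protein = "P1", peptide = "b",
                                              norm_area = 1))
  expect_error(rollup_protein(q_bad), "more than one protein")
})

test_that("94-peptide default rolls up to 41 proteins", {
  pep <- sum_transitions(default_study$transitions)
  prot <- rollup_protein(pep, value_col = "raw_area")
  expect_equal(dplyr::n_distinct(prot$protein), 41)
  expect_equal(nrow(prot), 41 * 98)
})

test_that("GIS normalization anchors each batch pool at exactly 1", {
  prot <- default_run$protein
  ratios <- gis_normalize(prot, default_study$metadata)
  gis_means <- ratios |>
    dplyr::left_join(default_study$metadata[, c("sample_id", "is_gis")],
                     by = "sample_id") |>
    dplyr::filter(is_gis) |>
    dplyr::summarise(m = mean(ratio), .by = c("protein", "batch"))
  expect_equal(gis_means$m, rep(1, nrow(gis_means)), tolerance = 1e-12)
  # value equal to its batch GIS mean maps to ratio 1
  one_gis <- ratios |>
    dplyr::semi_join(dplyr::filter(default_study$metadata, is_gis)[1, ],
                     by = "sample_id")
  expect_true(all(is.finite(one_gis$ratio)))
  # re-normalizing the ratio stage changes nothing (idempotence)
  again <- gis_normalize(ratios |> dplyr::select(-"ratio") |>
                           dplyr::mutate(abundance = ratios$ratio),
                         default_study$metadata)
  expect_equal(again$ratio, ratios$ratio, tolerance = 1e-12)
})

test_that("GIS normalization removes a batch-level scale shift", {
  des <- small_design()
  st <- simulate_study(des, clean_truth(des), seed = 21)
  pep <- sum_transitions(st$transitions)
  prot <- rollup_protein(pep, value_col = "raw_area")
  # impose a 2x global shift on batch B2
  shifted <- prot |>
    dplyr::mutate(abundance = abundance *
                    ifelse(batch == "B2", 2, 1))
  ratios <- gis_normalize(shifted, st$metadata)
  by_batch <- ratios |>
    dplyr::left_join(st$metadata[, c("sample_id", "is_gis")],
                     by = "sample_id") |>
    dplyr::filter(!is_gis) |>
    dplyr::summarise(m = mean(ratio), .by = c("protein", "batch")) |>
    tidyr::pivot_wider(names_from = "batch", values_from = "m")
  expect_equal(by_batch$B1, by_batch$B2, tolerance = 1e-12)
})

test_that("GIS normalization reports unusable pools", {
  prot <- tibble::tibble(sample_id = c("S1", "G1"), protein = "P1",
                         abundance = c(10, NA))
  meta <- tibble::tibble(sample_id = c("S1", "G1"), batch = "B1",
                         is_gis = c(FALSE, TRUE))
  expect_error(gis_normalize(prot, meta), "P1")
})

test_that("compute_cv follows the percent sd/mean definition", {
  expect_equal(compute_cv(c(5, 5, 5)), 0)
  expect_equal(compute_cv(c(90, 100, 110)), 10)  # sample SD 10, mean 100
  expect_true(is.na(compute_cv(c(4))))
  expect_true(is.na(compute_cv(c(-10, 10))))     # mean <= 0 undefined
  expect_true(is.na(compute_cv(c(NA, NA, 3))))
  # precision flag: high iff CV <= 30
  qc <- gis_cv(sum_transitions(default_study$transitions),
               default_study$metadata, "raw_area",
               precision_threshold = 30)
  expect_identical(qc$high_precision, !is.na(qc$cv) & qc$cv <= 30)
})

test_that("covariate regression returns exact OLS residuals", {
  meta4 <- tibble::tibble(sample_id = paste0("S", 1:4),
                          is_gis = FALSE,
                          age = c(1, 1, 2, 2), sex = c(0, 1, 1, 0))
  # value orthogonal to age and sex: residuals are the demeaned values
  v <- c(-1, 1, -1, 1)
  dat <- tibble::tibble(sample_id = paste0("S", 1:4), protein = "P1",
                        ratio = v)
  res <- regress_covariates(dat, meta4, log2_transform = FALSE)
  expect_equal(res$value, v - mean(v), tolerance = 1e-12)

  # value built exactly from age: residuals vanish
  dat2 <- tibble::tibble(sample_id = paste0("S", 1:4), protein = "P1",
                         ratio = 0.05 * meta4$age)
  res2 <- regress_covariates(dat2, meta4, log2_transform = FALSE)
  expect_equal(res2$value, rep(0, 4), tolerance = 1e-10)

  # a single-level covariate is dropped with a warning
  meta_one_sex <- dplyr::mutate(meta4, sex = 1)
  expect_warning(regress_covariates(dat, meta_one_sex,
                                    log2_transform = FALSE), "sex")
})

test_that("regression recovers a simulated age effect", {
  des <- study_design()
  tr <- ground_truth(des, age_coef = 0.02, noise_sd_log = 0.15)
  st <- simulate_study(des, tr, seed = 17)
  run <- run_all(st, seed = 17, tasks = "ad_vs_control")
  # fit the same OLS the regression stage uses and compare the age slope
  # to the injected coefficient (natural-log 0.02 -> log2 0.02/log(2))
  df <- run$protein_ratio |>
    dplyr::inner_join(dplyr::filter(st$metadata, !is_gis),
                      by = "sample_id")
  fits <- df |>
    dplyr::summarise(
      beta = coef(lm(log2(ratio) ~ age + sex))[["age"]],
      se = summary(lm(log2(ratio) ~ age + sex))$coefficients["age", 2],
      .by = "protein")
  expected <- 0.02 / log(2)
  z <- (fits$beta - expected) / fits$se
  expect_lte(sum(abs(z) > 3), 2)
  expect_lt(abs(mean(fits$beta) - expected), 0.01)
})

test_that("residualizing residuals changes nothing", {
  reg <- default_run$regressed
  again <- regress_covariates(reg, default_study$metadata,
                              value_col = "value", log2_transform = FALSE)
  expect_equal(again$value, reg$value, tolerance = 1e-12)
})
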