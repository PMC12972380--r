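test_that("sample-missingness outlier rule flags the 90%-missing sample", {
  # 69 samples at 10% and 1 sample at 90% missingness -> only that sample
  # exceeds mean + 5 SD
  set.seed(1)
  p <- 100
  v <- matrix(rexp(p * 70, 1e-5), p, 70,
              dimnames = list(sprintf("m%03d", 1:p), sprintf("s%02d", 1:70)))
  for (j in 1:69) v[sample(p, 10), j] <- NA
  v[sample(p, 90), 70] <- NA
  meta <- data.frame(sample_id = colnames(v),
                     subject_id = sprintf("S%02d", 1:70),
                     role = "experimental", group = "control",
                     timepoint = "baseline", batch = "B1",
                     stringsAsFactors = FALSE)
  flagged <- flag_sample_outliers(ion_matrix(v), meta)
  expect_identical(as.character(flagged), "s70")
})

test_that("batch-median normalization makes reference medians exactly 1 per batch", {
  cohort <- simulate_cohort(sim_config(seed = 2))
  norm <- batch_median_normalize(cohort$matrix, cohort$samples)
  for (b in c("B1", "B2")) {
    ref <- cohort$samples$sample_id[cohort$samples$role == "reference_serum" &
                                      cohort$samples$batch == b]
    med <- apply(unclass(norm)[, ref], 1, median)
    expect_equal(unname(med), rep(1, nrow(norm)), tolerance = 1e-12)
  }
})

test_that("batch normalization removes a planted multiplicative batch effect", {
  cohort <- simulate_cohort(sim_config(batch_factor_sd = 1,
                                       missing_logit_intercept = -Inf,
                                       outlier_rate = 0, n_forced_missing = 0,
                                       n_high_cv = 0, seed = 12))
  meta <- cohort$samples
  ex <- meta[meta$role == "experimental", ]
  norm <- log2(unclass(batch_median_normalize(cohort$matrix, meta))[, ex$sample_id])
  # per-metabolite mean difference between batches shrinks to the
  # subject-noise sampling floor (the planted SD-1 effect itself vanishes)
  raw <- log2(unclass(cohort$matrix)[, ex$sample_id])
  gap <- function(m) {
    b1 <- ex$sample_id[ex$batch == "B1"]; b2 <- ex$sample_id[ex$batch == "B2"]
    rowMeans(m[, b1]) - rowMeans(m[, b2])
  }
  expect_lt(mean(abs(gap(norm))), 0.5 * mean(abs(gap(raw))))
  # and the residual gap no longer tracks the planted (SD-1, dominant)
  # batch effect that gap(raw) is a direct readout of
  expect_lt(abs(cor(gap(norm), gap(raw))), 0.3)
})

test_that("CV filter matches the hand-computed CV and applies a strict threshold", {
  # replicate values {0.5, 1.0, 1.5, 1.0}: mean 1, sd sqrt(1/6) -> CV 40.82%
  v <- matrix(c(0.5, 1.0, 1.5, 1.0,
                1.0, 1.0, 1.0, 1.0), 2, 4, byrow = TRUE,
              dimnames = list(c("noisy", "steady"), paste0("ref", 1:4)))
  meta <- data.frame(sample_id = paste0("ref", 1:4), subject_id = "",
                     role = "reference_serum", group = "", timepoint = "",
                     batch = "B1", stringsAsFactors = FALSE)
  res <- cv_filter(ion_matrix(v), meta)
  expect_equal(unname(res$cv["noisy"]), 100 * sqrt(1 / 6), tolerance = 1e-12)
  expect_identical(res$excluded, "noisy")
  # a CV exactly at the threshold is retained (strict >)
  res25 <- cv_filter(ion_matrix(v), meta,
                     threshold_pct = 100 * sqrt(1 / 6))
  expect_length(res25$excluded, 0)
})

test_that("missingness filter is strict at the 30% boundary", {
  v <- matrix(1, 2, 10, dimnames = list(c("at", "above"), paste0("s", 1:10)))
  v["at", 1:3] <- NA       # exactly 30%
  v["above", 1:4] <- NA    # 40%
  res <- missingness_filter(ion_matrix(v))
  expect_identical(res$excluded, "above")
  expect_equal(unname(res$missingness), c(0.3, 0.4))
})

test_that("log2 transform errors on non-positive cells, naming the cell", {
  v <- matrix(c(1, 0, 4, 8), 2, 2,
              dimnames = list(c("ok", "zero"), c("s1", "s2")))
  expect_error(log2_transform(ion_matrix(v)), "zero")
  expect_error(log2_transform(ion_matrix(v)), "s1")
  v[2, 1] <- 2
  lg <- log2_transform(ion_matrix(v))
  expect_true(is_log_scale(lg))
  expect_equal(unclass(lg)["ok", "s2"], 2)
})

test_that("kNN imputation never alters observed cells and is deterministic", {
  set.seed(3)
  v <- matrix(rnorm(40 * 15, 15), 40, 15,
              dimnames = list(sprintf("m%02d", 1:40), paste0("s", 1:15)))
  v[sample(length(v), 60)] <- NA
  v[1, ] <- rnorm(15, 15)
  x <- ion_matrix(v, log_scale = TRUE)
  imp1 <- knn_impute(x)
  imp2 <- knn_impute(x)
  obs <- !is.na(v)
  expect_identical(unclass(imp1)[obs], v[obs])
  expect_identical(unclass(imp1)[, ], unclass(imp2)[, ])
  expect_false(anyNA(imp1))
})

test_that("kNN donors are restricted to metabolites observed in the target sample", {
  # metabolite m1 is missing in s1; its nearest neighbour m2 is also missing
  # in s1, so the imputed value must come from the remaining donors
  v <- rbind(m1 = c(NA, 10, 10, 10),
             m2 = c(NA, 10.01, 10.01, 10.01),
             m3 = c(20, 10.2, 10.2, 10.2),
             m4 = c(30, 10.3, 10.3, 10.3))
  colnames(v) <- paste0("s", 1:4)
  imp <- knn_impute(ion_matrix(v, log_scale = TRUE), k = 1)
  expect_equal(unclass(imp)["m1", "s1"], 20)  # m3, not the absent m2
})

test_that("IQR outlier rule is strict and blanks both timepoints of a flagged subject", {
  meta <- exp_meta(c(control = 5, bodybuilding = 5, endurance = 5,
                     sprint = 5))
  set.seed(4)
  v <- matrix(rnorm(2 * nrow(meta), 10, 0.1), 2, nrow(meta),
              dimnames = list(c("hit", "clean"), meta$sample_id))
  v["hit", "S01_post"] <- 30   # far outside median +- 3 IQR
  res <- iqr_outlier_removal(ion_matrix(v, log_scale = TRUE), meta)
  expect_identical(res$flagged$sample_id, "S01_post")
  expect_identical(res$flagged$subject_id, "S01")
  expect_equal(res$n_blanked, 2L)  # both of S01's cells for 'hit'
  expect_true(all(is.na(unclass(res$matrix)["hit",
                                            c("S01_pre", "S01_post")])))
  expect_false(anyNA(unclass(res$matrix)["clean", ]))

  # a cell exactly on the boundary is retained (strict inequality):
  # for {1..6, 13} the type-7 quantiles give median 4, IQR 3, so the upper
  # bound is exactly 13
  w <- matrix(c(1, 2, 3, 4, 5, 6, 13), 1, 7,
              dimnames = list("m", meta$sample_id[1:7]))
  res2 <- iqr_outlier_removal(ion_matrix(w, log_scale = TRUE), meta[1:7, ],
                              multiplier = 3)
  expect_equal(res2$n_flagged, 0L)
  w[1, 7] <- 13 + 1e-9
  res3 <- iqr_outlier_removal(ion_matrix(w, log_scale = TRUE), meta[1:7, ],
                              multiplier = 3)
  expect_equal(res3$n_flagged, 1L)
})

test_that("run_qc removes planted QC failures and returns a complete matrix", {
  cohort <- simulate_cohort(sim_config(seed = 6))
  qc <- run_qc(cohort$matrix, cohort$samples)
  expect_false(anyNA(qc$matrix))
  expect_true(is_log_scale(qc$matrix))
  # experimental columns only
  ex <- cohort$samples$sample_id[cohort$samples$role == "experimental"]
  expect_true(all(colnames(qc$matrix) %in% ex))
  # planted high-CV metabolites are overwhelmingly caught by the CV filter
  expect_gt(mean(cohort$truth$high_cv %in% qc$report$cv_excluded), 0.9)
  # planted forced-missing metabolites are caught by CV or missingness filter
  caught <- union(qc$report$missingness_excluded, qc$report$cv_excluded)
  expect_gt(mean(cohort$truth$forced_missing %in% caught), 0.9)
  # excluded metabolites are gone from the final matrix
  expect_length(intersect(rownames(qc$matrix), caught), 0)
})
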