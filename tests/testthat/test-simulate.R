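test_that("simulation is deterministic in the seed", {
  a <- simulate_cohort(sim_config(seed = 3))
  b <- simulate_cohort(sim_config(seed = 3))
  c <- simulate_cohort(sim_config(seed = 4))
  expect_identical(unclass(a$matrix)[, ], unclass(b$matrix)[, ])
  expect_identical(a$truth$module, b$truth$module)
  expect_false(identical(unclass(a$matrix)[, ], unclass(c$matrix)[, ]))
})

test_that("cohort dimensions and truth bookkeeping match the configuration", {
  cfg <- sim_config(seed = 8)
  cohort <- simulate_cohort(cfg)
  n_sub <- sum(cfg$n_per_group)
  expect_equal(nrow(cohort$matrix), cfg$n_metabolites)
  # 2 samples/subject + per batch 4 serum + 1 plasma wells
  expect_equal(ncol(cohort$matrix), 2 * n_sub + 2 * 5)
  expect_equal(sum(cohort$samples$role == "experimental"), 2 * n_sub)
  expect_equal(tabulate(cohort$truth$module), cfg$module_sizes)
  expect_length(cohort$truth$high_cv, cfg$n_high_cv)
  expect_length(cohort$truth$forced_missing, cfg$n_forced_missing)
  expect_equal(nrow(cohort$traits), n_sub)
  expect_equal(ncol(cohort$traits), cfg$n_traits + 1)  # + subject_id
})

test_that("forced-missing metabolites exceed the 30% missingness threshold", {
  cohort <- simulate_cohort(sim_config(seed = 9))
  ex <- cohort$samples$sample_id[cohort$samples$role == "experimental"]
  frac <- rowMeans(is.na(unclass(cohort$matrix)[cohort$truth$forced_missing,
                                                ex]))
  expect_true(all(frac > 0.30))
})

test_that("planted modules reach the target within-module correlation", {
  # disable missingness/outliers to measure the correlation directly
  cfg <- sim_config(missing_logit_intercept = -Inf, outlier_rate = 0,
                    n_forced_missing = 0, seed = 21)
  cohort <- simulate_cohort(cfg)
  ex <- cohort$samples[cohort$samples$role == "experimental", ]
  base_cols <- ex$sample_id[ex$timepoint == "baseline"]
  lg <- log2(unclass(cohort$matrix)[, base_cols])
  mean_abs_cor <- function(ids) {
    cc <- abs(cor(t(lg[ids, ])))
    mean(cc[upper.tri(cc)])
  }
  m1 <- names(cohort$truth$module)[cohort$truth$module == 1]
  bg <- names(cohort$truth$module)[cohort$truth$module == 0][1:100]
  expect_lt(abs(mean_abs_cor(m1) - cfg$within_module_cor), 0.1)
  expect_lt(mean_abs_cor(bg), 0.3)
})

test_that("shared responses appear in fold changes at the planted magnitude", {
  cfg <- sim_config(missing_logit_intercept = -Inf, outlier_rate = 0,
                    n_forced_missing = 0, seed = 22)
  cohort <- simulate_cohort(cfg)
  lg <- ion_matrix(log2(unclass(cohort$matrix)[, ]), log_scale = TRUE)
  fc <- log2_fold_changes(lg, cohort$samples)
  shared <- cohort$truth$response_shared
  planted <- names(shared)[shared != 0]
  obs <- rowMeans(fc[planted, ])
  expect_lt(max(abs(obs - shared[planted])), 1.5)
  expect_gt(cor(obs, shared[planted]), 0.95)
})

test_that("apply_missingness_and_outliers perturbs experimental cells only and records truth", {
  cohort <- simulate_cohort(sim_config(missing_logit_intercept = -Inf,
                                       outlier_rate = 0,
                                       n_forced_missing = 0, seed = 23))
  cfg <- sim_config(outlier_rate = 0.02, n_forced_missing = 5, seed = 23)
  set.seed(99)
  out <- apply_missingness_and_outliers(cohort$matrix, cohort$samples, cfg)
  ref_cols <- cohort$samples$sample_id[cohort$samples$role != "experimental"]
  expect_identical(unclass(out$matrix)[, ref_cols],
                   unclass(cohort$matrix)[, ref_cols])
  idx <- cbind(out$truth$outliers$metabolite_id,
               out$truth$outliers$sample_id)
  ratio <- unclass(out$matrix)[idx] / unclass(cohort$matrix)[idx]
  expect_true(all(abs(log2(ratio)) == cfg$outlier_log2_shift))
})

test_that("sim_config validates its arguments", {
  expect_error(sim_config(module_sizes = c(600, 600)), "exceed")
  expect_error(sim_config(within_module_cor = 1), "within_module_cor")
  expect_error(sim_config(subject_sd = -1), "non-negative")
  expect_error(sim_config(n_per_group = c(a = 5, b = 5, c = 5, d = 5)),
               "named with the four groups")
})
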