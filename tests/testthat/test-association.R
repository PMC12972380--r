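test_that("standardized beta of the simple model equals the Pearson correlation", {
  set.seed(1)
  meta <- exp_meta(c(control = 4, bodybuilding = 4, endurance = 4,
                     sprint = 4))
  subjects <- unique(meta$subject_id)
  reps <- data.frame(subject_id = subjects, module = "turquoise",
                     eigenmetabolite = rnorm(16),
                     zscore_mean = rnorm(16), stringsAsFactors = FALSE)
  traits <- data.frame(subject_id = subjects,
                       vo2max = rnorm(16), bmi = rnorm(16))
  out <- module_trait_lm(reps, traits)
  row <- out[out$trait == "vo2max" & out$measure == "eigenmetabolite", ]
  expect_equal(row$beta, cor(reps$eigenmetabolite, traits$vo2max),
               tolerance = 1e-12)
  ref <- cor.test(reps$eigenmetabolite, traits$vo2max)
  expect_equal(row$p, ref$p.value, tolerance = 1e-12)
  # BH is applied within each measure family
  for (ms in unique(out$measure)) {
    i <- out$measure == ms
    expect_equal(out$p_fdr[i], p.adjust(out$p[i], "BH"))
  }
})

test_that("group adjustment absorbs purely group-driven associations", {
  set.seed(2)
  meta <- exp_meta(c(control = 8, bodybuilding = 8, endurance = 8,
                     sprint = 8))
  ex <- meta[meta$timepoint == "baseline", ]
  g <- ex$group
  # representative and trait both depend on the subject's group only (plus
  # independent noise): association vanishes once group is adjusted for
  shift <- c(control = 0, bodybuilding = 2, endurance = 4, sprint = 6)
  reps <- data.frame(subject_id = ex$subject_id, module = "turquoise",
                     eigenmetabolite = shift[g] + rnorm(32, 0, 0.5),
                     zscore_mean = shift[g] + rnorm(32, 0, 0.5),
                     stringsAsFactors = FALSE)
  traits <- data.frame(subject_id = ex$subject_id,
                       vo2max = shift[g] + rnorm(32, 0, 0.5))
  plain <- module_trait_lm(reps, traits)
  adj <- module_trait_lm(reps, traits, meta, adjust_for_group = TRUE)
  p_plain <- plain$p[plain$measure == "eigenmetabolite"]
  p_adj <- adj$p[adj$measure == "eigenmetabolite"]
  expect_lt(p_plain, 1e-6)
  expect_gt(p_adj, 0.01)
  expect_true(all(adj$group_adjusted))
})

test_that("tukey_kramer reproduces TukeyHSD on balanced and unbalanced designs", {
  set.seed(3)
  for (sizes in list(c(6, 6, 6, 6), c(4, 7, 9, 5))) {
    g <- rep(c("a", "b", "c", "d"), sizes)
    v <- rnorm(length(g), rep(c(0, 0.5, 1, 0), sizes))
    tk <- tukey_kramer(v, g)
    ref <- TukeyHSD(aov(v ~ factor(g)))[[1]]
    key <- paste(tk$group2, tk$group1, sep = "-")
    expect_equal(tk$p, unname(ref[key, "p adj"]), tolerance = 1e-8)
  }
  expect_error(tukey_kramer(rnorm(3), c("a", "a", "b")), ">= 2 observations")
})

test_that("module_group_anova reports F, Bonferroni and the module-level threshold", {
  set.seed(4)
  meta <- exp_meta(c(control = 7, bodybuilding = 9, endurance = 11,
                     sprint = 8))
  ex <- meta[meta$timepoint == "baseline", ]
  shift <- c(control = 0, bodybuilding = 0, endurance = 2, sprint = 0)
  reps <- rbind(
    data.frame(subject_id = ex$subject_id, module = "turquoise",
               eigenmetabolite = shift[ex$group] + rnorm(35, 0, 0.7),
               zscore_mean = 0, stringsAsFactors = FALSE),
    data.frame(subject_id = ex$subject_id, module = "blue",
               eigenmetabolite = rnorm(35), zscore_mean = 0,
               stringsAsFactors = FALSE))
  res <- module_group_anova(reps, meta)
  expect_equal(res$bonferroni_threshold, 0.05 / 2)
  an <- res$anova
  expect_lt(an$p[an$module == "turquoise"], 0.001)
  expect_equal(an$p_bonferroni, pmin(1, an$p * 2))
  # the post-hoc contrasts single out the endurance group
  ph <- res$posthoc[res$posthoc$module == "turquoise", ]
  sig <- ph[ph$p < 0.05, ]
  expect_true(all(sig$group1 == "endurance" | sig$group2 == "endurance"))
})

test_that("per-metabolite group ANOVA agrees with lm and carries both adjustments", {
  set.seed(5)
  meta <- exp_meta(c(control = 5, bodybuilding = 5, endurance = 5,
                     sprint = 5))
  x <- null_log2_matrix(10, meta)
  res <- per_metabolite_group_test(x, meta, posthoc = FALSE)$anova
  ex <- meta[meta$timepoint == "baseline", ]
  v <- unclass(x)["met_003", ex$sample_id]
  ref <- anova(lm(v ~ factor(ex$group)))
  expect_equal(res$F[res$metabolite_id == "met_003"], ref$`F value`[1],
               tolerance = 1e-12)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 10))
  expect_equal(res$p_fdr, p.adjust(res$p, "BH"))
})

test_that("module representatives carry both measures, positively correlated", {
  cohort <- simulate_cohort(sim_config(seed = 13))
  qc <- run_qc(cohort$matrix, cohort$samples)
  mods <- detect_modules(qc$matrix[, grep("_pre$", colnames(qc$matrix))],
                         timepoint = "baseline")
  reps <- module_representatives(qc$matrix, mods$assignment, cohort$samples)
  expect_true(all(c("subject_id", "module", "eigenmetabolite",
                    "zscore_mean") %in% names(reps)))
  n_sub <- length(unique(reps$subject_id))
  expect_equal(nrow(reps), n_sub * length(unique(reps$module)))
  for (m in unique(reps$module)) {
    rm <- reps[reps$module == m, ]
    expect_gte(cor(rm$eigenmetabolite, rm$zscore_mean), 0)
  }
  ve <- attr(reps, "var_explained")
  expect_true(all(ve > 0 & ve <= 1))
})

test_that("adjust_pvalues validates input and preserves NA", {
  expect_error(adjust_pvalues(c(0.5, 1.2)), "must be in")
  out <- adjust_pvalues(c(0.01, NA, 0.04), "bh")
  expect_true(is.na(out[2]))
})
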