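#' Per-subject module representatives
#'
#' Two per-subject summaries of each consensus module at baseline:
#' (i) the eigenmetabolite score (PC1 of the module's metabolite-standardized
#' sub-matrix) and (ii) the mean z-score (each member z-scored across
#' subjects, then averaged within subject). The eigenmetabolite sign is
#' oriented so the two measures correlate positively.
#'
#' @param x log-scale, imputed [ion_matrix] (experimental samples).
#' @param assignment consensus `module_assignment`.
#' @param meta sample metadata; representatives are computed on the
#'   `timepoint` samples (one per subject).
#' @param timepoint timepoint used (default `"baseline"`).
#' @return data.frame of class `module_representatives`: one row per
#'   (subject, module) with columns `subject_id`, `module`, `eigenmetabolite`,
#'   `zscore_mean`; per-module variance explained is kept in attribute
#'   `var_explained`.
#' @export
module_representatives <- function(x, assignment, meta,
                                   timepoint = "baseline") {
  ex <- .experimental(meta)
  ex <- ex[ex$timepoint == timepoint, , drop = FALSE]
  cols <- intersect(colnames(x), ex$sample_id)
  subj <- ex$subject_id[match(cols, ex$sample_id)]
  vals <- .values(x)[, cols, drop = FALSE]
  labels <- unclass(assignment)
  mods <- unique(labels)
  ve <- stats::setNames(numeric(length(mods)), mods)
  out <- list()
  for (m in mods) {
    members <- intersect(names(labels)[labels == m], rownames(vals))
    eig <- eigenmetabolite(vals, members)
    z <- t(scale(t(vals[members, , drop = FALSE])))
    zm <- colMeans(z)
    ve[m] <- eig$var_explained
    out[[m]] <- data.frame(subject_id = subj, module = m,
                           eigenmetabolite = as.numeric(eig$scores),
                           zscore_mean = as.numeric(zm),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  structure(res, var_explained = ve,
            class = c("module_representatives", "data.frame"))
}

# standardized simple / group-adjusted regression of a trait on a module
# representative; beta is the coefficient after z-scoring both variables
.std_lm <- function(y, z, group = NULL) {
  ok <- stats::complete.cases(y, z)
  y <- y[ok]; z <- z[ok]
  n <- length(y)
  if (n < 3L || stats::sd(y) == 0 || stats::sd(z) == 0)
    return(list(beta = NA_real_, p = NA_real_, n = n, testable = FALSE))
  ys <- as.numeric(scale(y)); zs <- as.numeric(scale(z))
  if (is.null(group)) {
    fit <- stats::lm(ys ~ zs)
  } else {
    g <- factor(group[ok])
    fit <- if (nlevels(g) > 1L) stats::lm(ys ~ zs + g) else stats::lm(ys ~ zs)
  }
  sm <- summary(fit)$coefficients
  list(beta = sm["zs", "Estimate"], p = sm["zs", "Pr(>|t|)"], n = n,
       testable = TRUE)
}

#' Module-trait association by linear models
#'
#' For every (module, trait) pair, regresses the trait on the module
#' representative, both z-scored, so the standardized beta of a simple model
#' equals the Pearson correlation. Both representative measures are tested:
#' eigenmetabolite models supply the default p-values, z-score-mean models
#' the effect directions for visualization. `adjust_for_group` adds athlete
#' group indicator covariates (control as reference), which absorbs
#' between-group differences so that purely group-driven trait associations
#' vanish. BH-FDR is applied within each measure across the
#' modules-by-traits family.
#'
#' @param reps [module_representatives()].
#' @param traits trait table (`subject_id` + numeric trait columns); subjects
#'   with a missing trait are dropped pairwise per model.
#' @param meta sample metadata (needed when `adjust_for_group = TRUE`).
#' @param adjust_for_group logical.
#' @return data.frame: `module`, `trait`, `measure`, `beta`, `p`, `p_fdr`,
#'   `n`, `testable`, `group_adjusted`.
#' @export
module_trait_lm <- function(reps, traits, meta = NULL,
                            adjust_for_group = FALSE) {
  trait_names <- setdiff(names(traits), "subject_id")
  group <- NULL
  if (adjust_for_group) {
    if (is.null(meta)) stop("meta is required when adjust_for_group = TRUE")
    ex <- .experimental(meta)
    group <- stats::setNames(ex$group, ex$subject_id)
    group <- group[!duplicated(names(group))]
    group <- factor(group, levels = c("control",
                                      setdiff(unique(group), "control")))
  }
  rows <- list()
  for (measure in c("eigenmetabolite", "zscore_mean")) {
    for (m in unique(reps$module)) {
      rm <- reps[reps$module == m, , drop = FALSE]
      z <- stats::setNames(rm[[measure]], rm$subject_id)
      for (tr in trait_names) {
        y <- stats::setNames(traits[[tr]], traits$subject_id)
        common <- intersect(names(z), names(y))
        fit <- .std_lm(y[common], z[common],
                       group = if (adjust_for_group)
                         as.character(group[common]) else NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, trait = tr, measure = measure, beta = fit$beta,
          p = fit$p, n = fit$n, testable = fit$testable,
          group_adjusted = adjust_for_group, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_fdr <- NA_real_
  for (measure in unique(out$measure)) {
    i <- out$measure == measure
    out$p_fdr[i] <- adjust_pvalues(out$p[i], "bh")
  }
  out[, c("module", "trait", "measure", "beta", "p", "p_fdr", "n",
          "testable", "group_adjusted")]
}

#' Tukey-Kramer all-pairs comparisons
#'
#' Post-hoc pairwise group comparisons after a one-way ANOVA, generalized to
#' unequal group sizes: for groups i, j the studentized-range statistic is
#' `q = |m_i - m_j| / sqrt((MSE / 2) (1/n_i + 1/n_j))` and the familywise
#' p-value is the upper tail of the studentized-range distribution with
#' `k` means and the ANOVA residual degrees of freedom.
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 levels with >= 2 observations each).
#' @return data.frame: `group1`, `group2`, `diff`, `p`.
#' @export
tukey_kramer <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; g <- factor(groups[ok])
  k <- nlevels(g)
  n_i <- tabulate(g)
  if (k < 2L || any(n_i < 2L))
    stop("Tukey-Kramer needs >= 2 groups with >= 2 observations each")
  m_i <- tapply(values, g, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / df
  pairs <- utils::combn(levels(g), 2L)
  res <- apply(pairs, 2L, function(pr) {
    i <- match(pr[1L], levels(g)); j <- match(pr[2L], levels(g))
    diff <- m_i[i] - m_i[j]
    se <- sqrt(mse / 2 * (1 / n_i[i] + 1 / n_i[j]))
    q <- abs(diff) / se
    c(diff = diff, p = stats::ptukey(q, k, df, lower.tail = FALSE))
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             diff = res[1L, ], p = res[2L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

# one-way ANOVA F and p for a single response vector
.oneway_f <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  v <- values[ok]; g <- factor(groups[ok])
  g <- droplevels(g)
  k <- nlevels(g); n <- length(v)
  if (k < 2L || n - k < 1L) return(c(F = NA_real_, p = NA_real_))
  gm <- tapply(v, g, mean); gn <- tabulate(g)
  ssb <- sum(gn * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  if (ssw == 0) {
    f <- if (ssb == 0) NA_real_ else Inf
    return(c(F = f, p = if (is.na(f)) NA_real_ else 0))
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  c(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Module-group association by one-way ANOVA with Tukey post-hoc tests
#'
#' Tests each module's eigenmetabolite (and mean z-score) against athlete
#' group assignment with a one-way ANOVA; for modules tested post hoc,
#' Tukey-Kramer comparisons identify which group pairs differ. The
#' module-level Bonferroni threshold `0.05 / n_modules` is reported.
#'
#' @param reps [module_representatives()].
#' @param meta sample metadata.
#' @param posthoc run Tukey-Kramer comparisons (default `TRUE`).
#' @param measure representative used for testing (default eigenmetabolite).
#' @return list of class `module_group_anova`: `anova` (module, F, p,
#'   p_bonferroni), `posthoc` (module, group1, group2, diff, p) and
#'   `bonferroni_threshold`.
#' @export
module_group_anova <- function(reps, meta, posthoc = TRUE,
                               measure = "eigenmetabolite") {
  ex <- .experimental(meta)
  group <- stats::setNames(ex$group, ex$subject_id)
  group <- group[!duplicated(names(group))]
  mods <- unique(reps$module)
  an <- lapply(mods, function(m) {
    rm <- reps[reps$module == m, , drop = FALSE]
    g <- group[rm$subject_id]
    fp <- .oneway_f(rm[[measure]], g)
    data.frame(module = m, F = fp["F"], p = fp["p"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  an <- do.call(rbind, an)
  an$p_bonferroni <- adjust_pvalues(an$p, "bonferroni")
  ph <- NULL
  if (posthoc) {
    ph <- lapply(mods, function(m) {
      rm <- reps[reps$module == m, , drop = FALSE]
      tk <- tukey_kramer(rm[[measure]], group[rm$subject_id])
      cbind(module = m, tk, stringsAsFactors = FALSE)
    })
    ph <- do.call(rbind, c(ph, make.row.names = FALSE))
  }
  structure(list(anova = an, posthoc = ph,
                 bonferroni_threshold = 0.05 / length(mods)),
            class = "module_group_anova")
}

#' @export
print.module_group_anova <- function(x, ...) {
  cat("module ~ group one-way ANOVA (Bonferroni threshold",
      format(x$bonferroni_threshold, digits = 3), ")\n")
  print(x$anova, digits = 3)
  invisible(x)
}

#' Per-metabolite group association
#'
#' One-way ANOVA of each metabolite's baseline abundance on athlete group,
#' with Tukey-Kramer pairwise comparisons and both Bonferroni and BH-FDR
#' adjustment across the metabolite family.
#'
#' @param x QC'd log2 [ion_matrix].
#' @param meta sample metadata; baseline experimental samples are used.
#' @param posthoc run Tukey-Kramer comparisons per metabolite.
#' @return list with `anova` (metabolite_id, F, p, p_bonferroni, p_fdr) and
#'   `posthoc` (metabolite_id, group1, group2, diff, p; `NULL` if disabled).
#' @export
per_metabolite_group_test <- function(x, meta, posthoc = TRUE) {
  ex <- .experimental(meta)
  ex <- ex[ex$timepoint == "baseline", , drop = FALSE]
  cols <- intersect(colnames(x), ex$sample_id)
  g <- factor(ex$group[match(cols, ex$sample_id)])
  vals <- .values(x)[, cols, drop = FALSE]
  fp <- t(apply(vals, 1L, .oneway_f, groups = g))
  an <- data.frame(metabolite_id = rownames(vals), F = fp[, "F"],
                   p = fp[, "p"], row.names = NULL, stringsAsFactors = FALSE)
  an$p_bonferroni <- adjust_pvalues(an$p, "bonferroni")
  an$p_fdr <- adjust_pvalues(an$p, "bh")
  ph <- NULL
  if (posthoc) {
    ph <- lapply(seq_len(nrow(vals)), function(i) {
      tk <- tukey_kramer(vals[i, ], g)
      cbind(metabolite_id = rownames(vals)[i], tk, stringsAsFactors = FALSE)
    })
    ph <- do.call(rbind, c(ph, make.row.names = FALSE))
  }
  list(anova = an, posthoc = ph)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up FDR adjustment
#' (with enforced monotonicity), as used throughout the package's testing
#' families.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
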