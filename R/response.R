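#' Per-subject log2 fold changes
#'
#' Post-exercise minus baseline abundance per subject on the log2 scale
#' (+1 = doubling). Subjects lacking either timepoint for a metabolite, and
#' (metabolite, subject) pairs blanked by the IQR outlier rule, contribute
#' `NA`.
#'
#' @param x log2-scale [ion_matrix].
#' @param meta sample metadata.
#' @param exclude optional data.frame with columns `metabolite_id`,
#'   `subject_id` of pairs to blank (typically `report$iqr_flagged` from
#'   [run_qc()]).
#' @return metabolite-by-subject matrix of fold changes.
#' @export
log2_fold_changes <- function(x, meta, exclude = NULL) {
  stopifnot(is_log_scale(x))
  ex <- .experimental(meta)
  base <- ex[ex$timepoint == "baseline", , drop = FALSE]
  post <- ex[ex$timepoint == "post", , drop = FALSE]
  subjects <- intersect(base$subject_id, post$subject_id)
  bcol <- base$sample_id[match(subjects, base$subject_id)]
  pcol <- post$sample_id[match(subjects, post$subject_id)]
  keep <- bcol %in% colnames(x) & pcol %in% colnames(x)
  subjects <- subjects[keep]; bcol <- bcol[keep]; pcol <- pcol[keep]
  vals <- .values(x)
  fc <- vals[, pcol, drop = FALSE] - vals[, bcol, drop = FALSE]
  colnames(fc) <- subjects
  if (!is.null(exclude) && nrow(exclude)) {
    i <- match(exclude$metabolite_id, rownames(fc))
    j <- match(exclude$subject_id, colnames(fc))
    ok <- !is.na(i) & !is.na(j)
    fc[cbind(i[ok], j[ok])] <- NA_real_
  }
  fc
}

# row-wise paired t on a difference matrix: t = mean / (sd / sqrt(n));
# zero-variance differences are "no evidence of change" (p = 1 by convention)
.row_paired_t <- function(d) {
  n <- rowSums(!is.na(d))
  m <- rowMeans(d, na.rm = TRUE)
  sd <- apply(d, 1L, stats::sd, na.rm = TRUE)
  t <- m / (sd / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  p[!is.na(sd) & sd == 0] <- 1
  t[!is.na(sd) & sd == 0] <- 0
  p[n < 2L] <- NA_real_
  t[n < 2L] <- NA_real_
  data.frame(mean_fc = m, t = t, p = p, n = n)
}

#' Two-tier paired exercise-response tests
#'
#' Per metabolite, two-sided paired t-tests of baseline vs post-exercise
#' abundance over all subjects and separately within each athlete group.
#' Tier 1 requires the overall p-value below the Bonferroni threshold
#' `alpha / m` (m = metabolites tested); tier 2 additionally requires
#' p < `alpha_group` in every group. Groups with fewer than two complete
#' pairs are untestable and excluded from the tier-2 flag. Zero-variance
#' differences are treated as no change (p = 1).
#'
#' @param x log2 [ion_matrix].
#' @param meta sample metadata.
#' @param alpha_overall tier-1 threshold; `NULL` uses `0.05 / nrow(x)` (the
#'   exact quotient, not a rounded value).
#' @param alpha_group per-group tier-2 threshold (default 0.05).
#' @param exclude IQR-blanked pairs, as in [log2_fold_changes()].
#' @return data.frame: per metabolite the overall and per-group mean fold
#'   change, t, p and n, plus `tier1` and `tier2` flags; the thresholds are
#'   attached as attributes.
#' @export
paired_tests <- function(x, meta, alpha_overall = NULL, alpha_group = 0.05,
                         exclude = NULL) {
  fc <- log2_fold_changes(x, meta, exclude = exclude)
  if (is.null(alpha_overall)) alpha_overall <- 0.05 / nrow(fc)
  ex <- .experimental(meta)
  group <- stats::setNames(ex$group, ex$subject_id)
  group <- group[!duplicated(names(group))]
  g <- group[colnames(fc)]
  overall <- .row_paired_t(fc)
  out <- data.frame(metabolite_id = rownames(fc),
                    mean_fc = overall$mean_fc, t = overall$t, p = overall$p,
                    n = overall$n, row.names = NULL, stringsAsFactors = FALSE)
  groups <- unique(g)
  group_ok <- matrix(TRUE, nrow(fc), length(groups),
                     dimnames = list(NULL, groups))
  for (gr in groups) {
    sub <- .row_paired_t(fc[, g == gr, drop = FALSE])
    out[[paste0("mean_fc_", gr)]] <- sub$mean_fc
    out[[paste0("t_", gr)]] <- sub$t
    out[[paste0("p_", gr)]] <- sub$p
    out[[paste0("n_", gr)]] <- sub$n
    group_ok[, gr] <- !is.na(sub$p) & sub$p < alpha_group
  }
  out$tier1 <- !is.na(out$p) & out$p < alpha_overall
  out$tier2 <- out$tier1 & rowSums(group_ok) == length(groups)
  structure(out, alpha_overall = alpha_overall, alpha_group = alpha_group)
}

#' Group-specific response ANOVA on log2 fold changes
#'
#' Per metabolite, a one-way ANOVA of the per-subject log2 fold change on
#' athlete group identifies metabolites whose exercise response differs
#' between groups (`differential`, p < alpha); Tukey-Kramer pairwise
#' contrasts locate the differing groups (an unadjusted Welch variant is
#' available). `differential_and_changed` additionally requires a nominal
#' within-group change (paired p < 0.05 in at least one group).
#'
#' @param x log2 [ion_matrix].
#' @param meta sample metadata.
#' @param alpha differential threshold (default 0.05).
#' @param posthoc run pairwise contrasts.
#' @param pairwise `"tukey"` (default) or `"welch"` (unadjusted Welch tests).
#' @param exclude IQR-blanked pairs.
#' @param paired result of [paired_tests()]; computed if `NULL`.
#' @return list of class `response_result`: `table` (per-metabolite results
#'   combining paired tests, ANOVA, flags and FDR) and `posthoc`.
#' @export
response_anova <- function(x, meta, alpha = 0.05, posthoc = TRUE,
                           pairwise = c("tukey", "welch"), exclude = NULL,
                           paired = NULL) {
  pairwise <- match.arg(pairwise)
  fc <- log2_fold_changes(x, meta, exclude = exclude)
  ex <- .experimental(meta)
  group <- stats::setNames(ex$group, ex$subject_id)
  group <- group[!duplicated(names(group))]
  g <- factor(group[colnames(fc)])
  fp <- t(apply(fc, 1L, .oneway_f, groups = g))
  if (is.null(paired)) paired <- paired_tests(x, meta, exclude = exclude)
  tab <- paired
  tab$anova_F <- fp[, "F"]
  tab$anova_p <- fp[, "p"]
  tab$anova_p_fdr <- adjust_pvalues(tab$anova_p, "bh")
  tab$differential <- !is.na(tab$anova_p) & tab$anova_p < alpha
  p_cols <- grep("^p_", names(tab), value = TRUE)
  any_changed <- apply(as.matrix(tab[, p_cols, drop = FALSE]), 1L,
                       function(z) any(!is.na(z) & z < 0.05))
  tab$differential_and_changed <- tab$differential & any_changed
  ph <- NULL
  if (posthoc) {
    ph <- lapply(seq_len(nrow(fc)), function(i) {
      v <- fc[i, ]
      if (pairwise == "tukey") {
        tk <- tukey_kramer(v, g)
      } else {
        pairs <- utils::combn(levels(g), 2L)
        tk <- do.call(rbind, apply(pairs, 2L, function(pr) {
          a <- v[g == pr[1L]]; b <- v[g == pr[2L]]
          tt <- stats::t.test(a[!is.na(a)], b[!is.na(b)])
          data.frame(group1 = pr[1L], group2 = pr[2L],
                     diff = mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE),
                     p = tt$p.value, stringsAsFactors = FALSE)
        }))
      }
      cbind(metabolite_id = rownames(fc)[i], tk, stringsAsFactors = FALSE)
    })
    ph <- do.call(rbind, c(ph, make.row.names = FALSE))
  }
  structure(list(table = tab, posthoc = ph, alpha = alpha),
            class = "response_result")
}

#' @export
print.response_result <- function(x, ...) {
  cat(sprintf(
    "exercise response: %d metabolites | tier1 %d | tier2 %d | differential %d | differential-and-changed %d\n",
    nrow(x$table), sum(x$table$tier1), sum(x$table$tier2),
    sum(x$table$differential), sum(x$table$differential_and_changed)))
  invisible(x)
}
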