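#' Match modules between two timepoints by membership overlap
#'
#' Pairs non-grey baseline modules with non-grey post-exercise modules by
#' greedy descent on intersection size (ties broken by larger Jaccard index,
#' then by label order); grey is matched to grey. For every pair the overlap
#' count, Jaccard index and a hypergeometric overlap p-value are reported;
#' modules left without a partner are listed as unmatched.
#'
#' @param base,post `module_assignment` objects over the same metabolites.
#' @return data.frame of class `module_match` with columns `baseline`,
#'   `post`, `overlap`, `jaccard`, `p_hyper`; unmatched labels are stored in
#'   attributes `unmatched_baseline` / `unmatched_post`.
#' @export
match_modules <- function(base, post) {
  if (!setequal(names(base), names(post)))
    stop("baseline and post assignments cover different metabolite sets")
  post <- post[names(base)]
  n_univ <- length(base)
  bl <- unclass(base); pl <- unclass(post)
  bmods <- setdiff(unique(bl), "grey")
  pmods <- setdiff(unique(pl), "grey")
  rows <- list()
  avail_b <- bmods; avail_p <- pmods
  while (length(avail_b) && length(avail_p)) {
    ov <- outer(avail_b, avail_p, Vectorize(function(b, p)
      sum(bl == b & pl == p)))
    if (max(ov) < 1L) break
    jac <- outer(avail_b, avail_p, Vectorize(function(b, p) {
      i <- sum(bl == b & pl == p)
      i / (sum(bl == b) + sum(pl == p) - i)
    }))
    cand <- which(ov == max(ov), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      jc <- jac[cand]
      cand <- cand[jc == max(jc), , drop = FALSE]
      ord <- order(avail_b[cand[, 1L]], avail_p[cand[, 2L]])
      cand <- cand[ord, , drop = FALSE]
    }
    b <- avail_b[cand[1L, 1L]]; p <- avail_p[cand[1L, 2L]]
    nb <- sum(bl == b); np <- sum(pl == p); k <- sum(bl == b & pl == p)
    rows[[length(rows) + 1L]] <- data.frame(
      baseline = b, post = p, overlap = k, jaccard = k / (nb + np - k),
      p_hyper = stats::phyper(k - 1, nb, n_univ - nb, np, lower.tail = FALSE),
      stringsAsFactors = FALSE)
    avail_b <- setdiff(avail_b, b); avail_p <- setdiff(avail_p, p)
  }
  k_grey <- sum(bl == "grey" & pl == "grey")
  nb <- sum(bl == "grey"); np <- sum(pl == "grey")
  if (nb && np)
    rows[[length(rows) + 1L]] <- data.frame(
      baseline = "grey", post = "grey", overlap = k_grey,
      jaccard = k_grey / (nb + np - k_grey),
      p_hyper = stats::phyper(k_grey - 1, nb, n_univ - nb, np,
                              lower.tail = FALSE),
      stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  structure(out, unmatched_baseline = avail_b, unmatched_post = avail_p,
            class = c("module_match", "data.frame"))
}

#' Refine matched modules to their cross-timepoint consensus
#'
#' A consensus module is the intersection of a matched baseline/post module
#' pair: only metabolites assigned to the same module at both timepoints are
#' kept (consensus grey is grey-at-both). Metabolites outside every
#' intersection are dropped from module-level analyses rather than
#' re-assigned to grey; they remain available for per-metabolite tests.
#'
#' @param base,post `module_assignment` objects.
#' @param match result of [match_modules()]; computed if `NULL`.
#' @return `module_assignment` over the retained metabolites only, labelled
#'   by the baseline module colors, with timepoint `"consensus"`.
#' @export
consensus_refine <- function(base, post, match = NULL) {
  if (is.null(match)) match <- match_modules(base, post)
  post <- post[names(base)]
  bl <- unclass(base); pl <- unclass(post)
  keep <- character(0)
  lab <- character(0)
  for (r in seq_len(nrow(match))) {
    ids <- names(base)[bl == match$baseline[r] & pl == match$post[r]]
    keep <- c(keep, ids)
    lab <- c(lab, rep(match$baseline[r], length(ids)))
  }
  module_assignment(stats::setNames(lab, keep), timepoint = "consensus")
}
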