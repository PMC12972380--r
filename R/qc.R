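#' Flag samples with outlying missingness
#'
#' A sample is flagged when its fraction of missing metabolite measurements
#' exceeds the mean missingness over all samples plus five standard
#' deviations (SD with the n-1 denominator).
#'
#' @param x raw [ion_matrix].
#' @param meta sample metadata; only experimental samples are considered.
#' @param n_sd number of SDs above the mean (default 5).
#' @return character vector of flagged sample ids (possibly empty), with the
#'   per-sample missingness fractions and the threshold as attributes.
#' @export
flag_sample_outliers <- function(x, meta, n_sd = 5) {
  cols <- .exp_cols(x, meta)
  if (length(cols) < 2L)
    stop("sample-missingness outlier check needs at least 2 experimental ",
         "samples (SD undefined)")
  frac <- colMeans(is.na(.values(x)[, cols, drop = FALSE]))
  thr <- mean(frac) + n_sd * stats::sd(frac)
  flagged <- names(frac)[frac > thr]
  structure(flagged, missingness = frac, threshold = thr)
}

#' Batch-median normalization against reference-serum aliquots
#'
#' Divides every value of a metabolite by the per-batch median of that
#' metabolite in the batch's reference-serum aliquots, removing multiplicative
#' batch effects. After normalization the reference-serum values of each batch
#' have median exactly 1 for every scaled metabolite. If fewer than two
#' reference values are present for a metabolite in a batch, that
#' (metabolite, batch) stays unscaled and is flagged (with a warning).
#'
#' @param x raw ion-count [ion_matrix].
#' @param meta sample metadata.
#' @return the normalized [ion_matrix]; flagged (metabolite, batch) pairs are
#'   attached as attribute `"unscaled"` (a data.frame).
#' @export
batch_median_normalize <- function(x, meta) {
  stopifnot(!is_log_scale(x))
  vals <- .values(x)
  unscaled <- data.frame(metabolite_id = character(0), batch = character(0),
                         stringsAsFactors = FALSE)
  for (b in unique(meta$batch)) {
    ref <- meta$sample_id[meta$role == "reference_serum" & meta$batch == b]
    ref <- intersect(ref, colnames(vals))
    incol <- intersect(meta$sample_id[meta$batch == b], colnames(vals))
    if (!length(incol)) next
    if (length(ref) < 2L)
      stop("batch '", b, "' has fewer than 2 reference_serum wells in the matrix")
    med <- apply(vals[, ref, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    n_present <- rowSums(!is.na(vals[, ref, drop = FALSE]))
    bad <- n_present < 2L | is.na(med) | med == 0
    if (any(bad)) {
      unscaled <- rbind(unscaled,
                        data.frame(metabolite_id = rownames(vals)[bad],
                                   batch = b, stringsAsFactors = FALSE))
      med[bad] <- 1
    }
    vals[, incol] <- vals[, incol, drop = FALSE] / med
  }
  if (nrow(unscaled))
    warning(nrow(unscaled), " (metabolite, batch) pair(s) left unscaled: ",
            "reference values missing")
  out <- ion_matrix(vals, log_scale = FALSE)
  attr(out, "unscaled") <- unscaled
  out
}

#' Coefficient-of-variation filter on reference aliquots
#'
#' Computes, per metabolite, the CV (%) = 100 * sd / mean over the normalized
#' reference-aliquot values (reference-serum wells pooled across batches by
#' default) and removes metabolites whose CV exceeds the threshold.
#' Metabolites with an undefined CV (fewer than two present replicate values,
#' or mean zero) are also removed and flagged as undefined.
#'
#' @param x batch-normalized, non-log [ion_matrix].
#' @param meta sample metadata.
#' @param threshold_pct CV threshold in percent (default 25).
#' @param role replicate role used for the CV (default `"reference_serum"`).
#' @param per_batch if `TRUE`, compute the CV per batch and aggregate by the
#'   maximum instead of pooling replicates.
#' @return list with `matrix` (retained metabolites), `cv` (named CV vector,
#'   `NA` where undefined) and `excluded` (character vector of removed ids).
#' @export
cv_filter <- function(x, meta, threshold_pct = 25,
                      role = "reference_serum", per_batch = FALSE) {
  stopifnot(!is_log_scale(x))
  ref <- meta$sample_id[meta$role == role]
  ref <- intersect(ref, colnames(x))
  if (!length(ref))
    stop("no replicate wells with role '", role, "' found in the matrix")
  vals <- .values(x)
  cv_of <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    100 * stats::sd(v) / m
  }
  if (per_batch) {
    cvb <- sapply(unique(meta$batch[meta$sample_id %in% ref]), function(b) {
      rb <- intersect(ref, meta$sample_id[meta$batch == b])
      apply(vals[, rb, drop = FALSE], 1L, cv_of)
    })
    cv <- apply(as.matrix(cvb), 1L, function(z)
      if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
  } else {
    cv <- apply(vals[, ref, drop = FALSE], 1L, cv_of)
  }
  names(cv) <- rownames(vals)
  drop <- is.na(cv) | cv > threshold_pct
  list(matrix = x[!drop, , drop = FALSE], cv = cv,
       excluded = rownames(vals)[drop])
}

#' Missingness filter
#'
#' Removes metabolites whose fraction of missing values over the experimental
#' samples strictly exceeds the threshold (exactly 30% is retained).
#'
#' @param x [ion_matrix].
#' @param meta sample metadata; missingness is defined on experimental
#'   samples only. `NULL` uses all columns.
#' @param threshold missingness fraction (default 0.30).
#' @return list with `matrix` (retained), `missingness` (named fractions) and
#'   `excluded` (removed ids).
#' @export
missingness_filter <- function(x, meta = NULL, threshold = 0.30) {
  cols <- if (is.null(meta)) colnames(x) else .exp_cols(x, meta)
  frac <- rowMeans(is.na(.values(x)[, cols, drop = FALSE]))
  drop <- frac > threshold
  list(matrix = x[!drop, , drop = FALSE], missingness = frac,
       excluded = rownames(x)[drop])
}

#' Log2 transformation
#'
#' Cell-wise log2; missing values stay missing. Zero or negative values are an
#' error naming the offending cell -- no silent pseudocount is added.
#'
#' @param x non-log [ion_matrix] with all present values > 0.
#' @return log2-scale [ion_matrix].
#' @export
log2_transform <- function(x) {
  stopifnot(!is_log_scale(x))
  vals <- .values(x)
  bad <- which(vals <= 0 & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive value at metabolite '", rownames(vals)[bad[1L, 1L]],
         "', sample '", colnames(vals)[bad[1L, 2L]],
         "': cannot log2 transform")
  ion_matrix(log2(vals), log_scale = TRUE)
}

# Pairwise metabolite distances on jointly observed samples, rescaled by the
# number of overlapping samples:  d_ij = sqrt( sum_joint (x_i - x_j)^2 / n_joint ).
# Computed with three matrix products so imputation stays fast at 1000+ rows.
.overlap_distance <- function(vals) {
  obs <- !is.na(vals)
  y <- vals
  y[!obs] <- 0
  w <- obs * 1
  n_joint <- tcrossprod(w)
  s2 <- tcrossprod(y^2, w)        # sum over joint of x_i^2
  cross <- tcrossprod(y)          # sum over joint of x_i x_j
  d2 <- (s2 + t(s2) - 2 * cross) / n_joint
  d2[n_joint == 0] <- NA_real_
  d2[d2 < 0] <- 0                 # numerical noise
  sqrt(d2)
}

#' k-nearest-neighbour imputation in metabolite space
#'
#' Fills each missing cell (metabolite i, sample s) with the mean of the
#' sample-s values of the k metabolites nearest to i. Nearness is Euclidean
#' distance over jointly observed samples, rescaled by the number of
#' overlapping samples; donor candidates are restricted to metabolites
#' observed in sample s. With fewer than k candidates all available donors
#' are used; with none, the metabolite's own observed mean is used. Ties in
#' distance are broken by metabolite id order, so the result is deterministic.
#'
#' @param x log-scale [ion_matrix] (experimental samples).
#' @param k number of donor neighbours (default 10).
#' @return fully imputed [ion_matrix]; observed cells are never altered.
#' @export
knn_impute <- function(x, k = 10) {
  vals <- .values(x)
  if (!anyNA(vals)) return(x)
  n_obs <- rowSums(!is.na(vals))
  if (any(n_obs == 0))
    stop("metabolite '", rownames(vals)[which(n_obs == 0)[1L]],
         "' has no observed values; apply the missingness filter first")
  d <- .overlap_distance(vals)
  diag(d) <- NA_real_
  row_mean <- rowMeans(vals, na.rm = TRUE)
  out <- vals
  miss <- which(is.na(vals), arr.ind = TRUE)
  id_rank <- seq_len(nrow(vals))  # rows are already in id order
  for (s in unique(miss[, 2L])) {
    rows <- miss[miss[, 2L] == s, 1L]
    donors_s <- which(!is.na(vals[, s]))
    for (i in rows) {
      cand <- donors_s[!is.na(d[i, donors_s])]
      if (!length(cand)) {
        out[i, s] <- row_mean[i]
        next
      }
      ord <- cand[order(d[i, cand], id_rank[cand])]
      use <- ord[seq_len(min(k, length(ord)))]
      out[i, s] <- mean(vals[use, s])
    }
  }
  ion_matrix(out, log_scale = TRUE)
}

#' Interquartile-range outlier removal
#'
#' Per metabolite, computes the median and IQR (type-7 quantiles) over all
#' experimental samples (both timepoints) and flags cells strictly outside
#' `[median - m*IQR, median + m*IQR]`. For every flagged (metabolite, subject)
#' pair, both of that subject's timepoint cells for the metabolite are set
#' missing, so that a paired analysis never uses a half-blanked pair.
#'
#' @param x log-scale, imputed [ion_matrix].
#' @param meta sample metadata.
#' @param multiplier IQR multiplier (default 3).
#' @return list with `matrix` (cells blanked), `flagged` (data.frame of
#'   flagged points: metabolite_id, sample_id, subject_id), `n_flagged`
#'   (count of out-of-bounds points) and `n_blanked` (cells set missing).
#' @export
iqr_outlier_removal <- function(x, meta, multiplier = 3) {
  cols <- .exp_cols(x, meta)
  vals <- .values(x)
  ev <- vals[, cols, drop = FALSE]
  med <- apply(ev, 1L, stats::median, na.rm = TRUE)
  iqr <- apply(ev, 1L, stats::IQR, na.rm = TRUE, type = 7)
  lo <- med - multiplier * iqr
  hi <- med + multiplier * iqr
  bad <- (ev < lo | ev > hi) & !is.na(ev)
  idx <- which(bad, arr.ind = TRUE)
  subj <- meta$subject_id[match(cols, meta$sample_id)]
  flagged <- data.frame(metabolite_id = rownames(ev)[idx[, 1L]],
                        sample_id = cols[idx[, 2L]],
                        subject_id = subj[idx[, 2L]],
                        stringsAsFactors = FALSE)
  n_blanked <- 0L
  if (nrow(flagged)) {
    pairs <- unique(flagged[, c("metabolite_id", "subject_id")])
    for (r in seq_len(nrow(pairs))) {
      scols <- cols[subj == pairs$subject_id[r]]
      before <- sum(!is.na(vals[pairs$metabolite_id[r], scols]))
      vals[pairs$metabolite_id[r], scols] <- NA_real_
      n_blanked <- n_blanked + before
    }
  }
  list(matrix = ion_matrix(vals, log_scale = is_log_scale(x)),
       flagged = flagged, n_flagged = nrow(flagged), n_blanked = n_blanked)
}

#' QC parameters
#'
#' @param cv_max CV threshold in percent.
#' @param miss_max missingness threshold (fraction).
#' @param k kNN donor count.
#' @param iqr_mult IQR multiplier.
#' @param sample_sd SD multiplier of the sample-missingness check.
#' @param cv_per_batch see [cv_filter()].
#' @param iqr_before_impute if `TRUE`, compute IQR statistics on the
#'   unimputed matrix instead of after the first imputation.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(cv_max = 25, miss_max = 0.30, k = 10, iqr_mult = 3,
                      sample_sd = 5, cv_per_batch = FALSE,
                      iqr_before_impute = FALSE) {
  structure(list(cv_max = cv_max, miss_max = miss_max, k = k,
                 iqr_mult = iqr_mult, sample_sd = sample_sd,
                 cv_per_batch = cv_per_batch,
                 iqr_before_impute = iqr_before_impute),
            class = "qc_params")
}

#' Run the full QC chain
#'
#' Executes the preprocessing stages in fixed order: sample-missingness
#' outlier check, batch-median normalization, CV filter, missingness filter,
#' log2 transformation, kNN imputation, IQR outlier removal, re-imputation.
#' The returned matrix contains experimental samples only and has no missing
#' cells.
#'
#' @param x raw ion-count [ion_matrix] (experimental + reference wells).
#' @param meta sample metadata.
#' @param params a [qc_params()].
#' @return object of class `qc_result`: list with `matrix` (final log2,
#'   imputed, experimental-only [ion_matrix]) and `report` (a `qc_report`
#'   list: flagged samples, per-metabolite CV and missingness, exclusion
#'   lists, IQR coordinates and stage counts).
#' @export
run_qc <- function(x, meta, params = qc_params()) {
  validate_samples(meta)
  n_input <- nrow(x)
  flagged_samples <- flag_sample_outliers(x, meta, n_sd = params$sample_sd)
  if (length(flagged_samples))
    x <- x[, setdiff(colnames(x), flagged_samples), drop = FALSE]

  norm <- batch_median_normalize(x, meta)
  cvf <- cv_filter(norm, meta, threshold_pct = params$cv_max,
                   per_batch = params$cv_per_batch)
  msf <- missingness_filter(cvf$matrix, meta, threshold = params$miss_max)

  exp_cols <- .exp_cols(msf$matrix, meta)
  lg <- log2_transform(msf$matrix[, exp_cols, drop = FALSE])
  imp <- knn_impute(lg, k = params$k)
  iqr_in <- if (params$iqr_before_impute) lg else imp
  iqr <- iqr_outlier_removal(iqr_in, meta, multiplier = params$iqr_mult)
  final <- knn_impute(iqr$matrix, k = params$k)

  report <- structure(list(
    sample_missingness = attr(flagged_samples, "missingness"),
    sample_threshold = attr(flagged_samples, "threshold"),
    flagged_samples = as.character(flagged_samples),
    unscaled = attr(norm, "unscaled"),
    cv = cvf$cv, cv_excluded = cvf$excluded,
    missingness = msf$missingness, missingness_excluded = msf$excluded,
    iqr_flagged = iqr$flagged, n_iqr_flagged = iqr$n_flagged,
    n_iqr_blanked = iqr$n_blanked,
    counts = c(input = n_input,
               cv_excluded = length(cvf$excluded),
               missingness_excluded = length(msf$excluded),
               retained = nrow(final))), class = "qc_report")
  structure(list(matrix = final, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  samples flagged for missingness: %d (threshold %.3f)\n",
              length(x$flagged_samples), x$sample_threshold))
  cat(sprintf("  metabolites: %d input, %d excluded by CV, %d by missingness, %d retained\n",
              x$counts["input"], x$counts["cv_excluded"],
              x$counts["missingness_excluded"], x$counts["retained"]))
  cat(sprintf("  IQR outliers: %d points flagged, %d cells blanked\n",
              x$n_iqr_flagged, x$n_iqr_blanked))
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  print(x$report)
  print(x$matrix)
  invisible(x)
}
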