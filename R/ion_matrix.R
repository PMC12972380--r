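#' Ion-count abundance matrix
#'
#' The central data container: a metabolite-by-sample matrix of relative
#' abundances (ion counts) or log2 abundances, with `NA` marking missing
#' measurements. Row names are metabolite identifiers, column names sample
#' identifiers; both must be unique, and on the raw (non-log) scale all
#' present values must be non-negative.
#'
#' @param values numeric matrix with unique, non-empty row and column names;
#'   `NA` entries are missing measurements.
#' @param log_scale logical; `TRUE` once values are log2-transformed.
#' @return an object of class `ion_matrix` (a numeric matrix with a
#'   `log_scale` attribute).
#' @examples
#' m <- matrix(c(10, 20, NA, 40), 2, 2,
#'             dimnames = list(c("m1", "m2"), c("s1", "s2")))
#' x <- ion_matrix(m)
#' missing_fraction(x)
#' @export
ion_matrix <- function(values, log_scale = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  ids <- rownames(values)
  sids <- colnames(values)
  if (is.null(ids) || is.null(sids) || any(ids == "") || any(sids == ""))
    stop("ion_matrix requires non-empty row (metabolite) and column (sample) names")
  if (anyDuplicated(ids))
    stop("duplicate metabolite id: ", ids[duplicated(ids)][1L])
  if (anyDuplicated(sids))
    stop("duplicate sample id: ", sids[duplicated(sids)][1L])
  if (!isTRUE(log_scale) && any(values < 0, na.rm = TRUE))
    stop("negative abundances are not allowed on the raw ion-count scale")
  structure(values, log_scale = isTRUE(log_scale),
            class = c("ion_matrix", class(values)))
}

#' @export
print.ion_matrix <- function(x, ...) {
  cat(sprintf("ion_matrix: %d metabolites x %d samples (%s scale), %.1f%% missing\n",
              nrow(x), ncol(x),
              if (is_log_scale(x)) "log2" else "ion-count",
              100 * missing_fraction(x)))
  invisible(x)
}

#' @rdname ion_matrix
#' @param x an `ion_matrix`.
#' @export
is_log_scale <- function(x) isTRUE(attr(x, "log_scale"))

#' @rdname ion_matrix
#' @export
missing_mask <- function(x) is.na(unclass(x))

#' @rdname ion_matrix
#' @export
missing_fraction <- function(x) mean(is.na(x))

## subsetting keeps the class and log flag (drop is forced off)
#' @export
`[.ion_matrix` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, drop = FALSE]
  ion_matrix(out, log_scale = is_log_scale(x))
}

# internal: strip class, keep dimnames
.values <- function(x) {
  v <- unclass(x)
  attr(v, "log_scale") <- NULL
  v
}

#' Validate a sample-metadata table
#'
#' Checks the per-sample annotation used throughout the pipeline: sample role
#' (`experimental`, `reference_serum`, `reference_plasma`, `blank`), subject,
#' athlete group, timepoint and measurement batch. Experimental samples must
#' carry subject, group and timepoint; each (subject, timepoint) pair may occur
#' at most once; and every batch containing experimental samples must contain
#' at least two reference-serum wells, without which batch-median normalization
#' is impossible.
#'
#' @param meta data.frame with columns `sample_id`, `subject_id`, `role`,
#'   `group`, `timepoint`, `batch`.
#' @return `meta`, invisibly, after validation.
#' @export
validate_samples <- function(meta) {
  req <- c("sample_id", "subject_id", "role", "group", "timepoint", "batch")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in sample table")
  roles <- c("experimental", "reference_serum", "reference_plasma", "blank")
  bad <- setdiff(unique(meta$role), roles)
  if (length(bad))
    stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  groups <- c("control", "bodybuilding", "endurance", "sprint", "")
  bad <- setdiff(unique(meta$group), groups)
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "))
  tps <- c("baseline", "post", "")
  bad <- setdiff(unique(meta$timepoint), tps)
  if (length(bad))
    stop("unknown timepoint(s): ", paste(bad, collapse = ", "))
  ex <- meta[meta$role == "experimental", , drop = FALSE]
  if (any(ex$subject_id == "" | ex$group == "" | ex$timepoint == ""))
    stop("experimental samples must have subject_id, group and timepoint")
  key <- paste(ex$subject_id, ex$timepoint)
  if (anyDuplicated(key))
    stop("duplicated (subject_id, timepoint) pair: ", key[duplicated(key)][1L])
  for (b in unique(ex$batch)) {
    n_ref <- sum(meta$role == "reference_serum" & meta$batch == b)
    if (n_ref < 2)
      stop("batch '", b, "' has experimental samples but fewer than 2 ",
           "reference_serum wells")
  }
  invisible(meta)
}

# internal helpers used across the pipeline
.experimental <- function(meta) meta[meta$role == "experimental", , drop = FALSE]

.exp_cols <- function(x, meta) {
  intersect(colnames(x), .experimental(meta)$sample_id)
}
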