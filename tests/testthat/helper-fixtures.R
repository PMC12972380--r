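# Shared fixture builders: a minimal experimental-only sample table (two
# timepoints per subject) and matching matrices, used wherever a full
# simulated cohort would be overkill.

exp_meta <- function(n_per_group = c(control = 3, bodybuilding = 3,
                                     endurance = 3, sprint = 3)) {
  subject <- sprintf("S%02d", seq_len(sum(n_per_group)))
  group <- rep(names(n_per_group), n_per_group)
  data.frame(
    sample_id = c(rbind(paste0(subject, "_pre"), paste0(subject, "_post"))),
    subject_id = rep(subject, each = 2L),
    role = "experimental",
    group = rep(group, each = 2L),
    timepoint = rep(c("baseline", "post"), length(subject)),
    batch = "B1",
    stringsAsFactors = FALSE)
}

null_log2_matrix <- function(n_met, meta, mean = 15, sd = 1) {
  v <- matrix(stats::rnorm(n_met * nrow(meta), mean, sd), n_met, nrow(meta),
              dimnames = list(sprintf("met_%03d", seq_len(n_met)),
                              meta$sample_id))
  ion_matrix(v, log_scale = TRUE)
}

# matrix whose post columns equal baseline + given per-metabolite differences
# (one column of `d` per subject), for closed-form paired-test checks
paired_matrix_from_diffs <- function(d, meta, base_value = 10) {
  ex <- meta[meta$role == "experimental", ]
  subjects <- unique(ex$subject_id)
  stopifnot(ncol(d) == length(subjects))
  v <- matrix(base_value, nrow(d), nrow(ex),
              dimnames = list(rownames(d), ex$sample_id))
  for (j in seq_along(subjects)) {
    pre <- ex$sample_id[ex$subject_id == subjects[j] &
                          ex$timepoint == "baseline"]
    post <- ex$sample_id[ex$subject_id == subjects[j] &
                           ex$timepoint == "post"]
    v[, post] <- v[, pre] + d[, j]
  }
  ion_matrix(v, log_scale = TRUE)
}
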