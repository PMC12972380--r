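#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with the study
#' defaults: CV threshold 25%, missingness threshold 0.30, kNN k = 10, IQR
#' multiplier 3, soft power 6, minimum module size 30, tier-1 threshold
#' `0.05 / m` and per-group threshold 0.05.
#'
#' @param qc a [qc_params()].
#' @param network a [network_params()].
#' @param alpha_overall tier-1 threshold; `NULL` = `0.05 / m` with m the
#'   retained metabolite count.
#' @param alpha_group per-group paired threshold.
#' @param alpha_response differential-response ANOVA threshold.
#' @param sim a [sim_config()] used when no input data are supplied.
#' @param seed seed governing the synthetic data (analysis stages are
#'   deterministic by construction); overrides `sim$seed`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_params(), network = network_params(),
                            alpha_overall = NULL, alpha_group = 0.05,
                            alpha_response = 0.05,
                            sim = sim_config(), seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(qc = qc, network = network, alpha_overall = alpha_overall,
                 alpha_group = alpha_group, alpha_response = alpha_response,
                 sim = sim),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains simulation (or supplied data), QC, baseline and post-exercise
#' network module detection, consensus refinement, module representatives,
#' module-trait and module-group association, per-metabolite group tests and
#' the exercise-response analysis, in that fixed order. Reruns with the same
#' configuration and inputs are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param data optional list with elements `matrix`, `samples`, `traits`
#'   (and optionally `truth`); when `NULL` a cohort is simulated from
#'   `config$sim`.
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV together with a JSON manifest of the effective
#'   parameters.
#' @return list of class `metmodnet_run` with elements `qc`, `modules_base`,
#'   `modules_post`, `match`, `consensus`, `representatives`,
#'   `module_trait`, `module_trait_adj`, `module_group`, `metabolite_group`,
#'   `response`, `truth` (if simulated) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (is.null(data)) {
    data <- simulate_cohort(config$sim)
    truth <- data$truth
  } else {
    if (is.null(data$matrix) || is.null(data$samples))
      stop("data must contain at least 'matrix' and 'samples'")
    truth <- data$truth
  }
  meta <- validate_samples(data$samples)

  qc <- run_qc(data$matrix, meta, config$qc)
  x <- qc$matrix

  ex <- .experimental(meta)
  base_cols <- intersect(colnames(x), ex$sample_id[ex$timepoint == "baseline"])
  post_cols <- intersect(colnames(x), ex$sample_id[ex$timepoint == "post"])
  mods_base <- detect_modules(x[, base_cols, drop = FALSE], config$network,
                              timepoint = "baseline")
  mods_post <- detect_modules(x[, post_cols, drop = FALSE], config$network,
                              timepoint = "post")
  match <- match_modules(mods_base$assignment, mods_post$assignment)
  consensus <- consensus_refine(mods_base$assignment, mods_post$assignment,
                                match)

  reps <- module_representatives(x, consensus, meta, timepoint = "baseline")
  mt <- mt_adj <- mg <- NULL
  if (!is.null(data$traits)) {
    mt <- module_trait_lm(reps, data$traits, meta, adjust_for_group = FALSE)
    mt_adj <- module_trait_lm(reps, data$traits, meta,
                              adjust_for_group = TRUE)
  }
  mg <- module_group_anova(reps, meta, posthoc = TRUE)
  pm <- per_metabolite_group_test(x, meta, posthoc = FALSE)
  resp <- response_anova(x, meta, alpha = config$alpha_response,
                         posthoc = FALSE,
                         exclude = qc$report$iqr_flagged,
                         paired = paired_tests(x, meta,
                                               alpha_overall = config$alpha_overall,
                                               alpha_group = config$alpha_group,
                                               exclude = qc$report$iqr_flagged))

  manifest <- list(seed = config$sim$seed,
                   qc = unclass(config$qc),
                   network = unclass(config$network),
                   alpha_group = config$alpha_group,
                   alpha_response = config$alpha_response,
                   n_metabolites_retained = nrow(x),
                   n_samples = ncol(x))
  run <- structure(list(qc = qc, modules_base = mods_base,
                        modules_post = mods_post, match = match,
                        consensus = consensus, representatives = reps,
                        module_trait = mt, module_trait_adj = mt_adj,
                        module_group = mg, metabolite_group = pm,
                        response = resp, truth = truth, manifest = manifest),
                   class = "metmodnet_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

# write all result tables + manifest next to each other
.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(run$qc$matrix, file.path(out_dir, "clean_matrix.tsv"))
  asg <- function(a) data.frame(metabolite_id = names(a),
                                module = as.character(unclass(a)),
                                stringsAsFactors = FALSE)
  write_table(asg(run$modules_base$assignment),
              file.path(out_dir, "modules_baseline.tsv"))
  write_table(asg(run$modules_post$assignment),
              file.path(out_dir, "modules_post.tsv"))
  write_table(as.data.frame(run$match), file.path(out_dir, "module_match.tsv"))
  write_table(asg(run$consensus), file.path(out_dir, "consensus.tsv"))
  write_table(as.data.frame(run$representatives),
              file.path(out_dir, "module_representatives.tsv"))
  if (!is.null(run$module_trait))
    write_table(rbind(run$module_trait, run$module_trait_adj),
                file.path(out_dir, "module_trait.tsv"))
  write_table(run$module_group$anova, file.path(out_dir, "module_group.tsv"))
  write_table(run$metabolite_group$anova,
              file.path(out_dir, "metabolite_group.tsv"))
  write_table(run$response$table, file.path(out_dir, "response.tsv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.metmodnet_run <- function(x, ...) {
  cat("metmodnet pipeline run\n")
  print(x$qc$report)
  print(x$consensus)
  print(x$response)
  invisible(x)
}

#' Adjusted Rand index between a module assignment and ground truth
#'
#' Compares detected module labels with the planted membership of a
#' simulated cohort on the non-background metabolites (background metabolites
#' carry no planted structure, so recovery is judged on planted members that
#' survived QC).
#'
#' @param assignment a `module_assignment`.
#' @param truth ground-truth list from [simulate_cohort()].
#' @return adjusted Rand index.
#' @export
module_recovery_ari <- function(assignment, truth) {
  planted <- names(truth$module)[truth$module > 0]
  common <- intersect(planted, names(assignment))
  if (!length(common)) return(NA_real_)
  mclust::adjustedRandIndex(truth$module[common],
                            unclass(assignment)[common])
}
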