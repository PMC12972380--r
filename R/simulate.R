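#' Simulation configuration for a two-batch, two-timepoint athlete cohort
#'
#' Defines the generative model behind [simulate_cohort()]: a latent-factor
#' cohort of four groups measured at baseline and immediately post exercise,
#' with planted correlated metabolite modules, group-specific module shifts,
#' traits driven by module latent factors, shared and group-specific exercise
#' responses, multiplicative batch effects, reference-serum aliquots,
#' abundance-dependent missingness and sporadic outliers.
#'
#' Defaults mirror the cohort design the pipeline targets: 7 untrained
#' controls, 9 bodybuilders, 11 endurance athletes and 8 sprinters (35
#' subjects, 70 experimental samples), 1020 metabolites of which five modules
#' of sizes 180/120/90/60/45 carry a shared latent factor tuned to a mean
#' absolute within-module correlation of 0.6, two measurement batches each
#' with four reference-serum and one reference-plasma well, 69 metabolites
#' with inflated technical variance (planted CV-filter failures) and 94
#' metabolites forced above 30% missingness (planted missingness-filter
#' failures).
#'
#' @param n_per_group named integer vector of subjects per group.
#' @param n_metabolites total number of metabolites.
#' @param module_sizes sizes of the planted modules (each must be at least the
#'   downstream minimum module size, 30).
#' @param within_module_cor target mean absolute pairwise correlation within a
#'   module, in `[0, 1)`.
#' @param group_module_shift groups x modules matrix of latent-factor shifts
#'   (in factor-SD units); `NULL` plants a +2 endurance shift on module 1, a
#'   -2 bodybuilding shift on module 2 and a +2 sprint shift on module 3.
#'   A single-group shift below ~1.6 SD has Cohen's f under the cohort's
#'   80%-power detectability limit (f = 0.743 at alpha = 0.05/6) and would be
#'   undetectable by construction.
#' @param n_response_shared,response_shift_shared number of metabolites with a
#'   shared exercise response and its log2 magnitude.
#' @param n_response_group,response_shift_group,response_group number of
#'   metabolites responding only in `response_group`, and the log2 magnitude.
#' @param batch_factor_sd SD of the per-(batch, metabolite) multiplicative
#'   log2 effect.
#' @param subject_sd SD of the per-(subject, metabolite) random intercept
#'   shared by the two timepoints (induces within-pair correlation).
#' @param missing_logit_intercept,missing_logit_slope logistic model for
#'   abundance-dependent (MNAR) missingness on the rank-abundance scale; the
#'   probability a cell is missing is
#'   `plogis(intercept + slope * (1 - rank_fraction))`.
#' @param mnar if `FALSE`, missingness ignores abundance (MCAR at the mean
#'   rate implied by the logistic parameters).
#' @param n_forced_missing,forced_missing_frac number of metabolites forced to
#'   a fixed missingness fraction above the 30% filter threshold.
#' @param n_high_cv number of metabolites with inflated reference-aliquot
#'   technical noise (`high_cv_ref_sd`); the remainder use `ref_noise_sd`.
#' @param ref_noise_sd,high_cv_ref_sd technical log2 SD of reference wells.
#' @param outlier_rate fraction of experimental cells multiplied by
#'   `2^(+/- outlier_log2_shift)`.
#' @param outlier_log2_shift log2 magnitude of injected outliers.
#' @param n_traits,n_module_traits,trait_noise_sd number of traits; the first
#'   `n_module_traits` traits equal the corresponding module's baseline latent
#'   factor plus `N(0, trait_noise_sd)` noise, the rest are pure noise.
#' @param baseline_mean,baseline_sd distribution of per-metabolite mean log2
#'   abundance.
#' @param seed integer seed fixing the full output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(control = 7, bodybuilding = 9,
                                       endurance = 11, sprint = 8),
                       n_metabolites = 1020,
                       module_sizes = c(180, 120, 90, 60, 45),
                       within_module_cor = 0.6,
                       group_module_shift = NULL,
                       n_response_shared = 60, response_shift_shared = 2.5,
                       n_response_group = 30, response_shift_group = 2,
                       response_group = "sprint",
                       batch_factor_sd = 0.1,
                       subject_sd = 0.3,
                       missing_logit_intercept = -6.5,
                       missing_logit_slope = 4,
                       mnar = TRUE,
                       n_forced_missing = 94, forced_missing_frac = 0.4,
                       n_high_cv = 69,
                       ref_noise_sd = 0.08, high_cv_ref_sd = 0.8,
                       outlier_rate = 0.01, outlier_log2_shift = 6,
                       n_traits = 22, n_module_traits = 5,
                       trait_noise_sd = 0.5,
                       baseline_mean = 17, baseline_sd = 1.5,
                       seed = 1L) {
  groups <- c("control", "bodybuilding", "endurance", "sprint")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (!setequal(names(n_per_group), groups))
    stop("n_per_group must be named with the four groups")
  n_per_group <- n_per_group[groups]
  if (sum(module_sizes) > n_metabolites)
    stop("module sizes (", sum(module_sizes),
         ") exceed the metabolite count (", n_metabolites, ")")
  if (within_module_cor < 0 || within_module_cor >= 1)
    stop("within_module_cor must be in [0, 1)")
  if (batch_factor_sd < 0 || subject_sd < 0 || ref_noise_sd < 0 ||
      trait_noise_sd < 0)
    stop("standard deviations must be non-negative")
  n_mod <- length(module_sizes)
  if (is.null(group_module_shift)) {
    group_module_shift <- matrix(0, 4, n_mod,
                                 dimnames = list(groups, paste0("M", seq_len(n_mod))))
    if (n_mod >= 1) group_module_shift["endurance", 1] <- 2
    if (n_mod >= 2) group_module_shift["bodybuilding", 2] <- -2
    if (n_mod >= 3) group_module_shift["sprint", 3] <- 2
  }
  stopifnot(nrow(group_module_shift) == 4, ncol(group_module_shift) == n_mod)
  if (n_module_traits > n_mod) n_module_traits <- n_mod
  cfg <- list(n_per_group = n_per_group, n_metabolites = n_metabolites,
              module_sizes = module_sizes,
              within_module_cor = within_module_cor,
              group_module_shift = group_module_shift,
              n_response_shared = n_response_shared,
              response_shift_shared = response_shift_shared,
              n_response_group = n_response_group,
              response_shift_group = response_shift_group,
              response_group = response_group,
              batch_factor_sd = batch_factor_sd, subject_sd = subject_sd,
              missing_logit_intercept = missing_logit_intercept,
              missing_logit_slope = missing_logit_slope, mnar = mnar,
              n_forced_missing = n_forced_missing,
              forced_missing_frac = forced_missing_frac,
              n_high_cv = n_high_cv, ref_noise_sd = ref_noise_sd,
              high_cv_ref_sd = high_cv_ref_sd,
              outlier_rate = outlier_rate,
              outlier_log2_shift = outlier_log2_shift,
              n_traits = n_traits, n_module_traits = n_module_traits,
              trait_noise_sd = trait_noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Solve for the non-factor variance v that yields the target mean absolute
# within-module correlation under loadings |l| ~ U(0.5, 1):
#   E|cor| = (E[l / sqrt(l^2 + v)])^2 = rho
.noise_var_for_cor <- function(rho) {
  if (rho <= 0) return(Inf)
  g <- function(v) {
    e <- stats::integrate(function(l) l / sqrt(l^2 + v), 0.5, 1)$value / 0.5
    e^2 - rho
  }
  stats::uniroot(g, c(1e-8, 1e4), tol = 1e-10)$root
}

#' Simulate a complete cohort with ground truth
#'
#' Draws a full synthetic dataset from the latent-factor model of
#' [sim_config()]. On the log2 scale, metabolite `i` of module `m` in sample
#' `(subject j, timepoint t)` is
#' `baseline_i + loading_i * (f_mj + shift_{g(j),m}) + response_i(t, g(j)) +
#'  batch_effect + subject intercept + noise`;
#' background metabolites carry no latent factor. The matrix is exponentiated
#' to the ion-count scale before missingness and outliers are applied.
#' Reference aliquots are generated from the noise-free population mean plus
#' batch effect and technical noise, so batch-median normalization is
#' identifiable by construction.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` ([ion_matrix], ion-count scale),
#'   `samples` (sample metadata), `traits`, `annotation` and `truth`
#'   (ground-truth record: module membership, loadings, shifts, responses,
#'   trait drivers, planted QC failures and outlier coordinates).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- names(config$n_per_group)
  n_sub <- sum(config$n_per_group)
  subject_id <- sprintf("S%02d", seq_len(n_sub))
  subject_group <- rep(groups, config$n_per_group)
  subject_batch <- paste0("B", rep_len(1:2, n_sub))

  p <- config$n_metabolites
  met_id <- sprintf("met_%04d", seq_len(p))
  n_mod <- length(config$module_sizes)
  module <- integer(p)  # 0 = background
  idx <- 1L
  for (m in seq_len(n_mod)) {
    module[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }
  module <- sample(module)  # scatter module members over metabolite ids
  names(module) <- met_id

  # loadings and noise
  loading <- numeric(p)
  in_mod <- module > 0
  if (config$within_module_cor > 0) {
    l <- stats::runif(sum(in_mod), 0.5, 1)
    flip <- stats::runif(sum(in_mod)) < 0.2
    loading[in_mod] <- ifelse(flip, -l, l)
    v <- .noise_var_for_cor(config$within_module_cor)
  } else {
    v <- 1
  }
  sub_var <- min(config$subject_sd^2, 0.9 * v)
  noise_sd <- numeric(p)
  noise_sd[in_mod] <- sqrt(v - sub_var)
  noise_sd[!in_mod] <- sqrt(max(1 - sub_var, 1e-6))
  baseline <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)

  # latent factors per (module, subject), constant across timepoints
  f <- matrix(stats::rnorm(n_mod * n_sub), n_mod, n_sub)
  shift <- config$group_module_shift[subject_group, , drop = FALSE]  # n_sub x n_mod
  f_shifted <- f + t(shift)

  # exercise responses
  resp_shared <- numeric(p)
  resp_group <- numeric(p)
  resp_pool <- sample(p, config$n_response_shared + config$n_response_group)
  shared_idx <- resp_pool[seq_len(config$n_response_shared)]
  group_idx <- setdiff(resp_pool, shared_idx)
  resp_shared[shared_idx] <- config$response_shift_shared *
    sample(c(-1, 1), length(shared_idx), replace = TRUE)
  resp_group[group_idx] <- config$response_shift_group *
    sample(c(-1, 1), length(group_idx), replace = TRUE)

  batch_eff <- matrix(stats::rnorm(2 * p, 0, config$batch_factor_sd), 2, p,
                      dimnames = list(c("B1", "B2"), met_id))
  sub_int <- matrix(stats::rnorm(p * n_sub, 0, sqrt(sub_var)), p, n_sub)

  # experimental samples: subject x timepoint
  tp <- c("baseline", "post")
  samp_subject <- rep(subject_id, each = 2L)
  samp_tp <- rep(tp, n_sub)
  samp_id <- paste0(samp_subject, "_", ifelse(samp_tp == "baseline", "pre", "post"))
  samp_group <- rep(subject_group, each = 2L)
  samp_batch <- rep(subject_batch, each = 2L)

  n_samp <- length(samp_id)
  logx <- matrix(0, p, n_samp, dimnames = list(met_id, samp_id))
  for (s in seq_len(n_samp)) {
    j <- match(samp_subject[s], subject_id)
    cell <- baseline + sub_int[, j]
    if (n_mod > 0) {
      fac <- numeric(p)
      fac[in_mod] <- loading[in_mod] * f_shifted[module[in_mod], j]
      cell <- cell + fac
    }
    if (samp_tp[s] == "post") {
      cell <- cell + resp_shared
      if (samp_group[s] == config$response_group) cell <- cell + resp_group
    }
    cell <- cell + batch_eff[samp_batch[s], ]
    logx[, s] <- cell + stats::rnorm(p, 0, noise_sd)
  }

  # reference wells: population mean + batch effect + technical noise
  ref_sd <- rep(config$ref_noise_sd, p)
  high_cv <- sample(p, min(config$n_high_cv, p))
  ref_sd[high_cv] <- config$high_cv_ref_sd
  ref_meta <- list()
  ref_mat <- NULL
  for (b in c("B1", "B2")) {
    for (w in 1:4) {
      col <- baseline + batch_eff[b, ] + stats::rnorm(p, 0, ref_sd)
      ref_mat <- cbind(ref_mat, col)
      ref_meta[[length(ref_meta) + 1L]] <-
        data.frame(sample_id = paste0(b, "_serum_", w), subject_id = "",
                   role = "reference_serum", group = "", timepoint = "",
                   batch = b, stringsAsFactors = FALSE)
    }
    col <- baseline + batch_eff[b, ] + stats::rnorm(p, 0, ref_sd)
    ref_mat <- cbind(ref_mat, col)
    ref_meta[[length(ref_meta) + 1L]] <-
      data.frame(sample_id = paste0(b, "_plasma_1"), subject_id = "",
                 role = "reference_plasma", group = "", timepoint = "",
                 batch = b, stringsAsFactors = FALSE)
  }
  ref_meta <- do.call(rbind, ref_meta)
  colnames(ref_mat) <- ref_meta$sample_id

  counts <- ion_matrix(2^cbind(logx, ref_mat))
  meta <- rbind(
    data.frame(sample_id = samp_id, subject_id = samp_subject,
               role = "experimental", group = samp_group, timepoint = samp_tp,
               batch = samp_batch, stringsAsFactors = FALSE),
    ref_meta)
  validate_samples(meta)

  # traits: first n_module_traits are driven by module baseline factors
  traits <- data.frame(subject_id = subject_id)
  trait_module <- integer(0)
  for (t_i in seq_len(config$n_traits)) {
    nm <- c("vo2max", "bmi", "grip_strength", "reactive_strength",
            "endurance_training")[t_i]
    if (is.na(nm)) nm <- sprintf("trait_%02d", t_i)
    if (t_i <= config$n_module_traits) {
      traits[[nm]] <- f[t_i, ] + stats::rnorm(n_sub, 0, config$trait_noise_sd)
      trait_module[nm] <- t_i
    } else {
      traits[[nm]] <- stats::rnorm(n_sub)
    }
  }

  sups <- c("Lipid", "Amino Acid", "Xenobiotics", "Peptide", "Nucleotide",
            "Cofactors and Vitamins", "Carbohydrate", "Energy")
  annotation <- data.frame(
    metabolite_id = met_id,
    name = paste0("synthetic_compound_", seq_len(p)),
    superpathway = sample(c(sups, "unknown"), p, replace = TRUE,
                          prob = c(rep(1, 8), 0.8)),
    subpathway = paste0("subpathway_", sample(40, p, replace = TRUE)),
    hmdb_id = "", pubchem_id = "", stringsAsFactors = FALSE)

  truth <- list(module = module, loading = stats::setNames(loading, met_id),
                group_module_shift = config$group_module_shift,
                response_shared = stats::setNames(resp_shared, met_id),
                response_group = stats::setNames(resp_group, met_id),
                response_group_name = config$response_group,
                trait_module = trait_module,
                trait_noise_sd = config$trait_noise_sd,
                high_cv = met_id[high_cv],
                forced_missing = character(0),
                outliers = data.frame(metabolite_id = character(0),
                                      sample_id = character(0),
                                      stringsAsFactors = FALSE))

  out <- apply_missingness_and_outliers(counts, meta, config, truth)
  list(matrix = out$matrix, samples = meta, traits = traits,
       annotation = annotation, truth = out$truth)
}

#' Apply abundance-dependent missingness and sporadic outliers
#'
#' Post-processing stage of the generator, exposed separately so its rules can
#' be tested in isolation. Each experimental cell is set missing with a
#' probability that is logistic in its rank abundance (lower abundance, more
#' missing); a configurable number of metabolites is forced to a fixed
#' missingness fraction above the downstream 30% filter; and a configurable
#' fraction of the remaining cells is multiplied by a large factor to emulate
#' sporadic extreme values. All injected coordinates are recorded in the
#' returned truth.
#'
#' @param x ion-count scale [ion_matrix].
#' @param meta sample metadata (only experimental cells are perturbed).
#' @param config a [sim_config()].
#' @param truth ground-truth list to update (may be empty).
#' @return list with updated `matrix` and `truth`.
#' @export
apply_missingness_and_outliers <- function(x, meta, config, truth = list()) {
  vals <- .values(x)
  exp_cols <- .exp_cols(x, meta)
  ev <- vals[, exp_cols, drop = FALSE]
  n_cells <- length(ev)

  # logistic MNAR on the rank-abundance scale
  if (is.finite(config$missing_logit_intercept)) {
    rank_frac <- rank(ev, ties.method = "average") / n_cells
    lin <- if (isTRUE(config$mnar))
      config$missing_logit_intercept + config$missing_logit_slope * (1 - rank_frac)
    else
      config$missing_logit_intercept + config$missing_logit_slope * 0.5
    pm <- stats::plogis(lin)
    drop <- stats::runif(n_cells) < pm
    ev[drop] <- NA_real_
  }

  # forced high-missingness metabolites (always above the 30% threshold)
  forced <- character(0)
  if (config$n_forced_missing > 0) {
    forced_i <- sample(nrow(ev), min(config$n_forced_missing, nrow(ev)))
    n_force <- max(ceiling(config$forced_missing_frac * ncol(ev)),
                   floor(0.30 * ncol(ev)) + 1L)
    for (i in forced_i)
      ev[i, sample(ncol(ev), n_force)] <- NA_real_
    forced <- rownames(ev)[forced_i]
  }

  # sporadic outliers among the remaining present cells
  out_rec <- data.frame(metabolite_id = character(0), sample_id = character(0),
                        stringsAsFactors = FALSE)
  if (config$outlier_rate > 0) {
    present <- which(!is.na(ev))
    n_out <- round(config$outlier_rate * length(present))
    if (n_out > 0) {
      pick <- sample(present, n_out)
      sign <- sample(c(-1, 1), n_out, replace = TRUE)
      ev[pick] <- ev[pick] * 2^(sign * config$outlier_log2_shift)
      ai <- arrayInd(pick, dim(ev))
      out_rec <- data.frame(metabolite_id = rownames(ev)[ai[, 1L]],
                            sample_id = colnames(ev)[ai[, 2L]],
                            stringsAsFactors = FALSE)
    }
  }

  vals[, exp_cols] <- ev
  truth$forced_missing <- forced
  truth$outliers <- out_rec
  list(matrix = ion_matrix(vals), truth = truth)
}

#' Write a simulated cohort to a directory
#'
#' Emits `matrix.tsv`, `samples.tsv`, `traits.tsv`, `annotation.tsv` and
#' `truth.json` (the serializable parts of the ground truth).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$matrix, file.path(dir, "matrix.tsv"))
  write_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_table(cohort$traits, file.path(dir, "traits.tsv"))
  write_table(cohort$annotation, file.path(dir, "annotation.tsv"))
  tr <- cohort$truth
  tr$module <- as.list(tr$module)
  tr$group_module_shift <- as.data.frame(tr$group_module_shift)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
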