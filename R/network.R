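#' Network construction parameters
#'
#' @param power soft-thresholding power beta (> 0, default 6).
#' @param type network type; only `"unsigned"` (adjacency `|cor|^beta`) is
#'   implemented.
#' @param min_module_size smallest admissible module (default 30).
#' @param merge_height modules whose eigenmetabolites correlate above
#'   `1 - merge_height` are merged (default 0.25).
#' @param deep_split branch-cut sensitivity, integer 0-4 (default 2); higher
#'   values cut lower in the tree and produce more, smaller candidate
#'   branches.
#' @param pam_stage if `TRUE`, assign unlabelled (grey) metabolites to the
#'   nearest module when they are closer to it than to the grey pool
#'   (off by default).
#' @param cor_method correlation estimator (default `"pearson"`).
#' @return list of class `network_params`.
#' @export
network_params <- function(power = 6, type = "unsigned", min_module_size = 30,
                           merge_height = 0.25, deep_split = 2,
                           pam_stage = FALSE, cor_method = "pearson") {
  stopifnot(power > 0, min_module_size >= 2,
            deep_split %in% 0:4, merge_height >= 0, merge_height <= 1)
  type <- match.arg(type, "unsigned")
  structure(list(power = power, type = type,
                 min_module_size = as.integer(min_module_size),
                 merge_height = merge_height,
                 deep_split = as.integer(deep_split),
                 pam_stage = isTRUE(pam_stage), cor_method = cor_method),
            class = "network_params")
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` with Pearson correlation across samples;
#' the soft threshold beta emphasizes strong correlations while keeping the
#' network weighted. The diagonal is 1.
#'
#' @param x log-scale metabolite-by-sample matrix (fully imputed, >= 3
#'   samples) or [ion_matrix].
#' @param params a [network_params()].
#' @return symmetric metabolite-by-metabolite matrix with values in `[0, 1]`.
#' @export
adjacency <- function(x, params = network_params()) {
  vals <- if (inherits(x, "ion_matrix")) .values(x) else as.matrix(x)
  if (ncol(vals) < 3L) stop("adjacency needs at least 3 samples")
  v <- apply(vals, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance metabolite: ", rownames(vals)[which(v == 0)[1L]])
  a <- abs(stats::cor(t(vals), method = params$cor_method))^params$power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j` and connectivity `k_i = sum_{u != i} a_iu`; the
#' diagonal is set to 1. Two metabolites are topologically similar when they
#' share the same network neighbours, which makes `1 - TOM` a noise-robust
#' clustering dissimilarity.
#'
#' @param adj adjacency matrix from [adjacency()] (diagonal 1).
#' @return symmetric TOM matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adj) {
  k <- colSums(adj) - 1          # diagonal excluded from connectivity
  aa <- adj %*% adj              # includes u = i and u = j, each adding a_ij
  num <- aa - adj                # = sum_{u != i,j} a_iu a_uj + a_ij
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - adj)
  diag(tom) <- 1
  tom
}

# conventional size-ordered module color sequence
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue")

# relabel integer cluster codes (0 = unassigned) as size-ordered colors
.label_by_size <- function(codes) {
  out <- rep("grey", length(codes))
  names(out) <- names(codes)
  nz <- codes != 0
  if (any(nz)) {
    tab <- sort(table(codes[nz]), decreasing = TRUE)
    cols <- c(.module_colors,
              paste0("module_", seq_len(max(0, length(tab) - length(.module_colors)))))
    for (r in seq_along(tab))
      out[codes == as.integer(names(tab)[r])] <- cols[r]
  }
  out
}

#' Cluster the TOM dissimilarity and cut branches into modules
#'
#' Builds an average-linkage hierarchical tree on the dissimilarity and
#' detects modules by a dynamic branch cut with two rules. (1) Merges above
#' a data-adaptive cut height `h_min + frac * (h_max - h_min)` never join a
#' module; `frac` is controlled by `deep_split` (0.90, 0.95, 0.98, 0.99,
#' 0.995 for deep_split 0-4). (2) Below the cut height, a branch is split at
#' its top merge whenever both sub-branches hold at least `min_module_size`
#' members and the merge sits a clear gap (15% of the tree's height range)
#' above both sub-branch tops -- the tree-shape signature of two coherent
#' clusters joined late, which an absolute cut alone misses when modules are
#' tight. Branches smaller than `min_module_size` are dissolved and their
#' members labelled `"grey"`. An optional PAM-like stage reassigns grey
#' metabolites to the nearest module when they are closer to it (mean
#' dissimilarity) than to the grey pool. Labels are size-ordered colors,
#' largest module first (`"turquoise"`, `"blue"`, ...).
#'
#' @param dissim square dissimilarity matrix in `[0, 1]` (typically
#'   `1 - tom_similarity(...)`).
#' @param params a [network_params()].
#' @param timepoint optional tag stored on the assignment.
#' @return a `module_assignment`: named character vector metabolite -> label.
#' @export
cluster_and_cut <- function(dissim, params = network_params(),
                            timepoint = NULL) {
  ids <- rownames(dissim)
  if (nrow(dissim) < params$min_module_size) {
    warning("fewer metabolites than min_module_size; all assigned grey")
    return(module_assignment(stats::setNames(rep("grey", nrow(dissim)), ids),
                             timepoint = timepoint))
  }
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  frac <- c(0.90, 0.95, 0.98, 0.99, 0.995)[params$deep_split + 1L]
  codes <- .cut_tree(hc, params$min_module_size, frac)
  names(codes) <- ids
  labels <- .label_by_size(codes)
  if (params$pam_stage)
    labels <- .pam_assign(labels, dissim)
  module_assignment(stats::setNames(labels, ids), timepoint = timepoint)
}

# Dynamic branch cut on an hclust merge tree, built bottom-up in merge order.
# Each growing branch records its internal merge heights; when a merge joins
# two branches that each hold at least min_size members and the join height
# clears both branches' internal cohesion (their 75th-percentile merge
# height) by more than gap_frac * (height range), the join is cut and both
# sides become locked modules. Judging cohesion by an internal quantile --
# not the branch's literal top -- keeps chained absorption of stray
# metabolites from erasing the gap between two genuinely distinct modules.
# Merges above the cut height never extend a branch; whatever joins there
# (or joins a locked module) is left unassigned. Surviving branches of at
# least min_size become modules; all other objects get code 0 (grey).
.cut_tree <- function(hc, min_size, cut_frac, gap_frac = 0.15) {
  m <- hc$merge
  h <- hc$height
  n <- nrow(m) + 1L
  cut_h <- min(h) + cut_frac * (max(h) - min(h))
  gap_tol <- gap_frac * (max(h) - min(h))
  members <- vector("list", n - 1L)
  heights <- vector("list", n - 1L)
  status <- character(n - 1L)          # "active", "dead" (consumed/locked)
  codes <- integer(n)
  next_code <- 0L
  lock <- function(mem) {
    if (length(mem) >= min_size) {
      next_code <<- next_code + 1L
      codes[mem] <<- next_code
    }
  }
  kid_mem <- function(j) if (j < 0) -j else members[[j]]
  kid_hts <- function(j) if (j < 0) numeric(0) else heights[[j]]
  kid_ok <- function(j) j < 0 || status[j] == "active"
  cohesion <- function(ht) if (length(ht)) stats::quantile(ht, 0.75,
                                                           names = FALSE) else 0
  for (k in seq_len(n - 1L)) {
    a <- m[k, 1L]; b <- m[k, 2L]
    if (h[k] > cut_h || !kid_ok(a) || !kid_ok(b)) {
      # branch growth ends here: each viable side stands on its own
      for (j in c(a, b)) if (kid_ok(j)) {
        lock(kid_mem(j))
        if (j > 0) status[j] <- "dead"
      }
      status[k] <- "dead"
      next
    }
    ma <- kid_mem(a); mb <- kid_mem(b)
    if (length(ma) >= min_size && length(mb) >= min_size &&
        h[k] - max(cohesion(kid_hts(a)), cohesion(kid_hts(b))) > gap_tol) {
      lock(ma); lock(mb)                # two coherent modules joined late
      if (a > 0) status[a] <- "dead"
      if (b > 0) status[b] <- "dead"
      status[k] <- "dead"
    } else {
      members[[k]] <- c(ma, mb)
      heights[[k]] <- c(kid_hts(a), kid_hts(b), h[k])
      if (a > 0) status[a] <- "dead"    # consumed into the union
      if (b > 0) status[b] <- "dead"
      status[k] <- "active"
    }
  }
  for (k in seq_len(n - 1L))            # maximal surviving branches
    if (status[k] == "active") lock(members[[k]])
  codes
}

# PAM-like stage: grey objects join the module they are closest to (mean
# dissimilarity) when that is closer than the grey pool itself
.pam_assign <- function(labels, dissim) {
  mods <- setdiff(unique(labels), "grey")
  grey <- names(labels)[labels == "grey"]
  if (!length(mods) || length(grey) < 2L) return(labels)
  for (g in grey) {
    d_mod <- vapply(mods, function(m)
      mean(dissim[g, names(labels)[labels == m]]), numeric(1))
    d_grey <- mean(dissim[g, setdiff(grey, g)])
    if (min(d_mod) < d_grey)
      labels[g] <- mods[which.min(d_mod)]
  }
  labels
}

#' Module assignment
#'
#' A named character vector mapping metabolite ids to size-ordered color
#' labels, with `"grey"` for unassigned metabolites.
#'
#' @param labels named character vector.
#' @param timepoint optional tag (`"baseline"`, `"post"`, `"consensus"`).
#' @return object of class `module_assignment`.
#' @export
module_assignment <- function(labels, timepoint = NULL) {
  stopifnot(is.character(labels), !is.null(names(labels)))
  structure(labels, timepoint = timepoint, class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tp <- attr(x, "timepoint")
  cat("module assignment", if (!is.null(tp)) paste0("(", tp, ")"), "\n")
  tab <- sort(table(unclass(x)), decreasing = TRUE)
  grey <- tab[names(tab) == "grey"]
  tab <- tab[names(tab) != "grey"]
  for (m in names(tab)) cat(sprintf("  %-12s %d\n", m, tab[[m]]))
  if (length(grey)) cat(sprintf("  %-12s %d (unassigned)\n", "grey", grey[[1]]))
  invisible(x)
}

#' @export
`[.module_assignment` <- function(x, i, ...) {
  module_assignment(unclass(x)[i], timepoint = attr(x, "timepoint"))
}

#' Merge modules with highly correlated eigenmetabolites
#'
#' Iteratively merges the pair of modules whose eigenmetabolites are most
#' correlated, as long as that correlation is at least `1 - merge_height`;
#' after convergence labels are reassigned by descending size. Grey is never
#' merged.
#'
#' @param assignment a `module_assignment`.
#' @param x log-scale matrix used to compute eigenmetabolites.
#' @param merge_height height below which modules merge (default 0.25, i.e.
#'   eigenmetabolite correlation >= 0.75).
#' @return updated `module_assignment`.
#' @export
merge_close_modules <- function(assignment, x, merge_height = 0.25) {
  labels <- unclass(assignment)
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    eig <- sapply(mods, function(m)
      eigenmetabolite(x, names(labels)[labels == m])$scores)
    cc <- stats::cor(eig)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (max(cc) < 1 - merge_height) break
    labels[labels == mods[best[2L]]] <- mods[best[1L]]
  }
  # relabel by size, preserving grey
  codes <- match(labels, setdiff(unique(labels), "grey"))
  codes[is.na(codes)] <- 0L
  names(codes) <- names(labels)
  module_assignment(stats::setNames(.label_by_size(codes), names(labels)),
                    timepoint = attr(assignment, "timepoint"))
}

#' Eigenmetabolite of a module
#'
#' The first principal component of the module's metabolite-standardized
#' sub-matrix: each member is z-scored across samples, the PC1 per-sample
#' scores summarize the module per subject. Scores have mean zero and are
#' sign-oriented to correlate positively with the module's mean z-score.
#'
#' @param x log-scale matrix or [ion_matrix] (columns = samples/subjects).
#' @param members character vector of member metabolite ids.
#' @return list of class `eigenmetabolite` with `scores` (named per-sample),
#'   `var_explained` and `members`.
#' @export
eigenmetabolite <- function(x, members) {
  vals <- if (inherits(x, "ion_matrix")) .values(x) else as.matrix(x)
  if (ncol(vals) < 2L) stop("eigenmetabolite needs at least 2 samples")
  if (!length(members)) stop("empty module")
  z <- t(scale(t(vals[members, , drop = FALSE])))
  if (anyNA(z)) stop("zero-variance or missing metabolite in module")
  sv <- svd(z)
  scores <- sv$v[, 1L]
  names(scores) <- colnames(vals)
  msign <- stats::cor(scores, colMeans(z))
  if (!is.na(msign) && msign < 0) scores <- -scores
  structure(list(scores = scores,
                 var_explained = sv$d[1L]^2 / sum(sv$d^2),
                 members = members),
            class = "eigenmetabolite")
}

#' Detect modules in one timepoint
#'
#' Convenience wrapper chaining [adjacency()], [tom_similarity()],
#' [cluster_and_cut()] and [merge_close_modules()], and computing each
#' metabolite's module membership (kME, correlation with its own module's
#' eigenmetabolite).
#'
#' @param x log-scale, fully imputed metabolite-by-sample matrix or
#'   [ion_matrix].
#' @param params a [network_params()].
#' @param timepoint optional tag.
#' @return list of class `module_set`: `assignment`, `kME` (named numeric)
#'   and `params`.
#' @export
detect_modules <- function(x, params = network_params(), timepoint = NULL) {
  adj <- adjacency(x, params)
  tom <- tom_similarity(adj)
  assignment <- cluster_and_cut(1 - tom, params, timepoint = timepoint)
  assignment <- merge_close_modules(assignment, x, params$merge_height)
  vals <- if (inherits(x, "ion_matrix")) .values(x) else as.matrix(x)
  kme <- rep(NA_real_, nrow(vals))
  names(kme) <- rownames(vals)
  for (m in setdiff(unique(unclass(assignment)), "grey")) {
    members <- names(assignment)[unclass(assignment) == m]
    eig <- eigenmetabolite(vals, members)
    kme[members] <- as.numeric(stats::cor(t(vals[members, , drop = FALSE]),
                                          eig$scores))
  }
  structure(list(assignment = assignment, kME = kme, params = params),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  print(x$assignment)
  invisible(x)
}

#' Scale-free topology fit across candidate soft powers
#'
#' Diagnostic only: for each power, the R-squared of the regression of
#' `log10 p(k)` on `log10 k` over binned connectivities, the usual check that
#' the soft threshold induces an approximately scale-free degree
#' distribution.
#'
#' @param x log-scale matrix.
#' @param powers candidate powers.
#' @param n_bins histogram bins for the degree distribution.
#' @return data.frame with columns `power`, `rsq`, `mean_k`.
#' @export
soft_power_scan <- function(x, powers = c(1:10, 12, 14, 16, 18, 20),
                            n_bins = 10) {
  out <- lapply(powers, function(b) {
    a <- adjacency(x, network_params(power = b))
    k <- colSums(a) - 1
    br <- seq(min(k), max(k), length.out = n_bins + 1L)
    cut_k <- cut(k, br, include.lowest = TRUE)
    pk <- tabulate(cut_k, n_bins) / length(k)
    mk <- tapply(k, cut_k, mean)
    keep <- pk > 0 & !is.na(mk) & mk > 0
    rsq <- if (sum(keep) > 2)
      summary(stats::lm(log10(pk[keep]) ~ log10(mk[keep])))$r.squared
    else NA_real_
    data.frame(power = b, rsq = rsq, mean_k = mean(k))
  })
  do.call(rbind, out)
}
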