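#' Subgroup label string
#'
#' Canonical `"HIST_T_N_M"` label for a histology x TNM subgroup, used for
#' distance-matrix dimnames, dendrogram leaves and artifact files.
#'
#' @inheritParams validate_tnm
#' @return Character vector of labels.
#' @export
subgroup_label <- function(histology, t, n, m) {
  paste(histology, t, n, m, sep = "_")
}

.check_full_cohort <- function(records) {
  .check_cohort_times(records)
  need <- c("histology", "t", "n", "m")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  validate_tnm(records$histology, records$t, records$n, records$m)
  invisible(TRUE)
}

#' Build one Kaplan-Meier curve per histology x TNM subgroup
#'
#' Coarsens every record to clustering granularity (T1-T4, M0/M1), splits
#' the cohort by subgroup, estimates a KM curve for each, and places all
#' curves on one common monthly grid spanning the longest follow-up.
#' Subgroups with fewer than `min_group_size` patients are excluded from
#' the set and reported, since their curves are too unstable to cluster.
#'
#' @param records Cohort data.frame (`histology`, `t`, `n`, `m`,
#'   `time_months`, `event`).
#' @param min_group_size Minimum patients per subgroup (default 30).
#' @param grid_step Grid spacing in months.
#' @return A `subgroup_curve_set`: named list of curves, per-subgroup sizes,
#'   the common grid, a `keys` data.frame, and an `excluded` data.frame of
#'   under-sized subgroups.
#' @export
build_curve_set <- function(records, min_group_size = 30, grid_step = 1) {
  .check_full_cohort(records)
  ck <- coarsen_tnm(records$histology, records$t, records$n, records$m)
  lab <- subgroup_label(ck$histology, ck$t, ck$n, ck$m)
  sizes <- table(lab)
  keep <- names(sizes)[sizes >= min_group_size]
  excl <- data.frame(label = names(sizes)[sizes < min_group_size],
                     n = as.integer(sizes[sizes < min_group_size]),
                     stringsAsFactors = FALSE)
  if (length(keep) == 0)
    stop("all subgroups fall below min_group_size = ", min_group_size,
         call. = FALSE)
  k <- max(1L, ceiling(max(records$time_months) / grid_step))
  grid <- seq_len(k) * grid_step
  keep <- sort(keep)
  curves <- lapply(keep, function(lb) {
    regrid(km_estimate(records[lab == lb, , drop = FALSE], grid_step), grid)
  })
  names(curves) <- keep
  parts <- do.call(rbind, strsplit(keep, "_", fixed = TRUE))
  keys <- data.frame(histology = parts[, 1], t = parts[, 2], n = parts[, 3],
                     m = parts[, 4], label = keep,
                     n_patients = as.integer(sizes[keep]),
                     stringsAsFactors = FALSE)
  structure(list(curves = curves,
                 n_patients = stats::setNames(keys$n_patients, keep),
                 keys = keys, grid = grid, excluded = excl,
                 grid_step = grid_step),
            class = "subgroup_curve_set")
}

#' @export
print.subgroup_curve_set <- function(x, ...) {
  cat("Subgroup curve set:", length(x$curves), "subgroups on a",
      length(x$grid), "month grid;", nrow(x$excluded),
      "subgroup(s) excluded as undersized\n")
  invisible(x)
}

#' Pairwise log-rank chi-squared distance matrix
#'
#' Square symmetric matrix of per-capita curve-level log-rank statistics
#' ([curve_chi2_distance()] with `n_per_group = "infinite"`) between every
#' pair of subgroup curves. The per-capita statistic drops the common
#' group-size factor, which cannot change the clustering.
#'
#' @param set A `subgroup_curve_set` with at least two entries.
#' @return Symmetric numeric matrix with subgroup labels as dimnames and a
#'   zero diagonal.
#' @export
build_distance_matrix <- function(set) {
  stopifnot(inherits(set, "subgroup_curve_set"))
  k <- length(set$curves)
  if (k < 2)
    stop("need at least 2 subgroups to build a distance matrix",
         call. = FALSE)
  d <- matrix(0, k, k, dimnames = list(names(set$curves),
                                       names(set$curves)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <-
        curve_chi2_distance(set$curves[[i]], set$curves[[j]])$chi2
    }
  }
  d
}

#' Agglomerative clustering of the subgroup distance matrix
#'
#' Standard hierarchical agglomeration (via [stats::hclust()]) on the
#' precomputed curve-distance matrix. Average linkage is the default
#' reading of "hierarchical clustering of survival curves"; complete and
#' single linkage are exposed for sensitivity checks.
#'
#' @param m Distance matrix from [build_distance_matrix()].
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An `hclust` tree over the subgroup labels.
#' @export
agglomerate <- function(m, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            isTRUE(all.equal(m, t(m))), all(diag(m) == 0), all(m >= 0))
  stats::hclust(stats::as.dist(m), method = linkage)
}

# Patient-weighted pooled curve over a set of member subgroups.
.pooled_curve <- function(set, labels) {
  w <- set$n_patients[labels]
  s <- Reduce(`+`, Map(function(lb, wi) wi * set$curves[[lb]]$surv,
                       labels, w)) / sum(w)
  .new_survival_curve(set$grid, s, n0 = sum(w))
}

.median_survival <- function(curve) {
  i <- which(curve$surv <= 0.5)
  if (length(i) == 0) Inf else curve$time[min(i)]
}

#' Cut the cluster tree and label clusters as modified sub-stages
#'
#' Cuts the dendrogram into `k_substage` clusters, computes each cluster's
#' pooled (patient-weighted) 5-year CSS, orders clusters by decreasing
#' survival, assigns sub-stage labels IA, IB, ... IV in that order, and
#' groups consecutive sub-stages into stages I-IV by `stage_pattern`
#' (default 2+2+3+1 = 8, the shape of the 8-group lung staging ladder).
#' Ties in pooled CSS are broken by longer pooled median survival, then by
#' the larger cluster first.
#'
#' @param tree `hclust` tree from [agglomerate()].
#' @param set The `subgroup_curve_set` the tree was built from.
#' @param k_substage Number of sub-stage clusters (default 8).
#' @param stage_pattern Integer counts of sub-stages per stage; must sum to
#'   `k_substage`.
#' @param horizon Months at which pooled CSS orders the clusters
#'   (default 60).
#' @return A `regrouping`: per-subgroup assignment data.frame (`histology`,
#'   `t`, `n`, `m`, `label`, `cluster`, `substage`, `stage`), per-sub-stage
#'   pooled CSS, `k`, and the tree.
#' @export
cut_and_label <- function(tree, set, k_substage = 8,
                          stage_pattern = c(2, 2, 3, 1), horizon = 60) {
  stopifnot(inherits(tree, "hclust"), inherits(set, "subgroup_curve_set"))
  if (sum(stage_pattern) != k_substage)
    stop("stage_pattern must sum to k_substage", call. = FALSE)
  if (k_substage > length(tree$labels))
    stop("k_substage exceeds the number of clustered subgroups",
         call. = FALSE)
  cl <- stats::cutree(tree, k = k_substage)
  stats <- lapply(seq_len(k_substage), function(ci) {
    labs <- names(cl)[cl == ci]
    pc <- .pooled_curve(set, labs)
    list(css = css_at(pc, min(horizon, max(set$grid))),
         med = .median_survival(pc), size = sum(set$n_patients[labs]))
  })
  css <- vapply(stats, `[[`, numeric(1), "css")
  med <- vapply(stats, `[[`, numeric(1), "med")
  size <- vapply(stats, `[[`, numeric(1), "size")
  ord <- order(-css, -med, -size)
  substage_levels <- .substages[seq_len(k_substage)]
  stage_levels <- rep(.stages[seq_along(stage_pattern)], stage_pattern)
  rank_of_cluster <- match(seq_len(k_substage), ord)
  keys <- set$keys
  keys$cluster <- unname(cl[keys$label])
  keys$substage <- substage_levels[rank_of_cluster[keys$cluster]]
  keys$stage <- stage_levels[rank_of_cluster[keys$cluster]]
  structure(list(k = k_substage,
                 assignment = keys,
                 substage_css = stats::setNames(css[ord], substage_levels),
                 stage_pattern = stage_pattern,
                 horizon = horizon,
                 tree = tree),
            class = "regrouping")
}

#' @export
print.regrouping <- function(x, ...) {
  cat("Regrouping of", nrow(x$assignment), "subgroups into", x$k,
      "sub-stages\n")
  cat("  pooled", x$horizon, "month CSS by sub-stage:\n")
  print(round(x$substage_css, 3))
  invisible(x)
}

#' Derive a stage map from a regrouping
#'
#' Turns the clustering result into a coarse-granularity stage map
#' (`system = "derived_modified"`) with entry source `"derived"`. With
#' `complete = TRUE` (default) every coarse TNM cell not covered by the
#' clustering — typically subgroups excluded as undersized — is filled with
#' its coarsened 8th-edition assignment and flagged `source = "default"`,
#' never silently.
#'
#' @param r A `regrouping`.
#' @param complete Fill uncovered coarse cells from the 8th edition.
#' @return A coarse `stage_map`.
#' @export
derive_stage_map <- function(r, complete = TRUE) {
  stopifnot(inherits(r, "regrouping"))
  e <- r$assignment[c("histology", "t", "n", "m", "substage")]
  e$source <- "derived"
  if (complete) {
    grid <- .coarse_grid()
    have <- paste(e$histology, e$t, e$n, e$m)
    miss <- grid[!(paste(grid$histology, grid$t, grid$n, grid$m) %in% have), ,
                 drop = FALSE]
    if (nrow(miss)) {
      c8 <- coarsen_stage_map(stage_map_8th())
      lk <- stage_lookup(c8, miss$histology, miss$t, miss$n, miss$m)
      miss$substage <- lk$substage
      miss$source <- "default"
      e <- rbind(e, miss[names(e)])
    }
  }
  .new_stage_map("derived_modified", "coarse", e)
}

#' Export the cluster tree as Newick text
#'
#' Serializes the dendrogram with merge heights as branch lengths and
#' `HIST_T_N_M` leaf names, via [ape::as.phylo()].
#'
#' @param tree An `hclust` tree.
#' @return A single Newick string.
#' @export
export_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}
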