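#' Count supra-threshold aberrations in a smoothed profile
#'
#' A copy-number aberration, for burden purposes, is one local summit of
#' the smoothed curve: a local maximum (plateaus collapse to one summit)
#' exceeding `+t` counts as a gain, a local minimum below `-t` as a loss.
#' The same magnitude is applied to both tails, and summits never span
#' chromosomes. Counting summits rather than threshold crossings makes the
#' count exactly non-increasing in the cutoff: raising `t` can only retire
#' summits, whereas a noise dip can split one supra-threshold run into two.
#'
#' @param curve a `kse_curve` (signed, per tumor), or a numeric vector with
#'   `chrom` supplied.
#' @param t positive cutoff in KSE (log2-ratio) units.
#' @param chrom chromosome label per value when `curve` is a bare vector.
#' @return integer count of gains plus losses.
#' @export
count_cna_segments <- function(curve, t, chrom = NULL) {
  stopifnot(t > 0)
  if (inherits(curve, "kse_curve")) {
    v <- curve$values
    chrom <- curve$grid$chrom
  } else {
    v <- curve
    if (is.null(chrom)) chrom <- rep("chr", length(v))
  }
  n <- 0L
  for (ch in .chrom_levels(chrom)) {
    vi <- v[chrom == ch]
    n <- n + sum(vi[.local_maxima(vi)] > t) +
      sum(vi[.local_maxima(-vi)] < -t)
  }
  n
}

#' CNA-burden sweep over a grid of KSE cutoffs
#'
#' Each tumor's profile is smoothed once; for every cutoff the number of
#' supra-threshold aberrations is counted per tumor. Group medians and
#' means are reported per cutoff, and a two-sided Welch t-test compares
#' the mean counts of two named groups at each cutoff (medians are the
#' headline summary, means are what the t-test examines). Counts are, per
#' tumor, non-increasing in the cutoff.
#'
#' @param cohort an `acgh_cohort` (normalized).
#' @param test_groups character(2): the groups compared by the t-test;
#'   defaults to the first two groups of the sample sheet.
#' @param spec a [kernel_spec()].
#' @param grid_step_bp smoothing grid step.
#' @param cutoffs ascending positive cutoffs (default 0.02 to 1.00 in
#'   steps of 0.02).
#' @return a `burden_table`: list with `cutoffs`, `counts`
#'   (sample x cutoff), `samples`, `medians`, `means` (group x cutoff),
#'   `p_value` per cutoff, `test_groups`.
#' @export
burden_table <- function(cohort, test_groups = NULL, spec = kernel_spec(),
                         grid_step_bp = 1e5,
                         cutoffs = seq(0.02, 1, by = 0.02)) {
  stopifnot(inherits(cohort, "acgh_cohort"), all(cutoffs > 0),
            !is.unsorted(cutoffs))
  groups <- unique(cohort$samples$group)
  if (is.null(test_groups)) test_groups <- utils::head(groups, 2)
  kse <- kse_matrix(cohort, spec, grid_step_bp)
  chrom <- kse$grid$chrom
  counts <- matrix(0L, ncol(kse$values), length(cutoffs),
                   dimnames = list(cohort$samples$sample_id,
                                   sprintf("%.2f", cutoffs)))
  for (j in seq_len(ncol(kse$values))) {
    v <- kse$values[, j]
    for (k in seq_along(cutoffs))
      counts[j, k] <- count_cna_segments(v, cutoffs[k], chrom)
  }
  agg <- function(fun) {
    out <- matrix(NA_real_, length(groups), length(cutoffs),
                  dimnames = list(groups, colnames(counts)))
    for (g in groups)
      out[g, ] <- apply(counts[cohort$samples$group == g, , drop = FALSE],
                        2, fun)
    out
  }
  p_value <- rep(NA_real_, length(cutoffs))
  ia <- cohort$samples$group == test_groups[1]
  ib <- cohort$samples$group == test_groups[2]
  if (sum(ia) < 2 || sum(ib) < 2) {
    warning("a test group has < 2 samples; p-values omitted")
  } else {
    for (k in seq_along(cutoffs))
      p_value[k] <- tryCatch(
        stats::t.test(counts[ia, k], counts[ib, k])$p.value,
        error = function(e) NA_real_) # constant data at extreme cutoffs
  }
  structure(list(cutoffs = cutoffs, counts = counts,
                 samples = cohort$samples, medians = agg(stats::median),
                 means = agg(mean), p_value = p_value,
                 test_groups = test_groups),
            class = "burden_table")
}

#' Mean smoothed signal per tumor within a set of genomic regions
#'
#' Entry `(sample, region)` is the mean of the sample's KSE values at grid
#' positions inside `[start_mb, end_mb)` on the region's chromosome; `NA`
#' if the region covers no grid point.
#'
#' @param kse a `kse_set` of per-tumor signed curves.
#' @param regions a `region_table`.
#' @return numeric matrix, samples x regions.
#' @export
region_mean_matrix <- function(kse, regions) {
  stopifnot(inherits(kse, "kse_set"), inherits(regions, "region_table"))
  chroms <- .chrom_levels(kse$grid$chrom)
  unknown <- setdiff(unique(regions$chrom), chroms)
  if (length(unknown))
    .stopf("region(s) on unknown chromosome: %s",
           paste(unknown, collapse = ", "))
  labels <- make.unique(paste0(regions$chrom_region, "_", regions$direction))
  out <- matrix(NA_real_, ncol(kse$values), nrow(regions),
                dimnames = list(colnames(kse$values), labels))
  for (i in seq_len(nrow(regions))) {
    idx <- which(kse$grid$chrom == regions$chrom[i] &
                   kse$grid$pos >= regions$start_mb[i] * 1e6 &
                   kse$grid$pos < regions$end_mb[i] * 1e6)
    if (length(idx))
      out[, i] <- colMeans(kse$values[idx, , drop = FALSE])
  }
  out
}

#' Hierarchically cluster tumors on region-mean profiles
#'
#' Distance is `1 - Pearson r` between sample feature vectors; linkage is
#' complete; leaves are ordered by reordering the dendrogram on mean
#' feature values; the tree is cut into `n_branches` branches and, when
#' group labels are supplied, a branch-composition table is reported.
#' Regions are clustered the same way on the transposed matrix
#' (two-dimensional clustering).
#'
#' @param mat samples x regions feature matrix (e.g. from
#'   [region_mean_matrix()]); no missing entries.
#' @param n_branches number of branches to cut (default 2).
#' @param groups optional per-sample group labels for the composition
#'   table.
#' @return a `cluster_result`: list with `hclust`, `dendrogram`,
#'   `branches` (named integer vector), `composition` (group x branch
#'   table or `NULL`), `region_hclust`, `leaf_order`.
#' @export
cluster_tumors <- function(mat, n_branches = 2, groups = NULL) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 3) .stopf("need >= 3 samples to cluster")
  if (anyNA(mat)) .stopf("feature matrix must not contain missing entries")
  v <- apply(mat, 1, stats::var)
  if (any(v == 0))
    .stopf("zero-variance sample vector: %s",
           paste(rownames(mat)[v == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  hc <- stats::hclust(d, method = "complete")
  dend <- stats::reorder(stats::as.dendrogram(hc), rowMeans(mat),
                         agglo.FUN = mean)
  branches <- stats::cutree(hc, k = n_branches)
  composition <- if (!is.null(groups)) table(group = groups,
                                             branch = branches) else NULL
  region_hc <- NULL
  vr <- apply(mat, 2, stats::var)
  if (ncol(mat) >= 3 && all(vr > 0))
    region_hc <- stats::hclust(stats::as.dist(1 - stats::cor(mat)),
                               method = "complete")
  structure(list(hclust = hc, dendrogram = dend, branches = branches,
                 composition = composition, region_hclust = region_hc,
                 leaf_order = labels(dend)),
            class = "cluster_result")
}

#' Export a clustering dendrogram in Newick format
#'
#' @param result a `cluster_result`.
#' @param path output file.
#' @param what `"samples"` or `"regions"`.
#' @return invisibly, the path.
#' @export
export_newick <- function(result, path, what = c("samples", "regions")) {
  what <- match.arg(what)
  hc <- if (what == "samples") result$hclust else result$region_hclust
  if (is.null(hc)) .stopf("no %s tree available", what)
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
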