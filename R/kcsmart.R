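#' Gaussian smoothing kernel specification
#'
#' The kernel width is the total effective support of the Gaussian:
#' `sigma_mb = width_mb / 4` with truncation at `truncation * sigma` on each
#' side, so the default 20 Mb kernel has sigma = 5 Mb and support +/- 10 Mb.
#' Kernels never cross chromosome boundaries.
#'
#' @param width_mb kernel width in Mb (default 20, the width at which
#'   smoothed single-tumor profiles recapitulate raw BAC-array data well).
#' @param truncation support half-width in multiples of sigma (>= 2).
#' @return a `kernel_spec` list with `width_mb`, `sigma_mb`, `truncation`.
#' @export
kernel_spec <- function(width_mb = 20, truncation = 2) {
  stopifnot(width_mb > 0, truncation >= 2)
  structure(list(width_mb = width_mb, sigma_mb = width_mb / 4,
                 truncation = truncation),
            class = "kernel_spec")
}

#' Truncated Gaussian kernel weight
#'
#' `K(d) = exp(-d^2 / (2 sigma^2))` for `|d| <= truncation * sigma`, else 0.
#' `K(0) = 1`; symmetric in `d`.
#'
#' @param d_bp distance(s) in bp.
#' @param spec a [kernel_spec()].
#' @return weights in `[0, 1]`.
#' @export
kernel_weight <- function(d_bp, spec = kernel_spec()) {
  sigma <- spec$sigma_mb * 1e6
  w <- exp(-d_bp^2 / (2 * sigma^2))
  w[abs(d_bp) > spec$truncation * sigma] <- 0
  w
}

# Precompute, per chromosome, the truncated-Gaussian weight matrix from a
# regular grid to the probe midpositions, plus its row sums. Reused across
# samples and permutations so the matrix product is the only per-pass cost.
.kse_weights <- function(map, spec, grid_step_bp) {
  lens <- .map_chrom_lengths(map)
  chroms <- .chrom_levels(map$chrom)
  per_chrom <- vector("list", length(chroms))
  names(per_chrom) <- chroms
  grid_list <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n_pts <- max(1L, floor(lens[[ch]] / grid_step_bp))
    pos <- (seq_len(n_pts) - 0.5) * grid_step_bp
    idx <- which(map$chrom == ch)
    W <- kernel_weight(outer(pos, map$midpos[idx], "-"), spec)
    per_chrom[[ci]] <- list(idx = idx, W = W, denom = rowSums(W))
    grid_list[[ci]] <- data.frame(chrom = ch, pos = pos,
                                  stringsAsFactors = FALSE)
  }
  list(grid = do.call(rbind, grid_list), per_chrom = per_chrom)
}

# Nadaraya-Watson smoothing of a probes x samples matrix onto the grid;
# grid points with zero total kernel weight come back NA (absent)
.apply_kse <- function(wts, values) {
  out <- matrix(NA_real_, nrow(wts$grid), ncol(values),
                dimnames = list(NULL, colnames(values)))
  row0 <- 0L
  for (pc in wts$per_chrom) {
    n <- length(pc$denom)
    rows <- row0 + seq_len(n)
    if (length(pc$idx)) {
      num <- pc$W %*% values[pc$idx, , drop = FALSE]
      ok <- pc$denom > 0
      out[rows[ok], ] <- num[ok, , drop = FALSE] / pc$denom[ok]
    } else {
      warning(sprintf("chromosome %s has no probes; grid marked absent",
                      wts$grid$chrom[rows[1]]))
    }
    row0 <- row0 + n
  }
  out
}

#' Kernel-smoothed estimate (KSE) curves for every sample of a cohort
#'
#' For each genomic grid position x the KSE is the locally normalized kernel
#' sum over the probes of x's chromosome,
#' `KSE(x) = sum_i a_i K(x - x_i) / sum_i K(x - x_i)`, with `a_i` the log2
#' ratio anchored at probe midposition `x_i`. This keeps the curve in log2-
#' ratio units, so cutoffs applied to it are commensurate with the input
#' data. Positions beyond kernel reach of any probe are `NA`.
#'
#' @param cohort an `acgh_cohort`.
#' @param spec a [kernel_spec()].
#' @param grid_step_bp grid step within chromosomes (default 100 kb);
#'   must be at most a quarter kernel width.
#' @param values optional replacement probes x samples matrix (same probe
#'   order as the cohort map), e.g. rectified gains/losses.
#' @return a `kse_set`: list with `grid` (chrom, pos), `values`
#'   (grid x samples matrix), `samples`, `spec`, `grid_step_bp`.
#' @export
kse_matrix <- function(cohort, spec = kernel_spec(), grid_step_bp = 1e5,
                       values = NULL) {
  stopifnot(inherits(cohort, "acgh_cohort"), inherits(spec, "kernel_spec"))
  if (grid_step_bp > spec$width_mb * 1e6 / 4)
    .stopf("grid_step_bp must be <= kernel width / 4")
  if (is.null(values)) values <- cohort$values
  wts <- .kse_weights(cohort$map, spec, grid_step_bp)
  structure(list(grid = wts$grid, values = .apply_kse(wts, values),
                 samples = cohort$samples, spec = spec,
                 grid_step_bp = grid_step_bp),
            class = "kse_set")
}

#' Smoothed profile of a single tumor
#'
#' @inheritParams kse_matrix
#' @param sample_id one sample id of the cohort.
#' @return a `kse_curve`: list with `grid`, `values` (one per grid point),
#'   `label`, `flavor = "signed"`.
#' @export
kse_profile <- function(cohort, sample_id, spec = kernel_spec(),
                        grid_step_bp = 1e5) {
  if (!sample_id %in% cohort$samples$sample_id)
    .stopf("unknown sample: %s", sample_id)
  ks <- kse_matrix(cohort, spec, grid_step_bp)
  structure(list(grid = ks$grid, values = ks$values[, sample_id],
                 label = sample_id, flavor = "signed",
                 grid_step_bp = grid_step_bp),
            class = "kse_curve")
}

#' Group-level gains and losses curves
#'
#' Gains: positive parts `max(a, 0)` of every tumor's probe values, pooled
#' over the group and smoothed (each tumor's probes contribute equally, so
#' the curve is the mean of per-tumor smoothed positive parts). Losses:
#' likewise with `min(a, 0)`. Gains are everywhere >= 0, losses <= 0.
#'
#' @inheritParams kse_matrix
#' @param group group label present in the cohort sample sheet.
#' @return list with `gains` and `losses` `kse_curve`s.
#' @export
group_kse <- function(cohort, group, spec = kernel_spec(),
                      grid_step_bp = 1e5) {
  cols <- which(cohort$samples$group == group)
  if (!length(cols)) .stopf("unknown or empty group: %s", group)
  A <- cohort$values[, cols, drop = FALSE]
  wts <- .kse_weights(cohort$map, spec, grid_step_bp)
  gains <- rowMeans(.apply_kse(wts, pmax(A, 0)))
  losses <- rowMeans(.apply_kse(wts, pmin(A, 0)))
  mk <- function(v, fl) structure(list(grid = wts$grid, values = v,
                                       label = group, flavor = fl,
                                       grid_step_bp = grid_step_bp),
                                  class = "kse_curve")
  list(gains = mk(gains, "gains"), losses = mk(losses, "losses"))
}

#' Single-group significance thresholds for gains and losses
#'
#' The null is generated by independently permuting each tumor's log2
#' ratios across probe positions (preserving every tumor's value
#' distribution while destroying genomic localization). The gain threshold
#' is the `1 - alpha` quantile of the genome-wide maximum of the null gains
#' curve over permutations; the loss threshold is the `alpha` quantile of
#' the genome-wide minimum of the null losses curve. Significant intervals
#' are maximal grid runs where the observed curve exceeds its threshold.
#'
#' @inheritParams group_kse
#' @param alpha genome-wide significance level (default 0.05).
#' @param n_perm number of permutations (>= 20; default 1000).
#' @param seed integer seed for the permutations.
#' @return list with `gain_threshold`, `loss_threshold`, `gains`, `losses`
#'   (observed curves) and `regions` (a `region_table` of significant
#'   intervals).
#' @export
single_group_threshold <- function(cohort, group, spec = kernel_spec(),
                                   grid_step_bp = 1e5, alpha = 0.05,
                                   n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 20, alpha > 0, alpha <= 1)
  cols <- which(cohort$samples$group == group)
  if (!length(cols)) .stopf("unknown or empty group: %s", group)
  A <- cohort$values[, cols, drop = FALSE]
  wts <- .kse_weights(cohort$map, spec, grid_step_bp)
  gains <- rowMeans(.apply_kse(wts, pmax(A, 0)))
  losses <- rowMeans(.apply_kse(wts, pmin(A, 0)))
  set.seed(seed)
  max_gain <- numeric(n_perm)
  min_loss <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    Ap <- apply(A, 2, sample)
    max_gain[p] <- max(rowMeans(.apply_kse(wts, pmax(Ap, 0))), na.rm = TRUE)
    min_loss[p] <- min(rowMeans(.apply_kse(wts, pmin(Ap, 0))), na.rm = TRUE)
  }
  t_gain <- stats::quantile(max_gain, 1 - alpha, names = FALSE)
  t_loss <- stats::quantile(min_loss, alpha, names = FALSE)
  regs <- rbind(.curve_runs_regions(wts$grid, gains > t_gain, "gain", group,
                                    grid_step_bp),
                .curve_runs_regions(wts$grid, losses < t_loss, "loss", group,
                                    grid_step_bp))
  list(gain_threshold = t_gain, loss_threshold = t_loss,
       gains = gains, losses = losses, grid = wts$grid, regions = regs)
}

# turn a logical flag over the grid into a region_table of maximal runs
.curve_runs_regions <- function(grid, flag, direction, group, step_bp,
                                merge_gap_steps = 0L) {
  rows <- list()
  for (ch in .chrom_levels(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    f <- flag[idx]
    if (merge_gap_steps > 0L) f <- .merge_gaps(f, merge_gap_steps)
    runs <- .runs(f)
    if (nrow(runs) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom_region = ch,
      start_mb = (grid$pos[idx[runs[, "start"]]] - step_bp / 2) / 1e6,
      end_mb = (grid$pos[idx[runs[, "end"]]] + step_bp / 2) / 1e6,
      idx_start = idx[runs[, "start"]], idx_end = idx[runs[, "end"]],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- region_table(character(0), numeric(0), numeric(0),
                        character(0), character(0))
    out$idx_start <- integer(0)
    out$idx_end <- integer(0)
    return(out)
  }
  df <- do.call(rbind, rows)
  out <- region_table(df$chrom_region, df$start_mb, df$end_mb,
                      direction, group)
  out$idx_start <- df$idx_start
  out$idx_end <- df$idx_end
  out
}
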