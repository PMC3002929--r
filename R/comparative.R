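#' Permutation / FDR configuration for two-group comparisons
#'
#' @param n_perm number of class-label permutations (default 6000; >= 20).
#' @param fdr target false discovery rate over grid positions (default 0.05).
#' @param seed integer seed.
#' @return a `permutation_config` list.
#' @export
permutation_config <- function(n_perm = 6000, fdr = 0.05, seed = 1L) {
  stopifnot(n_perm >= 20, fdr > 0, fdr < 1)
  structure(list(n_perm = as.integer(n_perm), fdr = fdr,
                 seed = as.integer(seed)),
            class = "permutation_config")
}

# per-position group means and population SDs from a grid x samples matrix
.group_moments <- function(V, sel) {
  mu <- rowMeans(V[, sel, drop = FALSE])
  sd <- sqrt(pmax(rowMeans(V[, sel, drop = FALSE]^2) - mu^2, 0))
  list(mu = mu, sd = sd)
}

.snr_values <- function(V, is_a, eps = 1e-8) {
  a <- .group_moments(V, is_a)
  b <- .group_moments(V, !is_a)
  (a$mu - b$mu) / (a$sd + b$sd + eps)
}

#' Per-position signal-to-noise ratio between two tumor groups
#'
#' `SNR(x) = (mu_A(x) - mu_B(x)) / (sd_A(x) + sd_B(x) + eps)` over the
#' per-tumor smoothed (KSE) values at each grid position, with
#' within-group population SDs and a small epsilon guard. Antisymmetric
#' under group swap.
#'
#' @param kse a `kse_set` of per-tumor signed KSE curves ([kse_matrix()]).
#' @param group_a,group_b group labels; each must have >= 2 tumors.
#' @param labels optional per-sample group labels overriding the cohort
#'   sample sheet carried by `kse`.
#' @param eps denominator guard (default 1e-8).
#' @return an `snr_curve`: list with `grid`, `snr`, `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `group_a`, `group_b`.
#' @export
snr_curve <- function(kse, group_a, group_b, labels = NULL, eps = 1e-8) {
  stopifnot(inherits(kse, "kse_set"))
  if (is.null(labels)) labels <- kse$samples$group
  if (length(labels) != ncol(kse$values))
    .stopf("labels length does not match sample count")
  sel <- labels %in% c(group_a, group_b)
  if (sum(labels == group_a) < 2 || sum(labels == group_b) < 2)
    .stopf("both groups need >= 2 tumors")
  V <- kse$values[, sel, drop = FALSE]
  is_a <- labels[sel] == group_a
  a <- .group_moments(V, is_a)
  b <- .group_moments(V, !is_a)
  structure(list(grid = kse$grid,
                 snr = (a$mu - b$mu) / (a$sd + b$sd + eps),
                 mean_a = a$mu, mean_b = b$mu, sd_a = a$sd, sd_b = b$sd,
                 group_a = group_a, group_b = group_b, eps = eps,
                 grid_step_bp = kse$grid_step_bp),
            class = "snr_curve")
}

#' FDR-controlling SNR thresholds by class-label permutation
#'
#' Group labels are shuffled over the tumors of the two groups; each
#' permutation yields a null SNR curve. For a candidate threshold `t`
#' (scanned over the observed SNR values of each tail), the estimated FDR
#' is the mean number of null grid positions at or above `t` divided by the
#' observed count at or above `t`. `t_pos` is the smallest candidate with
#' estimated FDR at or below the target (`Inf` if none); `t_neg` is the
#' analogous magnitude on the negative tail. Positive and negative tails
#' are thresholded separately, matching the separate display of gains and
#' losses.
#'
#' @inheritParams snr_curve
#' @param cfg a [permutation_config()].
#' @return list with `t_pos`, `t_neg` (positive magnitudes, possibly
#'   `Inf`), the observed `snr` curve, `fdr`, `n_perm`.
#' @export
permutation_fdr_threshold <- function(kse, group_a, group_b,
                                      cfg = permutation_config(),
                                      labels = NULL) {
  stopifnot(inherits(kse, "kse_set"), inherits(cfg, "permutation_config"))
  if (is.null(labels)) labels <- kse$samples$group
  sel <- labels %in% c(group_a, group_b)
  lab <- labels[sel]
  if (sum(lab == group_a) < 2 || sum(lab == group_b) < 2)
    .stopf("both groups need >= 2 tumors")
  V <- kse$values[, sel, drop = FALSE]
  keep <- stats::complete.cases(V)
  V <- V[keep, , drop = FALSE]
  obs <- .snr_values(V, lab == group_a)
  n_distinct <- choose(length(lab), sum(lab == group_a))
  if (n_distinct < cfg$n_perm)
    warning(sprintf(
      "only %.0f distinct label permutations < n_perm = %d; sampling with replacement",
      n_distinct, cfg$n_perm))
  cand_pos <- sort(unique(obs[obs > 0]))
  cand_neg <- sort(unique(-obs[obs < 0]))
  null_ge_pos <- numeric(length(cand_pos))
  null_ge_neg <- numeric(length(cand_neg))
  set.seed(cfg$seed)
  for (p in seq_len(cfg$n_perm)) {
    null_snr <- .snr_values(V, sample(lab) == group_a)
    if (length(cand_pos)) {
      ns <- sort(null_snr)
      null_ge_pos <- null_ge_pos + (length(ns) -
        findInterval(cand_pos, ns, left.open = TRUE))
    }
    if (length(cand_neg)) {
      ns <- sort(-null_snr)
      null_ge_neg <- null_ge_neg + (length(ns) -
        findInterval(cand_neg, ns, left.open = TRUE))
    }
  }
  pick <- function(cand, null_ge, obs_tail) {
    if (!length(cand)) return(Inf)
    obs_ge <- length(obs_tail) - findInterval(cand, sort(obs_tail),
                                              left.open = TRUE)
    fdr_hat <- (null_ge / cfg$n_perm) / pmax(1, obs_ge)
    ok <- which(fdr_hat <= cfg$fdr)
    if (!length(ok)) Inf else cand[min(ok)]
  }
  snr_obj <- structure(list(grid = kse$grid[keep, , drop = FALSE],
                            snr = obs,
                            mean_a = .group_moments(V, lab == group_a)$mu,
                            mean_b = .group_moments(V, lab != group_a)$mu,
                            group_a = group_a, group_b = group_b,
                            grid_step_bp = kse$grid_step_bp),
                       class = "snr_curve")
  list(t_pos = pick(cand_pos, null_ge_pos, obs[obs > 0]),
       t_neg = pick(cand_neg, null_ge_neg, -obs[obs < 0]),
       snr = snr_obj, fdr = cfg$fdr, n_perm = cfg$n_perm)
}

#' Call differential regions from a thresholded SNR curve
#'
#' Regions are maximal grid runs with `SNR > t_pos` (copy-number signal
#' favoring group A) or `SNR < -t_neg` (favoring group B); runs separated
#' by at most `merge_gap_steps` sub-threshold grid points are merged. Each
#' region is annotated with the direction of the favored group's mean KSE
#' inside it (gain or loss) and with peak positions: the local maxima of
#' the absolute group-mean difference `|mu_A - mu_B|` within the region,
#' reported in Mb so peaks stay in signal units.
#'
#' @param snr an `snr_curve` (from [snr_curve()] or
#'   [permutation_fdr_threshold()]`$snr`).
#' @param thresholds list with `t_pos`, `t_neg` as returned by
#'   [permutation_fdr_threshold()].
#' @param merge_gap_steps merge runs separated by at most this many grid
#'   steps (default 1).
#' @return a `region_table` with extra columns `favored_group`,
#'   `threshold_used`, `peaks_mb`.
#' @export
call_differential_regions <- function(snr, thresholds, merge_gap_steps = 1L) {
  stopifnot(inherits(snr, "snr_curve"))
  step <- snr$grid_step_bp
  dif <- abs(snr$mean_a - snr$mean_b)
  build <- function(flag, favored, mean_fav, thr) {
    regs <- .curve_runs_regions(snr$grid, flag, "gain", favored, step,
                                merge_gap_steps = merge_gap_steps)
    if (nrow(regs) == 0L) return(regs)
    for (i in seq_len(nrow(regs))) {
      span <- regs$idx_start[i]:regs$idx_end[i]
      regs$direction[i] <- if (mean(mean_fav[span]) >= 0) "gain" else "loss"
      regs$peaks_mb[[i]] <- snr$grid$pos[span[.local_maxima(dif[span])]] / 1e6
      regs$peaks_outside[[i]] <- rep(FALSE, length(regs$peaks_mb[[i]]))
    }
    regs$favored_group <- favored
    regs$threshold_used <- thr
    regs
  }
  out <- list()
  if (is.finite(thresholds$t_pos))
    out$pos <- build(snr$snr > thresholds$t_pos, snr$group_a, snr$mean_a,
                     thresholds$t_pos)
  if (is.finite(thresholds$t_neg))
    out$neg <- build(snr$snr < -thresholds$t_neg, snr$group_b, snr$mean_b,
                     thresholds$t_neg)
  out <- out[!vapply(out, is.null, logical(1))]
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out)) {
    empty <- region_table(character(0), numeric(0), numeric(0),
                          character(0), character(0))
    empty$favored_group <- character(0)
    empty$threshold_used <- numeric(0)
    return(empty)
  }
  res <- do.call(rbind, out)
  res$idx_start <- NULL
  res$idx_end <- NULL
  rownames(res) <- NULL
  res
}

# indices of local maxima (plateau runs collapse to their midpoint)
.local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left_ok <- c(TRUE, r$values[-1L] > r$values[-k])
  right_ok <- c(r$values[-k] > r$values[-1L], TRUE)
  is_max <- left_ok & right_ok
  as.integer(floor((starts[is_max] + ends[is_max]) / 2))
}

#' Intersect same-direction regions from two comparisons
#'
#' Returns the interval intersections of regions sharing chromosome and
#' direction. Peaks from both inputs are carried; peaks falling outside the
#' intersection are kept but flagged (`peaks_outside`), since a recurrent
#' peak just beyond the shared interval is still informative.
#'
#' @param regions_1,regions_2 `region_table`s in the same coordinate system.
#' @return a `region_table` of intersections, sorted by (chrom, start).
#' @export
overlap_regions <- function(regions_1, regions_2) {
  stopifnot(inherits(regions_1, "region_table"),
            inherits(regions_2, "region_table"))
  rows <- list()
  for (i in seq_len(nrow(regions_1))) {
    for (j in seq_len(nrow(regions_2))) {
      if (regions_1$chrom[i] != regions_2$chrom[j]) next
      if (regions_1$direction[i] != regions_2$direction[j]) next
      s <- max(regions_1$start_mb[i], regions_2$start_mb[j])
      e <- min(regions_1$end_mb[i], regions_2$end_mb[j])
      if (s >= e) next
      peaks <- c(regions_1$peaks_mb[[i]], regions_2$peaks_mb[[j]])
      grp <- paste(unique(c(regions_1$group[i], regions_2$group[j])),
                   collapse = "+")
      rows[[length(rows) + 1L]] <- list(
        chrom_region = regions_1$chrom_region[i], start_mb = s, end_mb = e,
        direction = regions_1$direction[i], group = grp, peaks = peaks)
    }
  }
  if (!length(rows))
    return(region_table(character(0), numeric(0), numeric(0), character(0),
                        character(0)))
  out <- region_table(
    vapply(rows, `[[`, character(1), "chrom_region"),
    vapply(rows, `[[`, numeric(1), "start_mb"),
    vapply(rows, `[[`, numeric(1), "end_mb"),
    vapply(rows, `[[`, character(1), "direction"),
    vapply(rows, `[[`, character(1), "group"),
    peaks_mb = lapply(rows, `[[`, "peaks"))
  for (i in seq_len(nrow(out)))
    out$peaks_outside[[i]] <- out$peaks_mb[[i]] < out$start_mb[i] |
      out$peaks_mb[[i]] >= out$end_mb[i]
  ord <- order(match(out$chrom, .chrom_levels(out$chrom)), out$start_mb)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
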