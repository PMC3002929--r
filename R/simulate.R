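#' Specify a recurrent copy-number segment for cohort simulation
#'
#' A segment is gained or lost in a tumor with a group-specific probability
#' (penetrance). When present, its amplitude in that tumor is drawn from
#' `N(amplitude_mean, amplitude_sd)` and attenuated by the tumor-cell
#' fraction, so partial tumor content shrinks the observed log2 ratio the
#' way admixed normal DNA does on a real array.
#'
#' @param chrom chromosome label (must exist in the probe map used later).
#' @param start_bp,end_bp segment bounds in bp, 0-based half-open.
#' @param direction `"gain"` or `"loss"`.
#' @param amplitude_mean mean log2-ratio amplitude; must be positive for
#'   gains, negative for losses.
#' @param amplitude_sd between-tumor SD of the amplitude (>= 0).
#' @param penetrance named numeric vector, group -> probability in `[0, 1]`.
#' @param id segment label used in the truth table.
#' @return a `cna_segment` list.
#' @export
cna_segment <- function(chrom, start_bp, end_bp, direction = c("gain", "loss"),
                        amplitude_mean, amplitude_sd = 0, penetrance,
                        id = NULL) {
  direction <- match.arg(direction)
  stopifnot(start_bp < end_bp, amplitude_sd >= 0,
            all(penetrance >= 0 & penetrance <= 1),
            !is.null(names(penetrance)))
  if (direction == "gain" && amplitude_mean <= 0)
    .stopf("gain segment must have amplitude_mean > 0")
  if (direction == "loss" && amplitude_mean >= 0)
    .stopf("loss segment must have amplitude_mean < 0")
  if (is.null(id)) id <- sprintf("%s:%.2f-%.2fMb_%s", chrom, start_bp / 1e6,
                                 end_bp / 1e6, direction)
  structure(list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 direction = direction, amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, penetrance = penetrance,
                 id = id),
            class = "cna_segment")
}

#' Specify a synthetic aCGH cohort
#'
#' Bundles everything [simulate_cohort()] needs: group sizes, the recurrent
#' segments with their per-group penetrances, probe-level noise, the range
#' of tumor-cell fractions, and the platform each group was hybridized on
#' together with a per-platform multiplicative scale. The platform scale
#' emulates the consistently wider log2-ratio distribution of FFPE-derived
#' DNA relative to fresh-frozen material; 1.5 vs 1.0 is the packaged default.
#'
#' @param n_per_group named integer vector, group -> number of tumors (>= 1).
#' @param segments list of [cna_segment()] objects.
#' @param probe_noise_sd i.i.d. Gaussian noise SD per probe, log2-ratio
#'   units (default 0.15, a typical BAC-array residual).
#' @param tumor_fraction_range length-2 interval in `[0, 1]` from which each
#'   tumor's cell fraction is drawn uniformly.
#' @param platform_by_group named character vector, group -> platform label.
#'   Defaults to `"array"` for every group.
#' @param platform_scale named numeric vector, platform -> positive scale
#'   factor applied multiplicatively to all values of that platform.
#' @param seed integer seed making the simulation deterministic.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group, segments = list(), probe_noise_sd = 0.15,
                        tumor_fraction_range = c(0.3, 0.9),
                        platform_by_group = NULL, platform_scale = NULL,
                        seed = 1L) {
  stopifnot(length(n_per_group) >= 1, all(n_per_group >= 1),
            !is.null(names(n_per_group)), probe_noise_sd >= 0,
            length(tumor_fraction_range) == 2,
            tumor_fraction_range[1] <= tumor_fraction_range[2],
            all(tumor_fraction_range >= 0 & tumor_fraction_range <= 1))
  groups <- names(n_per_group)
  if (is.null(platform_by_group))
    platform_by_group <- stats::setNames(rep("array", length(groups)), groups)
  if (!all(groups %in% names(platform_by_group)))
    .stopf("platform_by_group must cover every group")
  if (is.null(platform_scale))
    platform_scale <- stats::setNames(rep(1, length(unique(platform_by_group))),
                                      unique(platform_by_group))
  if (!all(platform_by_group %in% names(platform_scale)))
    .stopf("platform_scale must cover every platform")
  if (any(platform_scale <= 0)) .stopf("platform_scale must be > 0")
  for (seg in segments) {
    stopifnot(inherits(seg, "cna_segment"))
    extra <- setdiff(names(seg$penetrance), groups)
    if (length(extra))
      .stopf("segment %s has penetrance for unknown group(s): %s",
             seg$id, paste(extra, collapse = ", "))
  }
  structure(list(n_per_group = n_per_group, segments = segments,
                 probe_noise_sd = probe_noise_sd,
                 tumor_fraction_range = tumor_fraction_range,
                 platform_by_group = platform_by_group,
                 platform_scale = platform_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate an aCGH cohort with known segment truth
#'
#' For each tumor: a tumor-cell fraction is drawn uniformly from the spec's
#' range; each segment is present with its group's penetrance; the log2
#' ratio of a probe is the sum of the (amplitude x fraction) contributions
#' of the present segments covering its midposition, plus i.i.d. Gaussian
#' noise, finally multiplied by the platform scale of the tumor's group.
#' Every presence draw, amplitude and fraction is recorded in a truth table
#' so downstream detection can be scored against ground truth.
#'
#' @param map a `probe_map` from [make_probe_map()].
#' @param spec a [cohort_spec()].
#' @return list with elements `cohort` (an `acgh_cohort`) and `truth`
#'   (data frame: sample_id, group, segment_id, chrom, start_bp, end_bp,
#'   direction, present, amplitude, tumor_fraction).
#' @export
simulate_cohort <- function(map, spec) {
  stopifnot(inherits(map, "probe_map"), inherits(spec, "cohort_spec"))
  lens <- .map_chrom_lengths(map)
  for (seg in spec$segments) {
    if (!seg$chrom %in% names(lens) || seg$start_bp < 0 ||
        seg$end_bp > lens[[seg$chrom]])
      .stopf("segment %s lies outside the genome of the probe map", seg$id)
  }
  set.seed(spec$seed)
  groups <- names(spec$n_per_group)
  samples <- do.call(rbind, lapply(groups, function(g) {
    data.frame(sample_id = sprintf("%s_%02d", g, seq_len(spec$n_per_group[[g]])),
               group = g, platform = unname(spec$platform_by_group[[g]]),
               stringsAsFactors = FALSE)
  }))
  n_probe <- nrow(map)
  n_samp <- nrow(samples)
  in_seg <- lapply(spec$segments, function(seg)
    which(map$chrom == seg$chrom & map$midpos >= seg$start_bp &
            map$midpos < seg$end_bp))
  values <- matrix(0, n_probe, n_samp,
                   dimnames = list(map$probe_id, samples$sample_id))
  truth <- vector("list", n_samp)
  for (j in seq_len(n_samp)) {
    g <- samples$group[j]
    tf <- stats::runif(1, spec$tumor_fraction_range[1],
                       spec$tumor_fraction_range[2])
    rows <- lapply(seq_along(spec$segments), function(k) {
      seg <- spec$segments[[k]]
      pen <- if (g %in% names(seg$penetrance)) seg$penetrance[[g]] else 0
      present <- stats::rbinom(1, 1, pen) == 1L
      amp <- stats::rnorm(1, seg$amplitude_mean, seg$amplitude_sd)
      if (present) values[in_seg[[k]], j] <<- values[in_seg[[k]], j] + amp * tf
      data.frame(sample_id = samples$sample_id[j], group = g,
                 segment_id = seg$id, chrom = seg$chrom,
                 start_bp = seg$start_bp, end_bp = seg$end_bp,
                 direction = seg$direction, present = present,
                 amplitude = amp, tumor_fraction = tf,
                 stringsAsFactors = FALSE)
    })
    if (length(rows)) truth[[j]] <- do.call(rbind, rows)
  }
  if (spec$probe_noise_sd > 0)
    values <- values + matrix(stats::rnorm(n_probe * n_samp, 0,
                                           spec$probe_noise_sd),
                              n_probe, n_samp)
  scale <- spec$platform_scale[samples$platform]
  values <- sweep(values, 2, scale, "*")
  truth <- truth[!vapply(truth, is.null, logical(1))]
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(0), group = character(0),
               segment_id = character(0), chrom = character(0),
               start_bp = numeric(0), end_bp = numeric(0),
               direction = character(0), present = logical(0),
               amplitude = numeric(0), tumor_fraction = numeric(0),
               stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  list(cohort = acgh_cohort(map, values, samples), truth = truth_df)
}

#' Specify per-group TP53 mutation-class frequencies
#'
#' @param profiles named list, group -> numeric vector with entries
#'   `wildtype`, `complex`, `deleterious_missense`, `tolerated_missense`
#'   summing to 1 (tolerance 1e-9).
#' @param seed integer seed.
#' @return a `mutation_profile_spec` list.
#' @export
mutation_profile_spec <- function(profiles, seed = 1L) {
  classes <- c("wildtype", "complex", "deleterious_missense",
               "tolerated_missense")
  stopifnot(is.list(profiles), length(profiles) >= 1, !is.null(names(profiles)))
  for (g in names(profiles)) {
    p <- profiles[[g]]
    if (!all(classes %in% names(p)))
      .stopf("profile for group %s must name all of: %s", g,
             paste(classes, collapse = ", "))
    p <- p[classes]
    if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-9)
      .stopf("profile for group %s must be probabilities summing to 1", g)
    profiles[[g]] <- p
  }
  structure(list(profiles = profiles, seed = as.integer(seed)),
            class = "mutation_profile_spec")
}

# small catalogs used to synthesize parseable mutation strings
.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.synth_complex_string <- function() {
  kind <- sample(c("nonsense", "frameshift_del", "frameshift_ins",
                   "inframe_del", "splice"), 1)
  codon <- sample(30:330, 1)
  switch(kind,
    nonsense = sprintf("%s%dX", sample(.aa_letters, 1), codon),
    frameshift_del = sprintf("%ddel%s", codon,
                             paste(sample(c("A", "C", "G", "T"),
                                          sample(c(1, 2, 4), 1), TRUE),
                                   collapse = "")),
    frameshift_ins = sprintf("%dins%s", codon,
                             paste(sample(c("A", "C", "G", "T"),
                                          sample(c(1, 2), 1), TRUE),
                                   collapse = "")),
    inframe_del = if (stats::runif(1) < 0.5)
      sprintf("%d_%ddel", codon, codon + 1) else
      sprintf("%ddel%s", codon,
              paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")),
    splice = sprintf("IVS%d%+d %s > %s (splice)", sample(2:9, 1),
                     sample(c(-2, -1, 1, 2), 1), sample(c("A", "G"), 1),
                     sample(c("C", "T"), 1))
  )
}

.synth_missense_string <- function(hotspot_ok) {
  hs <- tp53_hotspots()
  if (hotspot_ok && stats::runif(1) < 0.5) {
    i <- sample(nrow(hs), 1)
    ref <- hs$ref_aa[i]; codon <- hs$codon[i]
  } else {
    repeat {
      codon <- sample(30:330, 1)
      if (!codon %in% hs$codon) break
    }
    ref <- sample(.aa_letters, 1)
  }
  alt <- sample(setdiff(.aa_letters, ref), 1)
  sprintf("%s%d%s", ref, codon, alt)
}

#' Simulate a TP53 mutation table
#'
#' Each tumor is assigned exactly one mutation class drawn from its group's
#' frequency profile and given a syntactically valid mutation string of that
#' class, so the emitted table round-trips through [parse_mutation()] with
#' the intended classification. Deleterious missense strings are drawn from
#' the hotspot catalog half the time; tolerated missense strings avoid it.
#'
#' @param spec a [mutation_profile_spec()].
#' @param n_per_group named integer vector, group -> number of tumors.
#' @return data frame in the mutation-table schema (sample_id, group,
#'   mutation, predicted_deleterious, abundance) plus the hidden
#'   `true_class` column used by tests.
#' @export
simulate_mutation_table <- function(spec, n_per_group) {
  stopifnot(inherits(spec, "mutation_profile_spec"))
  unknown <- setdiff(names(n_per_group), names(spec$profiles))
  if (length(unknown))
    .stopf("unknown group(s): %s", paste(unknown, collapse = ", "))
  set.seed(spec$seed)
  classes <- c("wildtype", "complex", "deleterious_missense",
               "tolerated_missense")
  rows <- lapply(names(n_per_group), function(g) {
    n <- n_per_group[[g]]
    cls <- sample(classes, n, replace = TRUE, prob = spec$profiles[[g]])
    mut <- vapply(cls, function(k) switch(k,
      wildtype = "wild type",
      complex = .synth_complex_string(),
      deleterious_missense = .synth_missense_string(hotspot_ok = TRUE),
      tolerated_missense = .synth_missense_string(hotspot_ok = FALSE)
    ), character(1))
    data.frame(sample_id = sprintf("%s_%03d", g, seq_len(n)), group = g,
               mutation = mut,
               predicted_deleterious = ifelse(cls == "tolerated_missense",
                                              FALSE,
                                              ifelse(cls == "wildtype", NA,
                                                     TRUE)),
               abundance = round(stats::runif(n, 0.26, 1), 2),
               true_class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
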