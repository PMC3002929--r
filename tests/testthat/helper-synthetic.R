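# shared fixtures built in code

# compact two-chromosome genome for fast smoothing tests
small_map <- function(spacing = 1e6, n_chr = 2, chr_mb = 100) {
  lens <- stats::setNames(rep(chr_mb * 1e6, n_chr),
                          paste0("chr", seq_len(n_chr)))
  make_probe_map(lens, spacing_bp = spacing)
}

# pure-noise two-group cohort
noise_cohort <- function(map, n_a = 10, n_b = 10, noise = 0.2, seed = 1,
                         groups = c("A", "B")) {
  spec <- cohort_spec(stats::setNames(c(n_a, n_b), groups),
                      segments = list(), probe_noise_sd = noise,
                      tumor_fraction_range = c(1, 1), seed = seed)
  simulate_cohort(map, spec)$cohort
}

# cohort with one group-specific 20 Mb gain on chr1
spike_cohort <- function(map, n_a = 10, n_b = 10, amplitude = 1,
                         noise = 0.2, seed = 1, start = 20e6, end = 40e6,
                         pen_b = 0) {
  seg <- cna_segment("chr1", start, end, "gain", amplitude, 0,
                     penetrance = c(A = 1, B = pen_b))
  spec <- cohort_spec(c(A = n_a, B = n_b), list(seg), probe_noise_sd = noise,
                      tumor_fraction_range = c(1, 1), seed = seed)
  simulate_cohort(map, spec)
}

# best per-region Jaccard index between called intervals (bp) and one true
# interval: does some call recover the truth?
interval_jaccard <- function(regions, true_chrom, true_start, true_end,
                             step_bp) {
  if (nrow(regions) == 0) return(0)
  best <- 0
  for (i in seq_len(nrow(regions))) {
    if (regions$chrom[i] != true_chrom) next
    s <- regions$start_mb[i] * 1e6; e <- regions$end_mb[i] * 1e6
    inter <- max(0, min(e, true_end) - max(s, true_start))
    union <- (e - s) + (true_end - true_start) - inter
    best <- max(best, inter / union)
  }
  best
}

expect_region_table <- function(x) {
  expect_s3_class(x, "region_table")
  expect_true(all(c("chrom_region", "chrom", "start_mb", "end_mb",
                    "direction", "group") %in% names(x)))
}
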