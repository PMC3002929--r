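#' Chromosome lengths of the human genome build used for the BAC platform
#'
#' Lengths (rounded to whole megabases) of the chromosomes of NCBI Build 36
#' (hg18). The default set is the 22 autosomes plus chromosome X, roughly
#' 3.02 Gb, so that a 1 Mb-spaced probe map over it has about 3,000 probes,
#' emulating the ~3,500-clone BAC/PAC array used for breast-tumor aCGH.
#' Chromosome Y is excluded: breast-tumor cohorts are effectively all female
#' and the platform's handling of Y is immaterial here.
#'
#' @param include_x include chromosome X (default `TRUE`).
#' @return named numeric vector of lengths in base pairs.
#' @export
hg18_chrom_lengths <- function(include_x = TRUE) {
  mb <- c(
    chr1 = 247, chr2 = 243, chr3 = 199, chr4 = 191, chr5 = 181,
    chr6 = 171, chr7 = 159, chr8 = 146, chr9 = 140, chr10 = 135,
    chr11 = 134, chr12 = 132, chr13 = 114, chr14 = 106, chr15 = 100,
    chr16 = 89, chr17 = 79, chr18 = 76, chr19 = 64, chr20 = 62,
    chr21 = 47, chr22 = 50, chrX = 155
  )
  if (!include_x) mb <- mb[names(mb) != "chrX"]
  mb * 1e6
}

#' Build an evenly spaced (optionally jittered) genomic probe map
#'
#' Places probes at the midpoints of consecutive `spacing_bp` windows along
#' each chromosome, optionally displaced by a uniform jitter, emulating a
#' BAC/PAC array with ~1 Mb average spacing. Probe intervals are
#' 0-based half-open; `midpos` is the interval midpoint (`floor((start+end)/2)`)
#' and is the position at which a probe's log2 ratio is anchored for kernel
#' smoothing.
#'
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param spacing_bp probe spacing in bp (default 1 Mb).
#' @param jitter_bp maximum uniform displacement of each probe midposition;
#'   must be smaller than `spacing_bp / 2` so probe order is preserved.
#' @param seed integer seed for the jitter draw; ignored when `jitter_bp = 0`.
#' @return a `probe_map` data frame with columns `chrom`, `start`, `end`,
#'   `midpos`, `probe_id`, sorted by (chrom, midpos), with the chromosome
#'   lengths kept in `attr(, "chrom_lengths")`.
#' @export
make_probe_map <- function(chrom_lengths, spacing_bp = 1e6, jitter_bp = 0,
                           seed = NULL) {
  if (length(chrom_lengths) == 0L) .stopf("no genome: empty chrom_lengths")
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)))
    .stopf("chrom_lengths must be a named vector")
  stopifnot(spacing_bp > 0, jitter_bp >= 0)
  if (jitter_bp >= spacing_bp / 2)
    .stopf("jitter_bp must be < spacing_bp/2")
  if (!is.null(seed)) set.seed(seed)
  half <- min(50000, floor(spacing_bp / 2)) # nominal clone half-width
  pieces <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    n <- floor(len / spacing_bp)
    if (n < 1L) return(NULL)
    mid <- (seq_len(n) - 0.5) * spacing_bp
    if (jitter_bp > 0) mid <- mid + stats::runif(n, -jitter_bp, jitter_bp)
    mid <- round(pmin(pmax(mid, half), len - half))
    data.frame(
      chrom = chr,
      start = mid - half,
      end = mid + half,
      midpos = mid,
      probe_id = sprintf("%s_p%04d", chr, seq_len(n)),
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  if (is.null(map) || nrow(map) == 0L) .stopf("no genome: no probes fit")
  map <- map[order(match(map$chrom, names(chrom_lengths)), map$midpos), ,
             drop = FALSE]
  rownames(map) <- NULL
  attr(map, "chrom_lengths") <- chrom_lengths
  class(map) <- c("probe_map", "data.frame")
  validate_probe_map(map)
}

#' @rdname make_probe_map
#' @param map object to validate.
#' @export
validate_probe_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("chrom", "start", "end", "midpos", "probe_id") %in% names(map)))
  if (any(map$start >= map$end)) .stopf("probe map: start must be < end")
  if (anyDuplicated(map$probe_id)) .stopf("probe map: duplicate probe_id")
  if (any(map$midpos != floor((map$start + map$end) / 2)))
    .stopf("probe map: midpos must equal floor((start+end)/2)")
  ord <- order(match(map$chrom, .chrom_levels(map$chrom)), map$midpos)
  if (!identical(ord, seq_len(nrow(map))))
    .stopf("probe map: probes must be sorted by (chrom, midpos)")
  map
}

# chromosome extents for grid construction: stored lengths if available,
# else the largest probe end per chromosome
.map_chrom_lengths <- function(map) {
  len <- attr(map, "chrom_lengths")
  chroms <- .chrom_levels(map$chrom)
  if (!is.null(len) && all(chroms %in% names(len))) return(len[chroms])
  vapply(chroms, function(ch) max(map$end[map$chrom == ch]), numeric(1))
}
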