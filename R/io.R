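#' Construct an aCGH cohort container
#'
#' Binds a probe map, a probes x samples matrix of log2 ratios and a sample
#' sheet (sample_id, group, platform). Rows of the matrix must correspond to
#' the probe map in order; no missing values are allowed once constructed
#' (loading via [read_acgh()] drops or imputes them first).
#'
#' @param map a `probe_map`.
#' @param values numeric matrix, probes x samples, rownames = probe ids,
#'   colnames = sample ids.
#' @param samples data frame with columns `sample_id`, `group`, `platform`.
#' @return an `acgh_cohort` list.
#' @export
acgh_cohort <- function(map, values, samples) {
  stopifnot(is.matrix(values), is.data.frame(samples),
            all(c("sample_id", "group", "platform") %in% names(samples)))
  if (nrow(values) != nrow(map))
    .stopf("matrix has %d rows but probe map has %d probes",
           nrow(values), nrow(map))
  if (ncol(values) != nrow(samples))
    .stopf("matrix has %d columns but sample sheet has %d samples",
           ncol(values), nrow(samples))
  if (!is.null(rownames(values)) &&
      !identical(rownames(values), map$probe_id))
    .stopf("matrix rownames do not match probe map order")
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), samples$sample_id))
    .stopf("matrix colnames do not match sample sheet order")
  if (anyNA(values)) .stopf("cohort matrix must not contain missing values")
  dimnames(values) <- list(map$probe_id, samples$sample_id)
  structure(list(map = map, values = values, samples = samples),
            class = "acgh_cohort")
}

#' @export
print.acgh_cohort <- function(x, ...) {
  cat(sprintf("aCGH cohort: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("groups:", paste(sprintf("%s=%d", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an aCGH cohort from probe/matrix/sample-sheet TSVs
#'
#' Probes are re-sorted by (chrom, midpos). Probes with more than 20%
#' missing values across samples are dropped; remaining missing cells are
#' imputed with the median of the probe's chromosome within that sample.
#' A load report (probes dropped, cells imputed) is emitted via [message()]
#' and attached as `attr(, "load_report")`.
#'
#' @param probe_path BED-like TSV: chrom, start, end, probe_id.
#' @param matrix_path TSV: probe_id column then one column per sample.
#' @param samples_path TSV: sample_id, group, platform.
#' @param max_missing_frac drop probes exceeding this missing fraction.
#' @return an `acgh_cohort`.
#' @export
read_acgh <- function(probe_path, matrix_path, samples_path,
                      max_missing_frac = 0.2) {
  for (p in c(probe_path, matrix_path, samples_path))
    if (!file.exists(p)) .stopf("file not found: %s", p)
  probes <- utils::read.delim(probe_path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end", "probe_id") %in% names(probes)))
    .stopf("probe file must have columns chrom, start, end, probe_id")
  bad <- which(is.na(probes$start) | is.na(probes$end) |
                 is.na(probes$chrom) | is.na(probes$probe_id) |
                 probes$probe_id == "")
  if (length(bad))
    .stopf("probe file: malformed row at line %d", bad[1] + 1L)
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (nrow(mat_df) == 0L || ncol(mat_df) < 2L) .stopf("empty matrix")
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  bad <- which(is.na(samples$sample_id) | is.na(samples$group) |
                 is.na(samples$platform))
  if (length(bad))
    .stopf("sample sheet: malformed row at line %d", bad[1] + 1L)
  missing_cols <- setdiff(samples$sample_id, names(mat_df))
  if (length(missing_cols))
    .stopf("matrix lacks sample column(s): %s",
           paste(utils::head(missing_cols, 5), collapse = ", "))
  stray <- setdiff(mat_df$probe_id, probes$probe_id)
  lost <- setdiff(probes$probe_id, mat_df$probe_id)
  if (length(stray) || length(lost))
    .stopf("probe id mismatch between map and matrix; first offenders: %s",
           paste(utils::head(c(stray, lost), 5), collapse = ", "))
  probes$midpos <- floor((probes$start + probes$end) / 2)
  ord <- order(match(probes$chrom, .chrom_levels(probes$chrom)), probes$midpos)
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  values <- as.matrix(mat_df[match(probes$probe_id, mat_df$probe_id),
                             samples$sample_id, drop = FALSE])
  rownames(values) <- probes$probe_id
  miss_frac <- rowMeans(is.na(values))
  keep <- miss_frac <= max_missing_frac
  n_dropped <- sum(!keep)
  probes <- probes[keep, , drop = FALSE]
  values <- values[keep, , drop = FALSE]
  n_imputed <- 0L
  if (anyNA(values)) {
    for (ch in .chrom_levels(probes$chrom)) {
      idx <- which(probes$chrom == ch)
      for (j in seq_len(ncol(values))) {
        nas <- idx[is.na(values[idx, j])]
        if (length(nas)) {
          values[nas, j] <- stats::median(values[idx, j], na.rm = TRUE)
          n_imputed <- n_imputed + length(nas)
        }
      }
    }
  }
  if (anyNA(values)) .stopf("imputation failed: fully missing chromosome")
  class(probes) <- c("probe_map", "data.frame")
  message(sprintf("read_acgh: %d probes dropped (>%d%% missing), %d cells imputed",
                  n_dropped, round(100 * max_missing_frac), n_imputed))
  cohort <- acgh_cohort(probes, values, samples)
  attr(cohort, "load_report") <- list(n_dropped = n_dropped,
                                      n_imputed = n_imputed)
  cohort
}

#' Write an aCGH cohort as probe/matrix/sample-sheet TSVs
#'
#' @param cohort an `acgh_cohort`.
#' @param probe_path,matrix_path,samples_path output TSV paths.
#' @return invisibly, the cohort.
#' @export
write_acgh <- function(cohort, probe_path, matrix_path, samples_path) {
  stopifnot(inherits(cohort, "acgh_cohort"))
  pm <- cohort$map[, c("chrom", "start", "end", "probe_id")]
  utils::write.table(pm, probe_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mat_df <- data.frame(probe_id = cohort$map$probe_id,
                       cohort$values, check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.table(mat_df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$samples[, c("sample_id", "group", "platform")],
                     samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cohort)
}

#' Standardize each platform stratum to pooled mean 0, SD 1
#'
#' aCGH log2 ratios from FFPE-derived DNA are consistently wider-distributed
#' than those from fresh-frozen tissue, so cohorts mixing platforms are
#' rescaled per platform before any cross-platform comparison: all cells
#' (every probe of every sample on that platform) are pooled, centred and
#' scaled as one stratum. Scaling whole datasets rather than individual
#' tumors preserves between-tumor differences in aberration burden.
#' The map is affine per platform, hence idempotent.
#'
#' @param cohort an `acgh_cohort`.
#' @return the cohort with standardized values.
#' @export
zscale_platform <- function(cohort) {
  stopifnot(inherits(cohort, "acgh_cohort"))
  v <- cohort$values
  for (pf in unique(cohort$samples$platform)) {
    cols <- which(cohort$samples$platform == pf)
    if (length(cols) < 2L || nrow(v) < 2L)
      .stopf("platform %s needs >= 2 samples and >= 2 probes", pf)
    cells <- as.vector(v[, cols])
    s <- stats::sd(cells)
    if (s == 0) .stopf("platform %s has zero variance", pf)
    v[, cols] <- (v[, cols] - mean(cells)) / s
  }
  cohort$values <- v
  cohort
}

#' Merge two cohorts measured on the same probe map, deduplicating samples
#'
#' Tumors hybridized in both cohorts (e.g. the same tumor on FFPE and
#' fresh-frozen platforms) are kept once, from the side named by `keep`.
#'
#' @param a,b `acgh_cohort` objects with identical probe maps
#'   (same chrom and midpos sequence).
#' @param duplicates data frame (or 2-column matrix) with columns
#'   `id_a`, `id_b` pairing duplicate sample ids; `NULL` for none.
#' @param keep `"a"` or `"b"`: which side's copy of each duplicate survives.
#' @return merged `acgh_cohort` with `ncol(a) + ncol(b) - nrow(duplicates)`
#'   samples.
#' @export
merge_cohorts <- function(a, b, duplicates = NULL, keep = c("a", "b")) {
  keep <- match.arg(keep)
  stopifnot(inherits(a, "acgh_cohort"), inherits(b, "acgh_cohort"))
  if (!identical(a$map$chrom, b$map$chrom) ||
      !identical(a$map$midpos, b$map$midpos))
    .stopf("probe maps differ between cohorts")
  drop_a <- character(0); drop_b <- character(0)
  if (!is.null(duplicates) && NROW(duplicates) > 0) {
    duplicates <- as.data.frame(duplicates, stringsAsFactors = FALSE)
    names(duplicates)[1:2] <- c("id_a", "id_b")
    missing_a <- setdiff(duplicates$id_a, a$samples$sample_id)
    missing_b <- setdiff(duplicates$id_b, b$samples$sample_id)
    if (length(missing_a) || length(missing_b))
      .stopf("duplicate id(s) not found: %s",
             paste(c(missing_a, missing_b), collapse = ", "))
    if (keep == "a") drop_b <- duplicates$id_b else drop_a <- duplicates$id_a
  }
  keep_a <- !(a$samples$sample_id %in% drop_a)
  keep_b <- !(b$samples$sample_id %in% drop_b)
  acgh_cohort(a$map,
              cbind(a$values[, keep_a, drop = FALSE],
                    b$values[, keep_b, drop = FALSE]),
              rbind(a$samples[keep_a, , drop = FALSE],
                    b$samples[keep_b, , drop = FALSE]))
}

# ---- genomic region tables ----------------------------------------------

#' Build a genomic-region table
#'
#' Regions are reported in 1-based megabases with two decimals, the
#' convention of the aberration tables this package writes. Peaks may fall
#' slightly outside their region (an overlap between two comparisons can
#' exclude a peak); such peaks carry `peaks_outside = TRUE` and are rendered
#' with a trailing `*` in the TSV.
#'
#' @param chrom_region printed region label, e.g. `"16q"` or `"chr5"`.
#' @param start_mb,end_mb bounds in Mb, `start_mb < end_mb`.
#' @param direction `"gain"` or `"loss"` per region.
#' @param group label of the tumor group the region favors.
#' @param peaks_mb list of numeric vectors of peak positions (Mb).
#' @param peaks_outside list of logical vectors flagging peaks outside the
#'   region bounds.
#' @return a `region_table` data frame.
#' @export
region_table <- function(chrom_region, start_mb, end_mb, direction, group,
                         peaks_mb = NULL, peaks_outside = NULL) {
  n <- length(chrom_region)
  if (is.null(peaks_mb)) peaks_mb <- rep(list(numeric(0)), n)
  if (is.null(peaks_outside))
    peaks_outside <- lapply(peaks_mb, function(p) rep(FALSE, length(p)))
  bad <- which(start_mb >= end_mb)
  if (length(bad))
    .stopf("region %d (%s): start_mb must be < end_mb", bad[1],
           chrom_region[bad[1]])
  out <- data.frame(chrom_region = chrom_region,
                    chrom = .region_chrom(chrom_region),
                    start_mb = start_mb, end_mb = end_mb,
                    direction = direction, group = group,
                    stringsAsFactors = FALSE)
  out$peaks_mb <- peaks_mb
  out$peaks_outside <- peaks_outside
  class(out) <- c("region_table", "data.frame")
  out
}

# "16q" -> "chr16", "2p-1" -> "chr2", "chr5" stays
.region_chrom <- function(label) {
  if (length(label) == 0L) return(character(0))
  core <- sub("^chr", "", label)
  core <- sub("^([0-9]+|[XY]).*$", "\\1", core)
  paste0("chr", core)
}

.format_peaks <- function(p, outside) {
  if (length(p) == 0) return("")
  paste0(sprintf("%.2f", p), ifelse(outside, "*", ""), collapse = ";")
}

.parse_peaks <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list(mb = numeric(0), outside = logical(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  outside <- grepl("\\*$", parts)
  list(mb = as.numeric(sub("\\*$", "", parts)), outside = outside)
}

#' Read / write genomic-region TSVs
#'
#' The TSV schema is `chrom_region, start_mb, end_mb, direction, group,
#' peaks_mb` with peaks semicolon-separated, two-decimal Mb, and a trailing
#' `*` marking peaks outside the region. Round-trips are byte-stable.
#'
#' @param path TSV path.
#' @return for `read_regions`, a `region_table` (zero rows for an empty
#'   file).
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (file.size(path) == 0L)
    return(region_table(character(0), numeric(0), numeric(0), character(0),
                        character(0)))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(peaks_mb = "character"))
  if (nrow(df) == 0L)
    return(region_table(character(0), numeric(0), numeric(0), character(0),
                        character(0)))
  bad <- which(is.na(df$start_mb) | is.na(df$end_mb) |
                 is.na(df$chrom_region) | is.na(df$direction))
  if (length(bad))
    .stopf("region file: malformed row at line %d", bad[1] + 1L)
  bad <- which(df$start_mb >= df$end_mb)
  if (length(bad))
    .stopf("row %d (%s): start_mb >= end_mb", bad[1], df$chrom_region[bad[1]])
  peaks <- lapply(df$peaks_mb, .parse_peaks)
  region_table(df$chrom_region, df$start_mb, df$end_mb, df$direction,
               df$group,
               peaks_mb = lapply(peaks, `[[`, "mb"),
               peaks_outside = lapply(peaks, `[[`, "outside"))
}

#' @rdname read_regions
#' @param regions a `region_table`.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_table"))
  df <- data.frame(chrom_region = regions$chrom_region,
                   start_mb = sprintf("%.2f", regions$start_mb),
                   end_mb = sprintf("%.2f", regions$end_mb),
                   direction = regions$direction, group = regions$group,
                   peaks_mb = mapply(.format_peaks, regions$peaks_mb,
                                     regions$peaks_outside),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(regions)
}
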