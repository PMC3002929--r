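# shared internal helpers

# maximal runs of TRUE in a logical vector (NA counts as FALSE);
# returns a two-column matrix of start/end indices
.runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# close FALSE gaps of length <= gap between TRUE runs
.merge_gaps <- function(flag, gap) {
  flag[is.na(flag)] <- FALSE
  if (gap < 1L || !any(flag)) return(flag)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interior <- !r$values & r$lengths <= gap &
    seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
  for (i in which(interior)) flag[starts[i]:ends[i]] <- TRUE
  flag
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# chromosome labels in order of first appearance
.chrom_levels <- function(chrom) unique(as.character(chrom))
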