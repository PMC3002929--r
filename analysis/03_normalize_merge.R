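#!/usr/bin/env Rscript
# Stage 3: cross-platform normalization and cohort merging.
#
# The FFPE-derived log2 ratios are consistently wider-distributed than the
# fresh-frozen ones, so each platform's dataset is standardized to pooled
# mean 0 / SD 1 before any cross-platform comparison. The six tumors
# measured on both platforms are then collapsed to a single copy, kept from
# the FFPE (luminal-J) side.
#
# Usage: Rscript analysis/03_normalize_merge.R

suppressMessages(library(cnacompare))
in_dir <- "results/synthetic"
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

read_side <- function(side) read_acgh(
  file.path(in_dir, paste0(side, "_probes.tsv")),
  file.path(in_dir, paste0(side, "_matrix.tsv")),
  file.path(in_dir, paste0(side, "_samples.tsv")))
ffpe <- read_side("ffpe")
frozen <- read_side("frozen")

sd_of <- function(cohort) sd(as.vector(cohort$values))
message(sprintf("pooled SD before scaling: FFPE %.3f, frozen %.3f",
                sd_of(ffpe), sd_of(frozen)))
ffpe <- zscale_platform(ffpe)
frozen <- zscale_platform(frozen)
message(sprintf("pooled SD after scaling:  FFPE %.3f, frozen %.3f",
                sd_of(ffpe), sd_of(frozen)))

dups <- read.delim(file.path(in_dir, "duplicates.tsv"))
merged <- merge_cohorts(ffpe, frozen, dups, keep = "a")
message(sprintf("merged cohort: %d tumors (%d + %d - %d duplicates)",
                ncol(merged$values), ncol(ffpe$values),
                ncol(frozen$values), nrow(dups)))
print(table(merged$samples$group))

write_acgh(merged,
           file.path(out_dir, "probes.tsv"),
           file.path(out_dir, "matrix.tsv"),
           file.path(out_dir, "samples.tsv"))
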