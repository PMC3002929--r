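#!/usr/bin/env Rscript
# Stage 1: simulate the study-style synthetic data.
#
# Two aCGH cohorts on a ~1 Mb BAC-style platform over hg18 autosomes + X:
#   - FFPE cohort:   27 BRCA1-mutated + 17 luminal-J tumors (scale 1.5)
#   - frozen cohort: 21 basal-like (BLBC) + 31 luminal-H tumors (scale 1.0)
# Six luminal-J tumors are additionally re-measured on the frozen platform,
# emulating the six tumors shared between the two published cohorts.
# Recurrent CNAs follow the packaged differential-region table: basal-type
# regions are frequent in BRCA1/BLBC tumors, luminal-type regions in the
# luminal groups. A TP53 mutation table with group-specific class
# frequencies is simulated alongside.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages(library(cnacompare))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 20260922L
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

map <- make_probe_map(hg18_chrom_lengths(), spacing_bp = 1e6,
                      jitter_bp = 2e5, seed = seed)
message(sprintf("probe map: %d probes on %d chromosomes",
                nrow(map), length(unique(map$chrom))))

regs <- read_regions(system.file("extdata", "table2_regions.tsv",
                                 package = "cnacompare"))
segment_for <- function(i) {
  basal <- regs$group[i] != "luminal"
  cna_segment(regs$chrom[i], regs$start_mb[i] * 1e6, regs$end_mb[i] * 1e6,
              regs$direction[i],
              amplitude_mean = if (regs$direction[i] == "gain") 0.5 else -0.5,
              amplitude_sd = 0.1,
              penetrance = if (basal)
                c(BRCA1 = 0.6, `luminal-J` = 0.1, BLBC = 0.6,
                  `luminal-H` = 0.1)
              else
                c(BRCA1 = 0.1, `luminal-J` = 0.7, BLBC = 0.1,
                  `luminal-H` = 0.7),
              id = sprintf("%s_%s_%02d", regs$chrom_region[i],
                           regs$direction[i], i))
}
segments <- lapply(seq_len(nrow(regs)), segment_for)

spec <- cohort_spec(
  n_per_group = c(BRCA1 = 27, `luminal-J` = 17, BLBC = 21, `luminal-H` = 31),
  segments = segments, probe_noise_sd = 0.15,
  tumor_fraction_range = c(0.3, 0.9),
  platform_by_group = c(BRCA1 = "FFPE", `luminal-J` = "FFPE",
                        BLBC = "frozen", `luminal-H` = "frozen"),
  platform_scale = c(FFPE = 1.5, frozen = 1.0), seed = seed)
sim <- simulate_cohort(map, spec)
print(sim$cohort)

## split by platform and re-measure six luminal-J tumors on frozen
is_ffpe <- sim$cohort$samples$platform == "FFPE"
subcohort <- function(keep) acgh_cohort(map,
  sim$cohort$values[, keep, drop = FALSE],
  sim$cohort$samples[keep, , drop = FALSE])
ffpe <- subcohort(is_ffpe)
frozen <- subcohort(!is_ffpe)

set.seed(seed + 1L)
dup_ids <- sim$cohort$samples$sample_id[sim$cohort$samples$group ==
                                          "luminal-J"][1:6]
dup_vals <- sim$cohort$values[, dup_ids, drop = FALSE] / 1.5 +
  matrix(rnorm(nrow(map) * 6, 0, 0.05), nrow(map)) # fresh frozen re-assay
colnames(dup_vals) <- paste0(dup_ids, "_ff")
frozen <- acgh_cohort(map, cbind(frozen$values, dup_vals),
                      rbind(frozen$samples,
                            data.frame(sample_id = colnames(dup_vals),
                                       group = "luminal-H",
                                       platform = "frozen")))
write.table(data.frame(id_a = dup_ids, id_b = paste0(dup_ids, "_ff")),
            file.path(out_dir, "duplicates.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

for (side in c("ffpe", "frozen")) {
  cohort <- if (side == "ffpe") ffpe else frozen
  write_acgh(cohort,
             file.path(out_dir, paste0(side, "_probes.tsv")),
             file.path(out_dir, paste0(side, "_matrix.tsv")),
             file.path(out_dir, paste0(side, "_samples.tsv")))
}
write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## TP53 mutation table with class frequencies in the style of the study
prof <- mutation_profile_spec(list(
  BRCA1 = c(wildtype = 0.10, complex = 0.52, deleterious_missense = 0.28,
            tolerated_missense = 0.10),
  BLBC = c(wildtype = 0.05, complex = 0.57, deleterious_missense = 0.28,
           tolerated_missense = 0.10),
  `luminal-J` = c(wildtype = 0.54, complex = 0.08,
                  deleterious_missense = 0.23, tolerated_missense = 0.15),
  `luminal-H` = c(wildtype = 0.74, complex = 0.07,
                  deleterious_missense = 0.13, tolerated_missense = 0.06)),
  seed = seed)
mut <- simulate_mutation_table(prof, c(BRCA1 = 27, `luminal-J` = 17,
                                       BLBC = 21, `luminal-H` = 31))
write.table(mut, file.path(out_dir, "mutations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("wrote synthetic cohorts (%d + %d tumors) and %d mutation rows to %s",
                ncol(ffpe$values), ncol(frozen$values), nrow(mut), out_dir))
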