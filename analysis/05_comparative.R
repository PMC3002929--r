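#!/usr/bin/env Rscript
# Stage 5: differential CNAs between tumor groups.
#
# Per-tumor smoothed profiles feed a per-position SNR between the groups of
# each comparison; 6000 class-label permutations set the FDR 0.05 threshold
# and maximal supra-threshold runs become differential regions with peak
# positions. The two basal-vs-luminal comparisons are intersected into a
# table of overlapping differential gains and losses, and the luminal-J vs
# luminal-H comparison serves as the merge control (no regions expected).
#
# Usage: Rscript analysis/05_comparative.R [seed]

suppressMessages(library(cnacompare))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 20260922L
dir.create("results/comparative", recursive = TRUE, showWarnings = FALSE)

cohort <- read_acgh("results/cohort/probes.tsv", "results/cohort/matrix.tsv",
                    "results/cohort/samples.tsv")
ks <- kse_matrix(cohort, kernel_spec(20), 1e6)
labels <- cohort$samples$group
labels[labels %in% c("luminal-J", "luminal-H")] <- "luminal"

comparisons <- list(c("BRCA1", "BLBC"), c("BRCA1", "luminal"),
                    c("BLBC", "luminal"))
region_sets <- list()
for (i in seq_along(comparisons)) {
  cmp <- comparisons[[i]]
  thr <- permutation_fdr_threshold(ks, cmp[1], cmp[2],
                                   permutation_config(n_perm = 6000,
                                                      fdr = 0.05,
                                                      seed = seed + i),
                                   labels = labels)
  regs <- call_differential_regions(thr$snr, thr)
  tag <- paste0(cmp[1], "_vs_", cmp[2])
  snr_df <- data.frame(chrom = thr$snr$grid$chrom, pos_bp = thr$snr$grid$pos,
                       snr = thr$snr$snr)
  write.table(snr_df, sprintf("results/comparative/snr_%s.tsv", tag),
              sep = "\t", quote = FALSE, row.names = FALSE)
  out <- regs; out$favored_group <- NULL; out$threshold_used <- NULL
  write_regions(out, sprintf("results/comparative/regions_%s.tsv", tag))
  region_sets[[tag]] <- regs
  message(sprintf("%s: t_pos %.3g, t_neg %.3g, %d region(s)",
                  tag, thr$t_pos, thr$t_neg, nrow(regs)))
}

# merge control: the two luminal groups should not differ
thr_ctrl <- permutation_fdr_threshold(ks, "luminal-J", "luminal-H",
                                      permutation_config(n_perm = 6000,
                                                         fdr = 0.05,
                                                         seed = seed + 9))
ctrl <- call_differential_regions(thr_ctrl$snr, thr_ctrl)
message(sprintf("luminal-J vs luminal-H control: %d region(s)", nrow(ctrl)))

# overlapping differential regions of the two basal-vs-luminal comparisons
ov <- overlap_regions(region_sets[["BRCA1_vs_luminal"]],
                      region_sets[["BLBC_vs_luminal"]])
write_regions(ov, "results/comparative/overlap_basal_vs_luminal.tsv")
message(sprintf("overlapping basal-vs-luminal regions: %d", nrow(ov)))
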