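#!/usr/bin/env Rscript
# Stage 7: unsupervised clustering on region-mean smoothed signal.
#
# For every tumor the mean KSE value inside each differential region of the
# packaged region table is computed; tumors and regions are hierarchically
# clustered (Pearson correlation, complete linkage), the tumor tree is cut
# into two branches and the branch composition per tumor group is reported
# -- the synthetic analog of the published two-branch basal/luminal split.
#
# Usage: Rscript analysis/07_cluster.R

suppressMessages(library(cnacompare))
dir.create("results/cluster", recursive = TRUE, showWarnings = FALSE)

cohort <- read_acgh("results/cohort/probes.tsv", "results/cohort/matrix.tsv",
                    "results/cohort/samples.tsv")
regs <- read_regions(system.file("extdata", "table2_regions.tsv",
                                 package = "cnacompare"))
ks <- kse_matrix(cohort, kernel_spec(20), 2.5e5)
feat <- region_mean_matrix(ks, regs)
feat <- feat[, colSums(is.na(feat)) == 0, drop = FALSE]
write.table(data.frame(sample_id = rownames(feat), feat, check.names = FALSE),
            "results/cluster/region_means.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

res <- cluster_tumors(feat, n_branches = 2, groups = cohort$samples$group)
export_newick(res, "results/cluster/tumors.nwk")
if (!is.null(res$region_hclust))
  export_newick(res, "results/cluster/regions.nwk", what = "regions")
comp <- as.data.frame.matrix(res$composition)
write.table(cbind(group = rownames(comp), comp),
            "results/cluster/branch_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("branch composition (tumors per group):")
print(res$composition)
basal <- c("BRCA1", "BLBC")
b_basal <- res$composition[basal, , drop = FALSE]
main_branch <- which.max(colSums(b_basal))
message(sprintf("basal-type tumors in their majority branch: %d / %d",
                sum(b_basal[, main_branch]), sum(b_basal)))
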