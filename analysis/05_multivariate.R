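#!/usr/bin/env Rscript
# Stage 5: ordination, PERMANOVA and transcriptome plasticity.
#
# Per species and origin bin: variance-stabilized transform, PCA over the
# most variable genes, one-way PERMANOVA on treatment and on treatment x
# timepoint cells, plasticity distances to the 4 h control centroid, and
# ANOVA with Tukey HSD across treatment x timepoint groups. Treatment
# effects are judged on the time-matched heated-vs-control contrasts
# (the reference group's own distances are deflated by centroid fitting).

suppressMessages(library(coralheat))
dir.create("results", showWarnings = FALSE)

counts <- read_count_matrix("results/bundle/counts.tsv")
meta <- read_sample_metadata("results/bundle/metadata.tsv")
bins <- read.delim("results/bin_assignments.tsv")
origin <- setNames(bins$bin, bins$gene_id)

rows <- list(); dists <- list()
perm_seed <- 20260930L
for (sp in unique(meta$species)) {
  msub <- meta[meta$species == sp, ]
  for (bn in c("host", "symbiont")) {
    g <- names(origin)[origin == bn]
    sub <- counts[g, msub$sample_id]
    sub <- sub[rowSums(sub) > 0, ]
    v <- vst_transform(sub)
    pc <- pca_samples(v)
    perm_seed <- perm_seed + 1
    pm <- permanova(dist(t(v)), msub$treatment, n_perm = 999,
                    seed = perm_seed)
    pl <- plasticity_analysis(v, msub)
    tk <- pl$tukey
    tm <- tk[(tk$group1 == "heated_24h" & tk$group2 == "control_24h") |
               (tk$group2 == "heated_24h" & tk$group1 == "control_24h"), ]
    rows[[paste(sp, bn)]] <- data.frame(
      species = sp, origin = bn,
      pc1_pct = round(100 * pc$var_explained[1], 1),
      pc2_pct = round(100 * pc$var_explained[2], 1),
      permanova_f = round(pm$pseudo_f, 2), permanova_p = pm$p,
      tukey_heat24_vs_ctl24_p = signif(tm$p_adj, 3))
    dists[[paste(sp, bn)]] <- cbind(species = sp, origin = bn, pl$distances)
  }
}
summ <- do.call(rbind, rows)
write.table(summ, "results/multivariate_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, dists), "results/plasticity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Per species x bin (PERMANOVA on treatment, 999 permutations;",
    "Tukey on the time-matched 24 h contrast):\n")
print(summ, row.names = FALSE)
cat("\nPlanted pattern: the sensitive species' host bin carries the",
    "treatment signal (large F and a near-zero 24 h contrast p);",
    "occasional small PERMANOVA p-values in the other species are",
    "permutation-level false positives at the nominal rate.\n")
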