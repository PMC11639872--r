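#!/usr/bin/env Rscript
# Stage 2: host/symbiont transcript binning.
#
# Assigns every gene to the host (best hit to Cnidaria) or symbiont
# (Dinophyceae) bin, summarizes which Symbiodiniaceae reference genomes
# the symbiont transcripts resemble most, reports per-bin GC content, and
# checks recovery against the planted origins.

suppressMessages(library(coralheat))
dir.create("results", showWarnings = FALSE)

counts <- read_count_matrix("results/bundle/counts.tsv")
truth <- read.delim("results/bundle/truth.tsv")
hits <- read_hit_table("results/bundle/hits.tsv")
sym_hits <- read_hit_table("results/bundle/sym_hits.tsv")

bins <- assign_bins(rownames(counts), hits)
write.table(bins, "results/bin_assignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tab <- table(bins$bin)
acc <- mean(bins$bin == truth$origin[match(bins$gene_id, truth$gene_id)])
cat("Bins:", paste(names(tab), tab, collapse = ", "), "\n")
cat("Agreement with planted origin:", sprintf("%.1f%%", 100 * acc),
    "(misses are the simulated best-hit error rate plus dropped genes)\n")

aff <- affiliation_summary(bins, sym_hits)
write.table(aff, "results/symbiont_affiliation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Symbiont affiliation (fraction of symbiont bin):\n")
print(aff, row.names = FALSE)

gc <- gc_content("results/bundle/sequences.fasta", bins)
cat(sprintf("GC content: host %.1f%%, symbiont %.1f%%\n",
            gc[["host"]], gc[["symbiont"]]))
write.table(data.frame(bin = names(gc), gc_percent = round(gc, 2)),
            "results/gc_content.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
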