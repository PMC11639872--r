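# coralheat

Comparative thermal-stress transcriptomics for coral holobionts.

Coral RNA-seq libraries mix transcripts of the cnidarian host with those
of its dinoflagellate symbionts, and coral species differ sharply in how
they respond to acute heat: tolerant species keep stress response genes
(SRGs) constitutively expressed ("frontloaded"), while sensitive species
induce them massively from a low baseline shortly before bleaching.
`coralheat` is an R package plus a numbered analysis workflow for the
complete comparison across several species sampled under a control
(28 °C) vs heated (32 °C) design at 4 h and 24 h:

* representative-isoform selection for RSEM-quantified de novo assemblies;
* host/symbiont transcript binning from best protein hits (Cnidaria vs
  Dinophyceae), Symbiodiniaceae affiliation summaries, per-bin GC content;
* domain-based SRG cataloguing with cross-group abundance association;
* differential expression by a two-group exact conditional
  negative-binomial test at strict thresholds;
* PCA, one-way PERMANOVA, and a transcriptome plasticity distance with
  ANOVA + Tukey HSD;
* frontloading classification of SRGs with family-level enrichment;
* a synthetic-data generator that plants known structure (origin, DE,
  frontloading, affiliation mixtures, GC) so every stage is verifiable
  against ground truth without any download.

It is written for analysts working on coral (or other host–symbiont)
stress transcriptomes who want each step of this standard design as a
tested, seed-reproducible function rather than an ad hoc script.

## The statistics at the core

**Differential expression.** Counts are modelled NB with variance
`μ + φμ²` and a single common dispersion `φ`, estimated by maximizing the
conditional NB log-likelihood given per-group totals on depth-equalized
pseudo-counts. For each gene the test conditions on the total
`z = z_A + z_B` over equalized libraries; under equal means,

    P(z_A = x | z) ∝ Γ(x + n_A r)/x! · Γ(z−x + n_B r)/(z−x)!,  r = 1/φ,

with the binomial split as the `φ = 0` limit. Two-sided p-values double
the smaller inclusive tail (capped at 1), FDR is Benjamini–Hochberg, and
a gene is called DE at `|log2FC| ≥ 4` and `FDR < 0.05`, with fold changes
`log2((m_B + 0.5)/(m_A + 0.5))` on TMM-scaled group means.

**Plasticity.** Each sample's Euclidean distance, in
`log2(count/size_factor + 1)` space, to the centroid of the 4 h control
group; treatment effects are judged on time-matched heated-vs-control
Tukey contrasts (the reference group's own distances are deflated by
centroid fitting, so the omnibus ANOVA is not null-calibrated — see the
methods vignette).

**Frontloading.** An SRG is frontloaded iff its basal expression (mean
CPM over all control libraries) strictly exceeds the transcriptome median
and `|log2FC| < 2` (strictly) at both heated timepoints; low-basal SRGs
significantly upregulated under heat form the contrasting responsive
class. Family enrichment is one-sided hypergeometric, BH-adjusted.

## Worked example

```r
library(coralheat)

cfg <- sim_config(seed = 7, n_species = 2,
                  n_genes_host = 800, n_genes_symbiont = 400)
sim <- simulate_counts(cfg)            # 1200 genes x 24 libraries

hits <- simulate_hits(sim$truth, cfg)
bins <- assign_bins(rownames(sim$counts), hits$nr)
table(bins$bin)
#>  dropped     host symbiont
#>       18      788      394

sp   <- cfg$responsive_species         # the thermally sensitive species
msub <- sim$meta[sim$meta$species == sp, ]
de   <- run_de(sim$counts[, msub$sample_id], msub)
round(de$dispersion, 3)
#> [1] 0.1
summarize_deg_counts(de$results, bins = setNames(bins$bin, bins$gene_id))
#>   timepoint_h   origin n_up n_down
#> 5           4     host   24      8
#> 6           4 symbiont    0      0
#> 2          24     host   20      9
#> 3          24 symbiont    0      0   (dropped-bin rows omitted here)

catalog <- assign_srg_families(simulate_domains(sim$truth, cfg),
                               cfg$srg_families)
host  <- bins$gene_id[bins$bin == "host"]
calls <- frontloading_calls(cpm(sim$counts[, msub$sample_id])[host, ],
                            msub, de$results, catalog)
sum(calls$frontloaded); sum(calls$low_basal_responsive)
#> [1] 45
#> [1] 21
```

The 24 libraries carry a planted 16-fold heat response in the sensitive
species only: the DE table shows host-dominated up-regulation there (24
up at 4 h), the estimated common dispersion recovers the simulated
φ = 0.1, and 45 of 79 catalogued SRGs are called frontloaded — at 0.956
precision against the planted labels.

The numbered scripts under `analysis/` run the same workflow at full
bundle scale (4 species × 12 libraries, 3,500 genes) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R         # synthetic study bundle + truth
Rscript analysis/02_binning.R          # host/symbiont bins, affiliation, GC
Rscript analysis/03_srg_catalog.R      # SRG families and abundances
Rscript analysis/04_differential_expression.R
Rscript analysis/05_multivariate.R     # PCA, PERMANOVA, plasticity
Rscript analysis/06_frontloading.R     # frontloaded vs responsive SRGs
```

`run_pipeline(pipeline_config(...))` performs the same stages end-to-end
from one config with a manifest and per-file checksums.

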