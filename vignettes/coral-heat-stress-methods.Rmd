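---
title: "Methods: comparative thermal-stress transcriptomics for coral holobionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative thermal-stress transcriptomics for coral holobionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Reef-building corals are holobionts: RNA extracted from a coral fragment
mixes transcripts of the cnidarian host with those of its dinoflagellate
symbionts (family Symbiodiniaceae). Species differ strongly in how they
respond to acute heat: thermally tolerant corals tend to keep a battery of
stress response genes (SRGs) — chaperones, antioxidants, efflux pumps,
immune and wound-healing factors — constitutively expressed
("frontloaded"), while sensitive species hold the same genes at low basal
levels and induce them massively once stressed, a strategy that precedes
bleaching when the response cannot be sustained.

`coralheat` implements the complete comparative analysis for this kind of
experiment — typically several sympatric species, a handful of colonies
each, a control (28 °C) and a heated (32 °C) treatment sampled at 4 h and
24 h — from gene-level count matrices and annotation tables onward:

1. **transcript_filter** — representative-isoform selection for de novo
   assemblies quantified with RSEM (drop zero-IsoPct isoforms, keep the
   isoform with the highest combined IsoPct, ties by length, then id;
   retain coding sequences).
2. **binning** — host/symbiont separation by best protein hit: a
   transcript whose best hit (e-value ≤ 1e−5; ranked by e-value, then
   percent identity, then bitscore) is to Cnidaria is host, to
   Dinophyceae is symbiont, anything else is dropped. Symbiont transcripts
   are further affiliated to Symbiodiniaceae reference genomes, and
   per-bin GC content is summarized (host ~42%, symbiont ~55% is the
   expected contrast).
3. **srg_catalog** — SRGs identified by characteristic protein domains
   (a gene belongs to a family iff it carries a defining domain at
   e ≤ 1e−5; multi-family genes resolve to the first family in the
   definition file). Family abundances are taken relative to the species'
   peptide total and compared across taxonomic groups by OLS on
   log-transformed abundances (half-minimum pseudocount) with BH
   correction — a transparent stand-in for heavier multivariable
   association frameworks, screened at the conventional q < 0.25.
4. **expression / diffexpr** — CPM and TPM, the `>2 CPM in ≥2 libraries`
   filter (strict inequality on the CPM threshold), TMM normalization
   factors, median-of-ratios size factors, a depth-corrected log2
   transform, and a two-group exact conditional NB test at the strict
   thresholds |log2FC| ≥ 4 and FDR < 0.05.
5. **multivariate** — PCA over the 500 most variable genes, one-way
   PERMANOVA with permutation p-values, and the transcriptome plasticity
   distance with ANOVA + Tukey HSD.
6. **frontloading** — the classification at the heart of the comparison:
   an SRG is *frontloaded* when its basal expression (mean CPM over all
   control libraries) strictly exceeds the transcriptome median and its
   response stays small (|log2FC| < 2, strictly, at both heated
   timepoints); low-basal SRGs that are significantly upregulated form
   the contrasting *responsive* class. Family-level enrichment of
   frontloaded genes uses a one-sided hypergeometric test, BH-adjusted.

## The differential expression model

Counts are modelled negative-binomially with variance `μ + φμ²` and a
single common dispersion φ shared across genes. φ is estimated by
maximizing the sum over genes of the conditional NB log-likelihood given
per-group totals (qCML style), on pseudo-counts rescaled to a common
effective depth; the estimate is floored at 0, and data with identical
replicates yield exactly 0.

For a gene with group totals `z_A + z_B = z` on equalized libraries, the
test conditions on `z`: under equal means the conditional law of `z_A` is

```
P(z_A = x | z) ∝ Γ(x + n_A r) / x! · Γ(z − x + n_B r) / (z − x)!,   r = 1/φ,
```

the NB analogue of the binomial split (and exactly the binomial split
when φ = 0). Two-sided p-values double the smaller (inclusive) tail,
capped at 1 — deterministic and conservative for skewed conditionals. The
test suite verifies this pmf against independent enumeration via
`dnbinom` for every instance with totals ≤ 30 (tolerance 1e−10), checks
type-I error calibration on null simulations, and cross-checks dispersion
and TMM against edgeR.

Library equalization multiplies counts by `target/effective size`
(effective size = library size × TMM factor; target = their geometric
mean) and rounds half-to-even. This is an approximation to full
quantile-to-quantile NB adjustment; the enumeration-oracle and
calibration tests pin its behaviour where it matters. Reported fold
changes are `log2((m_B + 0.5)/(m_A + 0.5))` on TMM-scaled group mean
counts; the 0.5 prior keeps zero-containing means finite and the
statistic antisymmetric.

**Power at the threshold.** A design of 3 + 3 replicates at φ = 0.1 gives
the significance part of the rule essentially full power against a
16-fold change (≥ 99%). The joint rule additionally requires the
*estimated* |log2FC| to reach 4; for a gene whose true effect sits
exactly at 4 the estimate is nearly symmetric around the threshold
(sd ≈ 0.37), so the joint rule retains only about half of such genes.
This is a property of thresholding an unbiased estimate at the true
effect size, not of the implementation; genes with effects comfortably
above the threshold are kept with high probability. The acceptance
report states both detection rates.

## Ordination, PERMANOVA and plasticity

Ordination and distances use `log2(count/size_factor + 1)` with
median-of-ratios size factors — a deliberately simple variance-stabilizing,
depth-corrected transform standing in for shrinkage-based regularized
logs; it preserves the properties the downstream statistics need
(monotone, depth-corrected, log scale) and is stated as such wherever it
is used.

PERMANOVA uses Anderson's pseudo-F from total and within-group sums of
squared Euclidean distances, with free label permutations and
`p = (1 + #[F* ≥ F]) / (n_perm + 1)` (never exactly 0); an exhaustive
mode enumerates all label permutations for small n and is tested against
an independent Gower-trace enumeration oracle, and the statistic is
cross-checked against `vegan::adonis2`. The operation is one-way; the
pipeline applies it per species to treatment groups and to
treatment × timepoint cells rather than fitting a multi-factor
decomposition, because the comparisons of interest here are single
contrasts per species and one-way permutation inference is exact in that
setting.

Transcriptome plasticity is each sample's Euclidean distance to the
centroid of the 4 h control group, in the full transformed gene space by
default (a first-two-PCs option exists, since a projection is a
legitimate variant of "transcriptome profile"). One caveat the package's
outputs respect: the reference samples' own distances are deflated
because the centroid is fitted to them (expected squared distance
`(n−1)/n · pσ²` versus `(n+1)/n · pσ²` for other groups), so the overall
ANOVA across groups is biased away from its null even for inert data.
Treatment effects are therefore judged on the *time-matched*
heated-vs-control Tukey contrasts (e.g. heated 24 h vs control 24 h),
which are exchangeable under the null and empirically hold the nominal
family-wise rate in the package's null simulations.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the pipeline targets:
4 species × (3 colonies × 2 treatments × 2 timepoints) = 48 libraries;
2,000 host + 1,500 symbiont genes; NB counts with common φ = 0.1 (a
typical bulk-RNA biological dispersion); baseline log2 means ~N(5, 2) so
the expression distribution has a meaningful median; log-normal library
sizes around 1e6 (sdlog 0.15) so CPM ≠ raw counts and normalization is
actually exercised; planted DE at |log2FC| = 4 (half up, half down) in
5% of host genes; 10% of host genes are SRGs, of which 55% are planted
frontloaded (baseline ≥ 0.5 log2 units above the population centre,
planted fold change 0) and 40% planted responsive (baseline ≥ 0.5 below,
planted log2FC = 4 under heat) — proportions chosen to mirror the
published contrast between tolerant corals (roughly 53–64% of SRGs
frontloaded) and a sensitive one (about half of SRGs below the
transcriptome median). Only one species — the last, by default — expresses
the planted effects, emulating the one thermally sensitive species in a
set of sympatric corals; the margin of ±0.5 log2 units between planted
basal classes and the population centre is what makes frontloading
recovery a sharp test (basal-mean noise at 6 control libraries is ≈ 0.13
log2 units).

Mean structure: `μ_gs = 2^(b_g + δ_gs) · L_s / Σ_g 2^(b_g)`, with δ the
planted log2 effect in heated samples of the responsive species. Effects
are planted directly in μ (library totals absorb the extra mass), so
planted fold changes are exact and composition bias is realistic enough
for TMM to have work to do.

Companion generators emit: best-hit tables whose top hit carries the
true origin's taxon with configurable accuracy (default 0.98, emulating
annotation error) plus decoy hits at worse e-values; a
Symbiodiniaceae-affiliation table drawn from a configurable reference
mixture (default dominated by *Durusdinium trenchii*, the profile of the
sensitive pocilloporid the design emulates); domain tables in which every
planted SRG carries one defining domain of its family and other genes
carry decoys; and random sequences hitting origin-specific GC targets
(host 0.42, symbiont 0.55). Everything is deterministic given the seed.

What the generator does **not** emulate — hence what green tests do not
show about real data: colony (genotype) random effects and any
within-treatment correlation structure; per-gene dispersion trends;
GC/length biases in quantification; assembly artefacts (chimeras,
fragmented ORFs); genuinely new gene content differing across species
(all species share one simulated gene set, which also makes the
cross-species SRG abundance comparison on the default bundle a planned
null); and partial, graded frontloading rather than a clean planted
dichotomy.

## Numerical choices and degenerate inputs

* Counts must be integers; RSEM expected counts are rounded half-to-even
  on ingest with a warning.
* Strict inequalities wherever the rule is stated strictly: the CPM
  filter (> 2), the FDR cut (< 0.05), both frontloading thresholds.
* Basal expression for frontloading uses CPM by default (`tpm`/`vst` are
  switchable), pooling both timepoints' controls; the stability bound is
  applied at both heated timepoints by default (`either` is a flag).
* Tie-breaks are total and deterministic: isoforms by IsoPct → length →
  id; hits by e-value → identity → bitscore → subject id; multi-family
  genes by family file order. All are logged.
* Dispersion: optimized on log φ over [1e−6, 5] with an explicit boundary
  comparison at φ ≈ 0 so Poisson-like data return 0 rather than 1e−6.
* Degenerate inputs error early and name the offender: empty count
  files, zero libraries, all-zero samples, missing genes/lengths, empty
  reference groups, single-group PERMANOVA; all-identical ANOVA inputs
  return p = 1 with a flag rather than NaN.
* PERMANOVA permutation comparisons use a relative tolerance of 1e−9 on
  F so the identity permutation always counts as ≥ the observed value.

## Problem sizes

The shipped analysis scripts and verification suite run at deliberately
desk-friendly sizes — 3,500 genes × 48 libraries for the full bundle,
2,000-gene single-species simulations (20 seeds) for calibration checks,
300-gene two-species simulations (50 seeds) for the plasticity scenario,
200 runs of 199 permutations for permutation-uniformity — chosen so the
whole pipeline reruns in minutes on one core while leaving every
statistical property measurable. All thresholds (CPM filter, |log2FC| ≥ 4,
FDR < 0.05, frontloading bound 2) are config fields with those defaults.

## Known limitations

* The shipped SRG family table is a small synthetic placeholder spanning
  the chemical/pathogen/wounding categories; real analyses must supply a
  curated domain catalog.
* The common-dispersion model has no tagwise/trended shrinkage; genes
  with atypical dispersion are tested at the shared φ.
* The exact test's depth equalization rounds pseudo-counts; at very low
  counts this discreteness makes p-values conservative (verified, not
  harmful, in the calibration tests).
* One-way PERMANOVA only; no multi-factor partitioning, no strata, and
  Euclidean distance only.
* GO/pathway enrichment, network reconstruction, orthogroup inference
  and read-level processing are out of scope: counts, hits, domains and
  orthogroup tables are inputs, not products.
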