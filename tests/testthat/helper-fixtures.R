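# Shared fixtures built in code.

# A small two-species bundle: sp01 tolerant (no planted effects expressed),
# sp02 responsive.
small_sim <- function(seed = 42, n_genes_host = 600, n_genes_symbiont = 300,
                      ...) {
  cfg <- sim_config(seed = seed, n_species = 2, n_genes_host = n_genes_host,
                    n_genes_symbiont = n_genes_symbiont, ...)
  c(list(cfg = cfg), simulate_counts(cfg))
}

toy_cpm_matrix <- function() {
  read_matrix_tsv(system.file("extdata", "toy_cpm.tsv",
                              package = "coralheat", mustWork = TRUE))
}

# Minimal count matrix with named dims.
mat <- function(x, nrow, genes = NULL, samples = NULL) {
  m <- matrix(x, nrow = nrow)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Metadata for a single species 2x2 design with r replicates per cell.
design_meta <- function(species = "spX", r = 3) {
  meta <- expand.grid(colony = seq_len(r), treatment = c("control", "heated"),
                      timepoint_h = c(4L, 24L), stringsAsFactors = FALSE)
  meta$species <- species
  meta$sample_id <- sprintf("%s_%s_%02dh_c%d", species, meta$treatment,
                            meta$timepoint_h, meta$colony)
  meta$colony <- as.character(meta$colony)
  meta[, c("sample_id", "species", "colony", "treatment", "timepoint_h")]
}
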