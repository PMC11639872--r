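# Synthetic holobiont fixture generator. Counts follow the negative
# binomial model assumed by the exact test (variance = mu + phi * mu^2),
# with known (planted) host/symbiont origin, DE status, SRG family and
# frontloading labels recorded in a ground-truth table for recovery tests.

#' Default SRG family definitions shipped with the package
#'
#' A small synthetic placeholder catalog covering the chemical, pathogen and
#' wounding stress categories; see `inst/extdata/srg_families.tsv` for the
#' caveats. Real analyses should supply their own table.
#'
#' @return SRG family definition data.frame.
#' @export
default_srg_families <- function() {
  read_srg_families(system.file("extdata", "srg_families.tsv",
                                package = "coralheat", mustWork = TRUE))
}

#' Build a validated simulation configuration
#'
#' Defaults mirror the experimental design the pipeline targets: 4 sympatric
#' coral species, 3 colonies (biological replicates) x 2 treatments
#' (28 degC control / 32 degC heated) x 2 exposure timepoints (4 h, 24 h)
#' = 12 libraries per species, mixed host/symbiont transcript origin,
#' planted differential expression at |log2FC| = 4, and planted
#' "frontloaded" (high basal expression, stable under heat) versus
#' "responsive" (low basal expression, strongly induced) SRG sets. One
#' species (the last, by default) is the thermally sensitive responder in
#' which planted DE and responsive-SRG effects are expressed; the others
#' are tolerant and transcriptionally stable.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_species Number of species (libraries are 12 per species).
#' @param n_genes_host,n_genes_symbiont Genes of each origin.
#' @param replicates_per_cell Colonies per treatment x timepoint cell.
#' @param timepoints_h Exposure durations in hours.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); a single
#'   common value, >= 0 (0 gives Poisson counts).
#' @param mean_log_expression,sd_log_expression Normal distribution of
#'   baseline log2 mean expression across genes.
#' @param de_fraction Fraction of host genes planted as differentially
#'   expressed (half up, half down) in the responsive species.
#' @param de_log2fc Planted effect size on the log2 scale.
#' @param de_timepoints_h Timepoints at which planted effects act.
#' @param srg_fraction Fraction of host genes that are SRGs.
#' @param frontloaded_fraction,responsive_fraction Fractions of SRGs planted
#'   as frontloaded (basal log2 mean at least 0.5 above the transcriptome
#'   centre, planted log2FC = 0) and as responsive (basal at least 0.5
#'   below, planted log2FC = `de_log2fc` in the responsive species).
#'   Fractions must sum to <= 1; the remainder are unremarkable SRGs.
#' @param responsive_species Species in which planted effects are expressed
#'   (default: the last species).
#' @param hit_accuracy Probability that a gene's best simulated hit carries
#'   the taxon matching its true origin.
#' @param symbiont_mixture Named probability vector over Symbiodiniaceae
#'   reference labels for symbiont best hits.
#' @param host_gc,symbiont_gc Target GC fractions for simulated sequences.
#' @param library_size_mean,library_size_sdlog Log-normal library-size
#'   model (so CPM differs from raw counts and normalization is exercised).
#' @param srg_families SRG family definition table used to label planted
#'   SRGs; defaults to [default_srg_families()].
#' @return A validated list of class `coralheat_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 4L,
                       n_genes_host = 2000L,
                       n_genes_symbiont = 1500L,
                       replicates_per_cell = 3L,
                       timepoints_h = c(4L, 24L),
                       dispersion = 0.1,
                       mean_log_expression = 5,
                       sd_log_expression = 2,
                       de_fraction = 0.05,
                       de_log2fc = 4,
                       de_timepoints_h = timepoints_h,
                       srg_fraction = 0.10,
                       frontloaded_fraction = 0.55,
                       responsive_fraction = 0.40,
                       responsive_species = NULL,
                       hit_accuracy = 0.98,
                       symbiont_mixture = c(Smic = 0.08, Bmin = 0.08,
                                            Cgor = 0.09, Dtre = 0.68,
                                            Fkaw = 0.07),
                       host_gc = 0.42,
                       symbiont_gc = 0.55,
                       library_size_mean = 1e6,
                       library_size_sdlog = 0.15,
                       srg_families = default_srg_families()) {
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              n_genes_host = as.integer(n_genes_host),
              n_genes_symbiont = as.integer(n_genes_symbiont),
              replicates_per_cell = as.integer(replicates_per_cell),
              timepoints_h = as.integer(timepoints_h),
              dispersion = dispersion,
              mean_log_expression = mean_log_expression,
              sd_log_expression = sd_log_expression,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              de_timepoints_h = as.integer(de_timepoints_h),
              srg_fraction = srg_fraction,
              frontloaded_fraction = frontloaded_fraction,
              responsive_fraction = responsive_fraction,
              hit_accuracy = hit_accuracy,
              symbiont_mixture = symbiont_mixture,
              host_gc = host_gc, symbiont_gc = symbiont_gc,
              library_size_mean = library_size_mean,
              library_size_sdlog = library_size_sdlog,
              srg_families = validate_srg_families(srg_families))
  cfg$species <- sprintf("sp%02d", seq_len(cfg$n_species))
  cfg$responsive_species <- if (is.null(responsive_species)) {
    cfg$species[cfg$n_species]
  } else as.character(responsive_species)
  fr <- c(de_fraction, srg_fraction, frontloaded_fraction,
          responsive_fraction, host_gc, symbiont_gc, hit_accuracy)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (frontloaded_fraction + responsive_fraction > 1) {
    stop("frontloaded_fraction + responsive_fraction must be <= 1",
         call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$replicates_per_cell < 2L) stop("need >= 2 replicates", call. = FALSE)
  if (cfg$n_genes_host < 1L || cfg$n_species < 1L) {
    stop("degenerate config: need >= 1 host gene and >= 1 species",
         call. = FALSE)
  }
  if (abs(sum(symbiont_mixture) - 1) > 1e-8 || is.null(names(symbiont_mixture))) {
    stop("symbiont_mixture must be a named probability vector summing to 1",
         call. = FALSE)
  }
  if (!all(cfg$responsive_species %in% cfg$species)) {
    stop("responsive_species must be among the configured species",
         call. = FALSE)
  }
  class(cfg) <- "coralheat_sim_config"
  cfg
}

#' Load a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys error.
#'
#' @param path YAML file path.
#' @return A validated `coralheat_sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown simulation config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$symbiont_mixture)) {
    raw$symbiont_mixture <- unlist(raw$symbiont_mixture)
  }
  if (!is.null(raw$srg_families)) {
    raw$srg_families <- read_srg_families(raw$srg_families)
  }
  do.call(sim_config, raw)
}

.rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Simulate a holobiont count matrix with planted structure
#'
#' Counts for gene g in sample s are drawn NB(mu_gs, phi) with
#' `mu_gs = 2^(b_g + delta_gs) * L_s / M`, where `b_g` is the baseline
#' log2 mean, `delta_gs` the planted log2 effect (non-zero only in heated
#' samples of the responsive species at the configured timepoints), `L_s`
#' a log-normal library-size draw, and `M` the baseline expression mass
#' (so expected library size is close to `L_s`). Planted frontloaded SRGs
#' have baseline at least 0.5 log2 units above the gene-population centre
#' and zero planted fold change; planted responsive SRGs have baseline at
#' least 0.5 below and planted log2FC `de_log2fc`.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `counts` (integer matrix, genes x samples), `meta`
#'   (sample metadata data.frame), and `truth` (per-gene ground-truth
#'   data.frame: origin, is_srg, srg_family, planted_status,
#'   planted_frontloaded, planted_responsive, basal_log2_mean,
#'   planted_log2fc).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "coralheat_sim_config"))
  set.seed(cfg$seed)
  n_h <- cfg$n_genes_host
  n_s <- cfg$n_genes_symbiont
  genes <- c(sprintf("h%05d", seq_len(n_h)),
             if (n_s > 0L) sprintf("s%05d", seq_len(n_s)))
  origin <- rep(c("host", "symbiont"), c(n_h, n_s))
  n_g <- length(genes)

  b <- stats::rnorm(n_g, cfg$mean_log_expression, cfg$sd_log_expression)

  host_idx <- which(origin == "host")
  n_srg <- round(cfg$srg_fraction * n_h)
  srg_idx <- sort(sample(host_idx, n_srg))
  fam_names <- cfg$srg_families$family
  srg_family <- rep(NA_character_, n_g)
  if (n_srg > 0L) srg_family[srg_idx] <- sample(fam_names, n_srg, replace = TRUE)

  n_front <- round(cfg$frontloaded_fraction * n_srg)
  n_resp <- round(cfg$responsive_fraction * n_srg)
  shuffled <- sample(srg_idx)
  front_idx <- sort(shuffled[seq_len(n_front)])
  resp_idx <- sort(shuffled[n_front + seq_len(n_resp)])
  m0 <- cfg$mean_log_expression
  b[front_idx] <- .rnorm_trunc(n_front, m0 + 1.5, 0.75, lower = m0 + 0.5)
  b[resp_idx] <- .rnorm_trunc(n_resp, m0 - 1.5, 0.75, upper = m0 - 0.5)

  nonsrg_host <- setdiff(host_idx, srg_idx)
  n_de <- round(cfg$de_fraction * n_h)
  if (n_de > length(nonsrg_host)) {
    stop("de_fraction too large for the non-SRG host gene pool", call. = FALSE)
  }
  de_idx <- sort(sample(nonsrg_host, n_de))
  n_up <- ceiling(n_de / 2)
  de_sign <- rep(NA_real_, n_g)
  de_shuffled <- sample(de_idx)
  de_sign[de_shuffled[seq_len(n_up)]] <- 1
  if (n_de > n_up) de_sign[de_shuffled[(n_up + 1):n_de]] <- -1

  planted_log2fc <- rep(0, n_g)
  planted_log2fc[de_idx] <- de_sign[de_idx] * cfg$de_log2fc
  planted_log2fc[resp_idx] <- cfg$de_log2fc

  status <- rep("null", n_g)
  status[de_idx] <- ifelse(de_sign[de_idx] > 0, "de_up", "de_down")
  status[resp_idx] <- "de_up"

  truth <- data.frame(
    gene_id = genes, origin = origin,
    is_srg = seq_len(n_g) %in% srg_idx,
    srg_family = srg_family,
    planted_status = status,
    planted_frontloaded = seq_len(n_g) %in% front_idx,
    planted_responsive = seq_len(n_g) %in% resp_idx,
    basal_log2_mean = b,
    planted_log2fc = planted_log2fc,
    stringsAsFactors = FALSE
  )

  meta <- expand.grid(colony = seq_len(cfg$replicates_per_cell),
                      treatment = .TREATMENTS,
                      timepoint_h = cfg$timepoints_h,
                      species = cfg$species,
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_%02dh_c%d", meta$species, meta$treatment,
                            meta$timepoint_h, meta$colony)
  meta$colony <- sprintf("%s_col%d", meta$species, meta$colony)
  meta <- meta[, c("sample_id", "species", "colony", "treatment", "timepoint_h")]

  n_samp <- nrow(meta)
  lib <- stats::rlnorm(n_samp, log(cfg$library_size_mean) -
                         cfg$library_size_sdlog^2 / 2, cfg$library_size_sdlog)
  mass <- sum(2^b)

  counts <- matrix(0L, n_g, n_samp, dimnames = list(genes, meta$sample_id))
  for (j in seq_len(n_samp)) {
    delta <- rep(0, n_g)
    if (meta$treatment[j] == "heated" &&
        meta$species[j] %in% cfg$responsive_species &&
        meta$timepoint_h[j] %in% cfg$de_timepoints_h) {
      delta <- planted_log2fc
    }
    mu <- 2^(b + delta) * lib[j] / mass
    counts[, j] <- if (cfg$dispersion > 0) {
      stats::rnbinom(n_g, mu = mu, size = 1 / cfg$dispersion)
    } else {
      stats::rpois(n_g, mu)
    }
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, meta = meta, truth = truth)
}

.SYM_REFS <- c("Smic", "Bmin", "Cgor", "Dtre", "Fkaw")
.DECOY_TAXA <- c("Bacteria", "Fungi", "Viridiplantae")

#' Simulate BLAST-style best-hit tables for binning
#'
#' Produces two hit tables: `nr` emulates a search against a broad protein
#' database, where each gene's best hit (lowest e-value) carries the taxon
#' matching its true origin (Cnidaria for host, Dinophyceae for symbiont)
#' with probability `cfg$hit_accuracy`, plus 0-2 worse decoy hits; `sym`
#' emulates the symbiont-vs-Symbiodiniaceae-genomes search, with the best
#' reference label drawn from `cfg$symbiont_mixture`.
#'
#' @param truth Ground-truth table from [simulate_counts()].
#' @param cfg The simulation config.
#' @return A list of two hit data.frames, `nr` and `sym`, in
#'   [read_hit_table()] layout.
#' @export
simulate_hits <- function(truth, cfg) {
  stopifnot(inherits(cfg, "coralheat_sim_config"))
  set.seed(cfg$seed + 101L)
  n_g <- nrow(truth)
  true_taxon <- ifelse(truth$origin == "host", "Cnidaria", "Dinophyceae")
  correct <- stats::runif(n_g) < cfg$hit_accuracy
  best_taxon <- ifelse(correct, true_taxon,
                       sample(.DECOY_TAXA, n_g, replace = TRUE))
  best <- data.frame(
    query_id = truth$gene_id,
    subject_id = sprintf("ref|%06d", sample.int(1e6, n_g)),
    pct_identity = round(stats::runif(n_g, 70, 99), 2),
    evalue = 10^-stats::runif(n_g, 30, 80),
    bitscore = round(stats::runif(n_g, 200, 900), 1),
    subject_taxon = best_taxon,
    stringsAsFactors = FALSE
  )
  n_extra <- sample(0:2, n_g, replace = TRUE)
  idx <- rep(seq_len(n_g), n_extra)
  extra <- data.frame(
    query_id = truth$gene_id[idx],
    subject_id = sprintf("ref|%06d", sample.int(1e6, length(idx), replace = TRUE)),
    pct_identity = round(stats::runif(length(idx), 40, 90), 2),
    evalue = 10^-stats::runif(length(idx), 6, 25),
    bitscore = round(stats::runif(length(idx), 50, 300), 1),
    subject_taxon = sample(c(.DECOY_TAXA, "Cnidaria", "Dinophyceae"),
                           length(idx), replace = TRUE),
    stringsAsFactors = FALSE
  )
  nr <- rbind(best, extra)
  nr <- nr[order(nr$query_id, nr$evalue), , drop = FALSE]
  rownames(nr) <- NULL

  sym_genes <- truth$gene_id[truth$origin == "symbiont"]
  n_sym <- length(sym_genes)
  sym <- NULL
  if (n_sym > 0L) {
    ref <- sample(names(cfg$symbiont_mixture), n_sym, replace = TRUE,
                  prob = cfg$symbiont_mixture)
    sym_best <- data.frame(
      query_id = sym_genes,
      subject_id = sprintf("%s|%05d", ref, sample.int(5e4, n_sym, replace = TRUE)),
      pct_identity = round(stats::runif(n_sym, 60, 98), 2),
      evalue = 10^-stats::runif(n_sym, 30, 80),
      bitscore = round(stats::runif(n_sym, 150, 800), 1),
      subject_taxon = ref,
      stringsAsFactors = FALSE
    )
    n_extra2 <- sample(0:1, n_sym, replace = TRUE)
    idx2 <- rep(seq_len(n_sym), n_extra2)
    ref2 <- sample(names(cfg$symbiont_mixture), length(idx2), replace = TRUE)
    sym_extra <- data.frame(
      query_id = sym_genes[idx2],
      subject_id = sprintf("%s|%05d", ref2, sample.int(5e4, length(idx2), replace = TRUE)),
      pct_identity = round(stats::runif(length(idx2), 40, 90), 2),
      evalue = 10^-stats::runif(length(idx2), 6, 25),
      bitscore = round(stats::runif(length(idx2), 50, 250), 1),
      subject_taxon = ref2,
      stringsAsFactors = FALSE
    )
    sym <- rbind(sym_best, sym_extra)
    sym <- sym[order(sym$query_id, sym$evalue), , drop = FALSE]
    rownames(sym) <- NULL
  }
  list(nr = nr, sym = sym)
}

#' Simulate a protein-domain annotation table
#'
#' Every planted SRG carries one defining domain of its family (low
#' e-value); non-SRG genes carry decoy accessions (PF9xxxx range, outside
#' any family definition) with probability 0.6.
#'
#' @param truth Ground-truth table from [simulate_counts()].
#' @param families SRG family definition table (defaults to the config's).
#' @param cfg The simulation config.
#' @return A domain annotation data.frame (`gene_id`, `domain_accession`,
#'   `domain_evalue`).
#' @export
simulate_domains <- function(truth, cfg, families = cfg$srg_families) {
  stopifnot(inherits(cfg, "coralheat_sim_config"))
  set.seed(cfg$seed + 202L)
  acc_list <- family_accession_list(families)
  srg <- truth[truth$is_srg, , drop = FALSE]
  rows <- list()
  if (nrow(srg) > 0L) {
    acc <- vapply(srg$srg_family, function(f) {
      a <- acc_list[[f]]
      a[sample.int(length(a), 1L)]
    }, character(1))
    rows$srg <- data.frame(gene_id = srg$gene_id, domain_accession = acc,
                           domain_evalue = 10^-stats::runif(nrow(srg), 10, 40),
                           stringsAsFactors = FALSE)
  }
  non <- truth$gene_id[!truth$is_srg]
  keep <- stats::runif(length(non)) < 0.6
  non <- non[keep]
  if (length(non)) {
    rows$decoy <- data.frame(
      gene_id = non,
      domain_accession = sprintf("PF9%04d", sample.int(9999, length(non),
                                                       replace = TRUE)),
      domain_evalue = 10^-stats::runif(length(non), 4, 30),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), domain_accession = character(0),
                      domain_evalue = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate transcript sequences with origin-specific GC content
#'
#' Random sequences whose expected GC fraction equals the origin-specific
#' target (`cfg$host_gc` for host genes, `cfg$symbiont_gc` for symbiont
#' genes), emulating the GC contrast between coral host and dinoflagellate
#' symbiont transcripts.
#'
#' @param truth Ground-truth table from [simulate_counts()].
#' @param cfg The simulation config.
#' @param length_range Integer range of sequence lengths (nt).
#' @return A [Biostrings::DNAStringSet] named by gene id.
#' @export
simulate_sequences <- function(truth, cfg, length_range = c(300L, 3000L)) {
  stopifnot(inherits(cfg, "coralheat_sim_config"))
  set.seed(cfg$seed + 303L)
  gc <- ifelse(truth$origin == "host", cfg$host_gc, cfg$symbiont_gc)
  lens <- sample(seq(length_range[1], length_range[2]), nrow(truth),
                 replace = TRUE)
  seqs <- vapply(seq_len(nrow(truth)), function(i) {
    p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
    paste(sample(c("A", "C", "G", "T"), lens[i], replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- truth$gene_id
  out
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits `counts.tsv`, `metadata.tsv`, `hits.tsv`, `sym_hits.tsv`,
#' `domains.tsv`, `srg_families.tsv`, `sequences.fasta`, `truth.tsv`, and
#' `config.yaml` under `dir`.
#'
#' @param cfg A [sim_config()] object.
#' @param dir Output directory (created if absent).
#' @param sequences Whether to simulate and write FASTA sequences.
#' @return Named character vector of written file paths, invisibly; the
#'   simulated objects are returned in attribute `"objects"`.
#' @export
simulate_bundle <- function(cfg, dir, sequences = TRUE) {
  stopifnot(inherits(cfg, "coralheat_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(cfg)
  hits <- simulate_hits(sim$truth, cfg)
  domains <- simulate_domains(sim$truth, cfg)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    hits = file.path(dir, "hits.tsv"),
    sym_hits = file.path(dir, "sym_hits.tsv"),
    domains = file.path(dir, "domains.tsv"),
    srg_families = file.path(dir, "srg_families.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_count_matrix(sim$counts, paths[["counts"]])
  write_sample_metadata(sim$meta, paths[["metadata"]])
  write_hit_table(hits$nr, paths[["hits"]])
  if (!is.null(hits$sym)) write_hit_table(hits$sym, paths[["sym_hits"]])
  .write_tsv(domains, paths[["domains"]])
  .write_tsv(cfg$srg_families, paths[["srg_families"]])
  .write_tsv(sim$truth, paths[["truth"]])
  objs <- list(counts = sim$counts, meta = sim$meta, truth = sim$truth,
               hits = hits, domains = domains)
  if (sequences) {
    paths <- c(paths, sequences = file.path(dir, "sequences.fasta"))
    seqs <- simulate_sequences(sim$truth, cfg)
    Biostrings::writeXStringSet(seqs, paths[["sequences"]])
    objs$sequences <- seqs
  }
  cfg_out <- cfg[setdiff(names(cfg), "srg_families")]
  cfg_out$symbiont_mixture <- as.list(cfg$symbiont_mixture)
  yaml::write_yaml(cfg_out, paths[["config"]])
  invisible(structure(paths, objects = objs))
}
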