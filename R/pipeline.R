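# End-to-end orchestration: filter -> bin -> catalog -> normalize -> DE ->
# multivariate -> frontloading, driven by a single config (list or YAML)
# with one global seed, stage logging to stderr plus a logfile, and a
# manifest with a checksum for every output file.

#' Build a validated pipeline configuration
#'
#' @param counts,metadata,hits,domains,srg_families Required input paths.
#' @param sym_hits,sequences,isoforms Optional input paths (symbiont
#'   reference hits, FASTA, isoform table).
#' @param outdir Output directory.
#' @param seed Global seed (drives PERMANOVA permutations).
#' @param n_permutations PERMANOVA permutation count.
#' @param cpm_min,lib_min Expression-filter thresholds.
#' @param lfc_de,fdr DE classification thresholds.
#' @param lfc_front Frontloading stability bound.
#' @param plasticity_space `"full"` or `"pc"`.
#' @param frontloading_unit Normalized unit for basal expression
#'   (`"cpm"`, `"tpm"` or `"vst"`; TPM requires `sequences` for lengths).
#' @param frontloading_timepoint_rule `"both"` or `"either"`.
#' @param species_groups Optional named vector mapping species to
#'   taxonomic groups for the SRG association stage.
#' @return A list of class `coralheat_pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, hits, domains, srg_families,
                            outdir, sym_hits = NULL, sequences = NULL,
                            isoforms = NULL, seed = 1L,
                            n_permutations = 999L, cpm_min = 2,
                            lib_min = 2L, lfc_de = 4, fdr = 0.05,
                            lfc_front = 2,
                            plasticity_space = "full",
                            frontloading_unit = "cpm",
                            frontloading_timepoint_rule = "both",
                            species_groups = NULL) {
  cfg <- as.list(environment())
  if (any(c(cfg$cpm_min, cfg$lib_min, cfg$lfc_de, cfg$fdr, cfg$lfc_front) <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  required <- c("counts", "metadata", "hits", "domains", "srg_families")
  for (nm in required) {
    if (!file.exists(cfg[[nm]])) {
      stop("input path for '", nm, "' does not exist: ", cfg[[nm]],
           call. = FALSE)
    }
  }
  for (nm in c("sym_hits", "sequences", "isoforms")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop("input path for '", nm, "' does not exist: ", cfg[[nm]],
           call. = FALSE)
    }
  }
  cfg$frontloading_unit <- match.arg(cfg$frontloading_unit,
                                     c("cpm", "tpm", "vst"))
  class(cfg) <- "coralheat_pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML path with keys matching [pipeline_config()] arguments.
#' @return A validated `coralheat_pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$species_groups)) raw$species_groups <- unlist(raw$species_groups)
  do.call(pipeline_config, raw)
}

.pipe_log <- function(logfile, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(line)
  cat(line, "\n", file = logfile, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Executes filter -> bin -> catalog -> normalize -> de -> multivariate ->
#' frontloading, writing every stage table as TSV under `config$outdir`
#' plus `manifest.tsv` (stage status and timing), `checksums.tsv` (md5 of
#' every output), and `pipeline.log`. Re-running with the same config and
#' seed reproduces all outputs bit-for-bit.
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @return A list with `manifest`, `checksums`, and the in-memory stage
#'   results (`bins`, `catalog`, `de`, `multivariate`, `frontloading`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config_from_yaml(config)
  stopifnot(inherits(config, "coralheat_pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$outdir, "pipeline.log")
  cat("", file = logfile)
  set.seed(config$seed)
  .pipe_log(logfile, "pipeline start; seed=", config$seed,
            "; thresholds: cpm>", config$cpm_min, " in >=", config$lib_min,
            " libs, |log2FC|>=", config$lfc_de, ", FDR<", config$fdr,
            ", frontloading |log2FC|<", config$lfc_front)
  stages <- c("filter", "bin", "catalog", "normalize", "de",
              "multivariate", "frontloading")
  manifest <- data.frame(stage = stages, status = "pending", elapsed_s = NA_real_,
                         stringsAsFactors = FALSE)
  outputs <- character(0)
  results <- list()
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest[manifest$stage == name, c("status", "elapsed_s")] <<-
      list(res$status, round(proc.time()[["elapsed"]] - t0, 3))
    outputs <<- c(outputs, res$outputs)
    .pipe_log(logfile, "stage ", name, ": ", res$status)
    res$value
  }

  counts <- read_count_matrix(config$counts)
  meta <- read_sample_metadata(config$metadata)
  validate_design(meta, counts)
  species <- unique(meta$species)

  # 1. filter: representative-isoform selection (optional input)
  run_stage("filter", function() {
    if (is.null(config$isoforms)) {
      return(list(status = "skipped (no isoform table)", outputs = character(0),
                  value = NULL))
    }
    iso <- .read_tsv(config$isoforms)
    filt <- filter_isoforms(iso)
    path <- file.path(config$outdir, "isoforms_representative.tsv")
    .write_tsv(filt, path)
    list(status = "ok", outputs = path, value = filt)
  })

  # 2. bin: host/symbiont assignment, affiliation, GC
  bins <- run_stage("bin", function() {
    hits <- read_hit_table(config$hits)
    assignments <- assign_bins(rownames(counts), hits)
    out <- file.path(config$outdir, "bin_assignments.tsv")
    .write_tsv(assignments, out)
    outs <- out
    if (!is.null(config$sym_hits)) {
      sym_hits <- read_hit_table(config$sym_hits)
      aff <- affiliation_summary(assignments, sym_hits)
      p <- file.path(config$outdir, "symbiont_affiliation.tsv")
      .write_tsv(aff, p)
      outs <- c(outs, p)
    }
    if (!is.null(config$sequences)) {
      gc <- gc_content(config$sequences, assignments)
      p <- file.path(config$outdir, "gc_content.tsv")
      .write_tsv(data.frame(bin = names(gc), gc_percent = round(gc, 4)), p)
      outs <- c(outs, p)
    }
    list(status = "ok", outputs = outs, value = assignments)
  })
  results$bins <- bins
  binned <- bins$gene_id[bins$bin != "dropped"]
  counts <- counts[binned, , drop = FALSE]
  origin <- stats::setNames(bins$bin, bins$gene_id)[binned]
  host_genes <- names(origin)[origin == "host"]

  # 3. catalog: SRG families on host genes
  catalog <- run_stage("catalog", function() {
    domains <- read_domain_table(config$domains)
    fams <- read_srg_families(config$srg_families)
    cat_all <- assign_srg_families(domains, fams)
    cat_host <- cat_all[cat_all$gene_id %in% host_genes, , drop = FALSE]
    out <- file.path(config$outdir, "srg_catalog.tsv")
    .write_tsv(cat_host, out)
    outs <- out
    totals <- stats::setNames(rep(length(host_genes), length(species)), species)
    per_sp <- do.call(rbind, lapply(species, function(sp) {
      cbind(species = sp, cat_host, stringsAsFactors = FALSE)
    }))
    abund <- srg_relative_abundance(per_sp, totals, families = fams)
    p <- file.path(config$outdir, "srg_abundance.tsv")
    .write_tsv(abund, p)
    outs <- c(outs, p)
    if (!is.null(config$species_groups)) {
      assoc <- group_association(abund, config$species_groups)
      p2 <- file.path(config$outdir, "srg_group_association.tsv")
      .write_tsv(assoc, p2)
      outs <- c(outs, p2)
    }
    list(status = "ok", outputs = outs, value = cat_host)
  })
  results$catalog <- catalog

  # 4. normalize: per-species CPM (written once; per-species TMM/vst are
  # computed inside the DE and multivariate stages)
  run_stage("normalize", function() {
    cpm_all <- cpm(counts)
    p <- file.path(config$outdir, "cpm.tsv")
    write_matrix_tsv(round(cpm_all, 4), p)
    list(status = "ok", outputs = p, value = NULL)
  })

  # 5. de: time-matched exact tests per species
  de_all <- run_stage("de", function() {
    res <- lapply(species, function(sp) {
      cols <- meta$sample_id[meta$species == sp]
      de <- run_de(counts[, cols, drop = FALSE],
                   meta[meta$species == sp, , drop = FALSE],
                   min_cpm = config$cpm_min, min_libraries = config$lib_min,
                   lfc_min = config$lfc_de, fdr_max = config$fdr)
      de$results$species <- sp
      de
    })
    names(res) <- species
    tab <- do.call(rbind, lapply(res, `[[`, "results"))
    tab$origin <- unname(origin[tab$gene_id])
    p <- file.path(config$outdir, "de_results.tsv")
    .write_tsv(tab, p)
    summ <- summarize_deg_counts(tab, bins = origin)
    p2 <- file.path(config$outdir, "deg_counts.tsv")
    .write_tsv(summ, p2)
    disp <- data.frame(species = species,
                       dispersion = vapply(res, `[[`, numeric(1), "dispersion"))
    p3 <- file.path(config$outdir, "dispersion.tsv")
    .write_tsv(disp, p3)
    list(status = "ok", outputs = c(p, p2, p3),
         value = list(per_species = res, table = tab, summary = summ))
  })
  results$de <- de_all

  # 6. multivariate: per species x origin bin
  multivar <- run_stage("multivariate", function() {
    perm_seed <- config$seed
    rows <- list()
    plast <- list()
    for (sp in species) {
      cols <- meta$sample_id[meta$species == sp]
      msub <- meta[meta$species == sp, , drop = FALSE]
      for (bn in intersect(c("host", "symbiont"), unique(origin))) {
        g <- names(origin)[origin == bn]
        sub <- counts[g, cols, drop = FALSE]
        sub <- sub[rowSums(sub) > 0, , drop = FALSE]
        v <- vst_transform(sub)
        pc <- pca_samples(v)
        d <- stats::dist(t(v))
        perm_seed <- perm_seed + 1L
        pm_t <- permanova(d, msub$treatment, n_perm = config$n_permutations,
                          seed = perm_seed)
        perm_seed <- perm_seed + 1L
        pm_c <- permanova(d, paste0(msub$treatment, "_", msub$timepoint_h),
                          n_perm = config$n_permutations, seed = perm_seed)
        pl <- plasticity_analysis(v, msub, space = config$plasticity_space)
        plast[[paste(sp, bn, sep = "_")]] <- cbind(species = sp, origin = bn,
                                                   pl$distances)
        rows[[paste(sp, bn, sep = "_")]] <- data.frame(
          species = sp, origin = bn,
          pc1_var = pc$var_explained[1L], pc2_var = pc$var_explained[2L],
          permanova_treatment_f = pm_t$pseudo_f, permanova_treatment_p = pm_t$p,
          permanova_cell_f = pm_c$pseudo_f, permanova_cell_p = pm_c$p,
          plasticity_anova_f = pl$anova$f, plasticity_anova_p = pl$anova$p,
          stringsAsFactors = FALSE)
      }
    }
    summ <- do.call(rbind, rows)
    p <- file.path(config$outdir, "multivariate_summary.tsv")
    .write_tsv(summ, p)
    ptab <- do.call(rbind, plast)
    p2 <- file.path(config$outdir, "plasticity.tsv")
    .write_tsv(ptab, p2)
    list(status = "ok", outputs = c(p, p2),
         value = list(summary = summ, plasticity = ptab))
  })
  results$multivariate <- multivar

  # 7. frontloading: per species over host SRGs
  front <- run_stage("frontloading", function() {
    unit_matrix <- function(cols) {
      switch(config$frontloading_unit,
             cpm = cpm(counts[, cols, drop = FALSE])[host_genes, , drop = FALSE],
             tpm = {
               if (is.null(config$sequences)) {
                 stop("TPM frontloading unit requires sequences for lengths")
               }
               seqs <- Biostrings::readDNAStringSet(config$sequences)
               names(seqs) <- sub("\\s.*$", "", names(seqs))
               lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
               tpm(counts[, cols, drop = FALSE], lens)[host_genes, , drop = FALSE]
             },
             vst = vst_transform(counts[, cols, drop = FALSE])[host_genes, ,
                                                               drop = FALSE])
    }
    calls_all <- list()
    reports <- list()
    for (sp in species) {
      cols <- meta$sample_id[meta$species == sp]
      msub <- meta[meta$species == sp, , drop = FALSE]
      nm <- unit_matrix(cols)
      de_sp <- de_all$table[de_all$table$species == sp, , drop = FALSE]
      calls <- frontloading_calls(nm, msub, de_sp, catalog,
                                  lfc_max = config$lfc_front,
                                  timepoint_rule = config$frontloading_timepoint_rule)
      calls_all[[sp]] <- cbind(species = sp, calls, stringsAsFactors = FALSE)
      rep_sp <- frontloading_report(calls)
      reports[[sp]] <- cbind(species = sp, rep_sp, stringsAsFactors = FALSE)
    }
    calls_tab <- do.call(rbind, calls_all)
    rep_tab <- do.call(rbind, reports)
    p <- file.path(config$outdir, "frontloading_calls.tsv")
    .write_tsv(calls_tab, p)
    p2 <- file.path(config$outdir, "frontloading_report.tsv")
    .write_tsv(rep_tab, p2)
    list(status = "ok", outputs = c(p, p2),
         value = list(calls = calls_tab, report = rep_tab))
  })
  results$frontloading <- front

  checks <- data.frame(file = basename(outputs),
                       md5 = unname(tools::md5sum(outputs)),
                       stringsAsFactors = FALSE)
  .write_tsv(checks, file.path(config$outdir, "checksums.tsv"))
  .write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
  .pipe_log(logfile, "pipeline complete: ", nrow(checks), " output files")
  c(list(manifest = manifest, checksums = checks), results)
}
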