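test_that("simulation is deterministic under a fixed seed", {
  a <- small_sim(seed = 11, n_genes_host = 200, n_genes_symbiont = 100)
  b <- small_sim(seed = 11, n_genes_host = 200, n_genes_symbiont = 100)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_hits(a$truth, a$cfg), simulate_hits(b$truth, b$cfg))
  expect_identical(simulate_domains(a$truth, a$cfg),
                   simulate_domains(b$truth, b$cfg))
  expect_identical(as.character(simulate_sequences(a$truth, a$cfg)),
                   as.character(simulate_sequences(b$truth, b$cfg)))
})

test_that("planted label counts follow the configured fractions exactly", {
  cfg <- sim_config(seed = 5, n_species = 1, n_genes_host = 2000,
                    n_genes_symbiont = 0, de_fraction = 0.05)
  sim <- simulate_counts(cfg)
  host_de <- sim$truth$origin == "host" &
    sim$truth$planted_status %in% c("de_up", "de_down") &
    !sim$truth$is_srg
  expect_identical(sum(host_de), 100L)
  expect_identical(sum(sim$truth$is_srg), as.integer(round(0.10 * 2000)))

  null_cfg <- sim_config(seed = 5, n_species = 1, n_genes_host = 500,
                         n_genes_symbiont = 0, de_fraction = 0,
                         srg_fraction = 0)
  null_sim <- simulate_counts(null_cfg)
  expect_identical(sum(null_sim$truth$planted_status != "null"), 0L)
})

test_that("ground truth bookkeeping is consistent", {
  sim <- small_sim(seed = 3, n_genes_host = 300, n_genes_symbiont = 150)
  expect_identical(anyDuplicated(sim$truth$gene_id), 0L)
  expect_identical(sort(sim$truth$gene_id), sort(rownames(sim$counts)))
  # frontloaded implies SRG; planted DE genes carry the configured log2FC
  expect_true(all(sim$truth$is_srg[sim$truth$planted_frontloaded]))
  de <- sim$truth$planted_status %in% c("de_up", "de_down")
  expect_true(all(abs(sim$truth$planted_log2fc[de]) == sim$cfg$de_log2fc))
  expect_true(all(sim$truth$planted_log2fc[!de &
                                             !sim$truth$planted_responsive] == 0))
  # frontloaded baselines sit above the population centre, responsive below
  m0 <- sim$cfg$mean_log_expression
  expect_true(all(sim$truth$basal_log2_mean[sim$truth$planted_frontloaded] >
                    m0 + 0.5))
  expect_true(all(sim$truth$basal_log2_mean[sim$truth$planted_responsive] <
                    m0 - 0.5))
})

test_that("planted effects appear in expected counts of heated samples", {
  sim <- small_sim(seed = 21, n_genes_host = 2000, n_genes_symbiont = 0,
                   dispersion = 0.05)
  up <- sim$truth$planted_status == "de_up" & !sim$truth$is_srg
  resp_sp <- sim$cfg$responsive_species
  heated <- sim$meta$sample_id[sim$meta$species == resp_sp &
                                 sim$meta$treatment == "heated"]
  ctl <- sim$meta$sample_id[sim$meta$species == resp_sp &
                              sim$meta$treatment == "control"]
  ratio <- rowMeans(cpm(sim$counts)[up, heated]) /
    rowMeans(cpm(sim$counts)[up, ctl] + 0.1)
  expect_gt(median(log2(ratio)), 3.3)
  # tolerant species shows no shift
  h2 <- sim$meta$sample_id[sim$meta$species == "sp01" &
                             sim$meta$treatment == "heated"]
  c2 <- sim$meta$sample_id[sim$meta$species == "sp01" &
                             sim$meta$treatment == "control"]
  ratio2 <- rowMeans(cpm(sim$counts)[up, h2] + 0.1) /
    rowMeans(cpm(sim$counts)[up, c2] + 0.1)
  expect_lt(abs(median(log2(ratio2))), 0.5)
})

test_that("simulated hits rank correctly and respect the accuracy knob", {
  sim <- small_sim(seed = 9, n_genes_host = 400, n_genes_symbiont = 200,
                   hit_accuracy = 1.0)
  hits <- simulate_hits(sim$truth, sim$cfg)
  best <- best_hits_per_query(hits$nr)
  idx <- match(sim$truth$gene_id, best$query_id)
  taxon <- best$subject_taxon[idx]
  expect_identical(taxon, ifelse(sim$truth$origin == "host",
                                 "Cnidaria", "Dinophyceae"))
  # per query, the retained hit has the minimum e-value
  one <- hits$nr[hits$nr$query_id == sim$truth$gene_id[1], ]
  expect_equal(best_hit(one)$evalue, min(one$evalue))
})

test_that("simulated affiliation mixture is recovered within binomial error", {
  cfg <- sim_config(seed = 13, n_species = 1, n_genes_host = 10,
                    n_genes_symbiont = 1000,
                    symbiont_mixture = c(Dtre = 0.7, Cgor = 0.3))
  sim <- simulate_counts(cfg)
  hits <- simulate_hits(sim$truth, cfg)
  best <- best_hits_per_query(hits$sym)
  frac <- mean(best$subject_taxon == "Dtre")
  ci_half <- 2.576 * sqrt(0.7 * 0.3 / 1000)
  expect_lt(abs(frac - 0.7), ci_half)
})

test_that("domain simulation plants defining domains exactly for SRGs", {
  sim <- small_sim(seed = 17, n_genes_host = 300, n_genes_symbiont = 0)
  dom <- simulate_domains(sim$truth, sim$cfg)
  acc <- family_accession_list(sim$cfg$srg_families)
  srg <- sim$truth[sim$truth$is_srg, ]
  defining <- dom[dom$domain_accession %in% unlist(acc), ]
  expect_setequal(defining$gene_id, srg$gene_id)
  # each SRG's planted accession belongs to its own family's set
  fam_of_acc <- rep(names(acc), lengths(acc))
  names(fam_of_acc) <- unlist(acc)
  got <- fam_of_acc[defining$domain_accession[match(srg$gene_id,
                                                    defining$gene_id)]]
  expect_identical(unname(got), srg$srg_family)

  no_srg <- sim_config(seed = 17, n_species = 1, n_genes_host = 100,
                       n_genes_symbiont = 0, srg_fraction = 0)
  sim2 <- simulate_counts(no_srg)
  dom2 <- simulate_domains(sim2$truth, no_srg)
  expect_false(any(dom2$domain_accession %in% unlist(acc)))
})

test_that("simulated sequences hit their GC targets", {
  cfg <- sim_config(seed = 23, n_species = 1, n_genes_host = 40,
                    n_genes_symbiont = 40)
  sim <- simulate_counts(cfg)
  seqs <- simulate_sequences(sim$truth, cfg)
  gc <- Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE)[, 1]
  host <- sim$truth$origin == "host"
  expect_lt(abs(mean(gc[host]) - 0.42), 0.02)
  expect_lt(abs(mean(gc[!host]) - 0.55), 0.02)

  pure <- sim_config(seed = 23, n_species = 1, n_genes_host = 3,
                     n_genes_symbiont = 0, host_gc = 1.0)
  sim_p <- simulate_counts(pure)
  seq_p <- simulate_sequences(sim_p$truth, pure)
  expect_true(all(Biostrings::letterFrequency(seq_p, "GC", as.prob = TRUE) == 1))
})

test_that("bundle files land on disk and round-trip", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 2, n_species = 1, n_genes_host = 80,
                    n_genes_symbiont = 40)
  paths <- simulate_bundle(cfg, dir)
  expect_true(all(file.exists(paths)))
  objs <- attr(paths, "objects")
  expect_identical(read_count_matrix(paths[["counts"]]), objs$counts)
  meta <- read_sample_metadata(paths[["metadata"]])
  expect_identical(meta$sample_id, objs$meta$sample_id)
  expect_identical(nrow(read_hit_table(paths[["hits"]])), nrow(objs$hits$nr))
  cfg_back <- yaml::read_yaml(paths[["config"]])
  expect_identical(cfg_back$seed, 2L)
})
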