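test_that("basal expression means all control libraries", {
  meta <- design_meta("sp1", r = 1)
  x <- matrix(seq_len(nrow(meta)), nrow = 1,
              dimnames = list("g1", meta$sample_id))
  b <- basal_expression(x, meta)
  ctl <- meta$treatment == "control"
  expect_equal(unname(b["g1"]), mean(x[1, ctl]))
  expect_error(basal_expression(x, transform(meta, treatment = "heated")),
               "no control")
})

test_that("the frontloading rule applies strict thresholds at both timepoints", {
  expect_true(classify_frontloaded(50, 10, 0.5, -0.3))
  expect_false(classify_frontloaded(5, 10, 0.5, -0.3))
  expect_false(classify_frontloaded(50, 10, 2.0, 0.1))   # strict < 2
  expect_false(classify_frontloaded(50, 10, 0.1, -2.5))  # both timepoints
  expect_false(classify_frontloaded(10, 10, 0.1, 0.1))   # strict > median
})

test_that("calls table keeps flags mutually exclusive and honours the rule", {
  meta <- design_meta("sp1", r = 2)
  set.seed(100)
  x <- matrix(rpois(20 * nrow(meta), 30), nrow = 20,
              dimnames = list(sprintf("g%d", 1:20), meta$sample_id))
  x[1, ] <- 500  # clear high-basal stable gene
  de <- expand.grid(gene_id = rownames(x), timepoint_h = c(4L, 24L),
                    stringsAsFactors = FALSE)
  de$log2fc <- 0.1
  de$status <- "ns"
  catalog <- data.frame(gene_id = rownames(x)[1:10], family = "HSP70",
                        category = "chemical", stringsAsFactors = FALSE)
  calls <- frontloading_calls(x, meta, de, catalog)
  expect_identical(nrow(calls), 10L)
  expect_true(calls$frontloaded[calls$gene_id == "g1"])
  expect_false(any(calls$frontloaded & calls$low_basal_responsive))

  # a low-basal significantly upregulated SRG is responsive, not frontloaded
  de2 <- de
  de2$log2fc[de2$gene_id == "g2"] <- 5
  de2$status[de2$gene_id == "g2"] <- "up"
  x2 <- x
  x2[2, ] <- 1
  calls2 <- frontloading_calls(x2, meta, de2, catalog)
  expect_true(calls2$low_basal_responsive[calls2$gene_id == "g2"])
  expect_false(calls2$frontloaded[calls2$gene_id == "g2"])
})

test_that("SRG distribution summaries reduce to identities on edge sets", {
  meta <- design_meta("sp1", r = 2)
  set.seed(101)
  x <- matrix(rpois(10 * nrow(meta), 40), nrow = 10,
              dimnames = list(sprintf("g%d", 1:10), meta$sample_id))
  de <- expand.grid(gene_id = rownames(x), timepoint_h = c(4L, 24L),
                    stringsAsFactors = FALSE)
  de$log2fc <- rep(c(1, -2), length.out = nrow(de))
  all_cat <- data.frame(gene_id = rownames(x), family = "HSP70",
                        category = "chemical", stringsAsFactors = FALSE)
  s <- srg_expression_summary(x, meta, all_cat, de)
  expect_equal(s$median_all, s$median_srg)  # SRG set == all genes
  expect_identical(s$n_above + s$n_below, 10L)
  expect_equal(unname(s$mean_abs_log2fc["4h"]), mean(abs(de$log2fc[de$timepoint_h == 4])))
})

test_that("responsive summaries average low-basal fold changes", {
  calls <- data.frame(
    gene_id = c("g1", "g2", "g3"), family = c("HSP70", "HSP70", "SOD"),
    category = "chemical",
    basal_expr = c(1, 2, 50), transcriptome_median = 10,
    log2fc_4h = c(2, 4, 0.1), log2fc_24h = c(1, 3, 0),
    status_4h = c("ns", "up", "ns"), status_24h = c("ns", "ns", "ns"),
    frontloaded = c(FALSE, FALSE, TRUE),
    low_basal_responsive = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  s <- responsive_srg_summary(calls)
  expect_equal(s$low_basal$mean_abs_log2fc[s$low_basal$timepoint_h == 4], 3)
  expect_equal(s$low_basal$n[1], 2L)
  up4 <- s$upregulated[s$upregulated$timepoint_h == 4, ]
  expect_equal(up4$n, 1L)
  expect_equal(up4$mean_log2fc, 4)
  expect_identical(s$upregulated_by_family$family, "HSP70")

  none <- calls[calls$basal_expr > 10, ]
  s0 <- responsive_srg_summary(none)
  expect_identical(nrow(s0$low_basal), 0L)
})

test_that("family enrichment follows the hypergeometric contrast", {
  calls <- data.frame(
    gene_id = sprintf("g%d", 1:60),
    family = rep(c("full", "bg1", "bg2"), each = 20),
    category = "chemical", basal_expr = 1, transcriptome_median = 0,
    log2fc_4h = 0, log2fc_24h = 0, status_4h = "ns", status_24h = "ns",
    frontloaded = c(rep(TRUE, 20), rep(c(TRUE, FALSE, FALSE, FALSE), 5),
                    rep(c(TRUE, FALSE, FALSE, FALSE), 5)),
    low_basal_responsive = FALSE, stringsAsFactors = FALSE)
  rep_tab <- frontloading_report(calls)
  expect_true(rep_tab$enriched[rep_tab$family == "full"])
  expect_false(any(rep_tab$enriched[rep_tab$family != "full"]))
  expect_equal(rep_tab$p_enrich[rep_tab$family == "full"],
               phyper(19, 30, 30, 20, lower.tail = FALSE), tolerance = 1e-12)

  # a single family spanning the whole catalog has no contrast
  whole <- calls
  whole$family <- "only"
  rw <- frontloading_report(whole)
  expect_equal(rw$p_enrich, 1, tolerance = 1e-12)

  zero <- calls
  zero$frontloaded <- FALSE
  expect_false(any(frontloading_report(zero)$enriched))
})

test_that("planted frontloaded SRGs are recovered with high precision/recall", {
  sim <- small_sim(seed = 111, n_genes_host = 1000, n_genes_symbiont = 0)
  dom <- simulate_domains(sim$truth, sim$cfg)
  catalog <- assign_srg_families(dom, sim$cfg$srg_families)
  tp <- fp <- fn <- 0
  for (sp in sim$cfg$species) {
    cols <- sim$meta$sample_id[sim$meta$species == sp]
    msub <- sim$meta[sim$meta$species == sp, ]
    de <- run_de(sim$counts[, cols], msub)
    calls <- frontloading_calls(cpm(sim$counts[, cols]), msub, de$results,
                                catalog)
    tr <- sim$truth[match(calls$gene_id, sim$truth$gene_id), ]
    tp <- tp + sum(calls$frontloaded & tr$planted_frontloaded)
    fp <- fp + sum(calls$frontloaded & !tr$planted_frontloaded)
    fn <- fn + sum(!calls$frontloaded & tr$planted_frontloaded)
  }
  expect_gte(tp / (tp + fp), 0.9)
  expect_gte(tp / (tp + fn), 0.9)
})
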