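test_that("count matrix round-trips through TSV exactly", {
  m <- mat(c(3L, 1L, 0L, 5L, 2L, 7L), nrow = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  back <- read_count_matrix(path)
  expect_identical(back, m)
  expect_equal(colSums(read_count_matrix(path)), c(s1 = 4L, s2 = 14L),
               ignore_attr = FALSE)
})

test_that("count reader rejects malformed input with line information", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t3\t0", "g2\t-1\t5"), path)
  expect_error(read_count_matrix(path), "negative count at line 3")

  writeLines(c("gene_id\ts1", "g1\t2", "g1\t3"), path)
  expect_error(read_count_matrix(path), "duplicate gene id 'g1'")

  writeLines("gene_id\ts1", path)
  expect_error(read_count_matrix(path), "no data rows")

  writeLines(c("gene_id\ts1", "g1\tabc"), path)
  expect_error(read_count_matrix(path), "non-numeric")
})

test_that("RSEM-style expected counts are rounded half-to-even with warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t2.5\t3.5", "g2\t1\t4"), path)
  expect_warning(m <- read_count_matrix(path), "rounded half-to-even")
  expect_identical(m["g1", ], c(s1 = 2L, s2 = 4L))
})

test_that("metadata is validated and canonicalized", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tspecies\tcolony\ttreatment\ttimepoint_h",
               "a\tsp1\tc1\tHeated\t4",
               "b\tsp1\tc2\tControl\t24"), path)
  meta <- read_sample_metadata(path)
  expect_identical(meta$treatment, c("heated", "control"))

  writeLines(c("sample_id\tspecies\tcolony\ttreatment\ttimepoint_h",
               "a\tsp1\tc1\twarmed\t4"), path)
  expect_error(read_sample_metadata(path), "unknown treatment")

  writeLines(c("sample_id\tspecies\tcolony\ttreatment\ttimepoint_h",
               "a\tsp1\tc1\tcontrol\t4", "a\tsp1\tc2\theated\t4"), path)
  expect_error(read_sample_metadata(path), "duplicate sample_id")

  writeLines(c("sample_id\tspecies\tcolony\ttreatment\ttimepoint_h",
               "a\tsp1\tc1\tcontrol\t12"), path)
  expect_error(read_sample_metadata(path), "declared set")
})

test_that("design validation matches samples and counts replicates", {
  meta <- design_meta("sp1")
  counts <- mat(rep(1L, 24), nrow = 2, samples = meta$sample_id)
  summary <- validate_design(meta, counts)
  expect_true(all(summary$cells$n_replicates == 3L))
  expect_length(summary$warnings, 0)

  extra <- cbind(counts, orphan = c(1L, 1L))
  expect_error(validate_design(meta, extra), "orphan")

  part <- meta[meta$treatment == "control", ]
  counts_p <- counts[, part$sample_id]
  summary_p <- validate_design(part, counts_p)
  expect_true(any(grepl("0 replicates", summary_p$warnings)))
})

test_that("hit tables read with or without header, enforcing ranges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\tsub1\t95.5\t100\t4\t0\t1\t100\t1\t100\t1e-50\t200\tCnidaria",
               "q2\tsub2\t80.0\t90\t9\t1\t1\t90\t1\t90\t1e-10\t90\tDinophyceae"),
             path)
  hits <- read_hit_table(path)
  expect_identical(hits$query_id, c("q1", "q2"))
  expect_identical(hits$subject_taxon, c("Cnidaria", "Dinophyceae"))
  expect_equal(hits$evalue, c(1e-50, 1e-10))

  writeLines("q1\tsub1\t120\t100\t4\t0\t1\t100\t1\t100\t1e-50\t200", path)
  expect_error(read_hit_table(path), "pct_identity")
})

test_that("SRG family tables enforce uniqueness, categories and domains", {
  fams <- data.frame(family = c("A", "B"), category = c("chemical", "wounding"),
                     accessions = c("PF00001,PF00002", "PF00003"))
  expect_silent(validate_srg_families(fams))
  expect_identical(family_accession_list(fams)$A, c("PF00001", "PF00002"))

  expect_error(validate_srg_families(
    data.frame(family = c("A", "A"), category = "chemical",
               accessions = "PF00001")), "duplicate")
  expect_error(validate_srg_families(
    data.frame(family = "A", category = "thermal", accessions = "PF00001")),
    "unknown SRG category")
  expect_error(validate_srg_families(
    data.frame(family = "A", category = "chemical", accessions = " ")),
    "empty defining-domain")
})

test_that("orthogroup reader drops a trailing Total column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Orthogroup\tspA\tspB\tTotal", "OG1\t2\t3\t5", "OG2\t0\t1\t1"),
             path)
  og <- read_orthogroup_counts(path)
  expect_identical(colnames(og), c("spA", "spB"))
  expect_identical(og["OG1", "spB"], 3L)
})
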