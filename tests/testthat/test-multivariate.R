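test_that("PCA separates clusters and reports well-formed variance fractions", {
  set.seed(90)
  base <- matrix(rnorm(40), nrow = 10)
  x <- cbind(base[, 1] + 0, base[, 1] + 0.001, base[, 2] + 10, base[, 2] + 10.001)
  rownames(x) <- sprintf("g%d", 1:10)
  colnames(x) <- sprintf("s%d", 1:4)
  pc <- pca_samples(x, n_top = 10)
  expect_gt(pc$var_explained[1], 0.95)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_lte(sum(pc$var_explained), 1 + 1e-9)
  # PC1 separates the two clusters
  expect_gt(abs(mean(pc$scores[1:2, 1]) - mean(pc$scores[3:4, 1])), 1)

  dup <- x[, c(1, 1, 3, 3)]
  colnames(dup) <- sprintf("s%d", 1:4)
  pd <- pca_samples(dup, n_top = 10)
  expect_equal(pd$scores[1, ], pd$scores[2, ])

  flat <- matrix(1, 5, 3, dimnames = list(sprintf("g%d", 1:5),
                                          sprintf("s%d", 1:3)))
  expect_error(pca_samples(flat), "constant")
})

test_that("PERMANOVA on well-separated 2+2 groups gives the enumeration p", {
  x <- matrix(c(0, 0.1, 10, 10.1), nrow = 1,
              dimnames = list("g1", sprintf("s%d", 1:4)))
  d <- dist(t(x))
  pm <- permanova(d, c("a", "a", "b", "b"), n_perm = "exhaustive")
  expect_equal(pm$p, 1 / 3, tolerance = 1e-12)
  expect_equal(pm$pseudo_f, oracle_permanova_f(d, c("a", "a", "b", "b")),
               tolerance = 1e-9)
})

test_that("exhaustive PERMANOVA equals the enumeration oracle on random data", {
  set.seed(91)
  for (rep in 1:5) {
    n <- sample(6:8, 1)
    groups <- sample(rep(c("a", "b"), length.out = n))
    x <- matrix(rnorm(4 * n), nrow = 4,
                dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:n)))
    d <- dist(t(x))
    pm <- permanova(d, groups, n_perm = "exhaustive")
    expect_equal(pm$pseudo_f, oracle_permanova_f(d, groups), tolerance = 1e-9)
    expect_equal(pm$p, oracle_permanova_p(d, groups), tolerance = 1e-12)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 and is label-invariant", {
  skip_if_not_installed("vegan")
  set.seed(92)
  x <- matrix(rnorm(60), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:12)))
  groups <- rep(c("a", "b", "c"), each = 4)
  d <- dist(t(x))
  pm <- permanova(d, groups, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(d ~ g, data = data.frame(g = groups),
                       permutations = 99)
  expect_equal(pm$pseudo_f, ad$F[1], tolerance = 1e-9)
  expect_equal(pm$r2, ad$R2[1], tolerance = 1e-9)

  # permuting sample order together with labels leaves F unchanged
  idx <- sample(12)
  pm2 <- permanova(as.matrix(d)[idx, idx], groups[idx], n_perm = 9, seed = 1)
  expect_equal(pm2$pseudo_f, pm$pseudo_f, tolerance = 1e-9)

  # determinism and the p-value floor
  pm3 <- permanova(d, groups, n_perm = 99, seed = 1)
  expect_identical(pm$p, pm3$p)
  expect_gte(pm$p, 1 / 100)
  expect_error(permanova(d, rep("a", 12)), "one group")
})

test_that("plasticity distance is Euclidean geometry to the reference centroid", {
  meta <- design_meta("sp1", r = 2)
  x <- matrix(0, nrow = 2, ncol = nrow(meta),
              dimnames = list(c("g1", "g2"), meta$sample_id))
  hot24 <- meta$sample_id[meta$treatment == "heated" & meta$timepoint_h == 24][1]
  x[, hot24] <- c(3, 4)
  pl <- plasticity_distance(x, meta)
  expect_equal(pl$distance[pl$sample_id == hot24], 5)
  ref <- meta$sample_id[meta$treatment == "control" & meta$timepoint_h == 4]
  expect_equal(pl$distance[pl$sample_id %in% ref], c(0, 0))
  # gene order cannot matter
  pl2 <- plasticity_distance(x[c("g2", "g1"), ], meta)
  expect_equal(pl2$distance, pl$distance)
  expect_error(plasticity_distance(x, meta[meta$treatment == "heated", ]),
               "empty reference")
})

test_that("one-way ANOVA matches the squared-t identity for two groups", {
  set.seed(93)
  a <- rnorm(8); b <- rnorm(8, 1)
  res <- anova_oneway(c(a, b), rep(c("a", "b"), each = 8))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$f, tt$statistic[[1]]^2, tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)

  sym <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(sym$f, 0)

  flat <- anova_oneway(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_true(flat$flagged)
  expect_equal(flat$p, 1)
})

test_that("ANOVA detects a five-within-sd shift almost always", {
  hits <- 0
  for (i in 1:40) {
    set.seed(9400 + i)
    v <- c(rnorm(3), rnorm(3), rnorm(3, 5), rnorm(3))
    g <- rep(c("a", "b", "c", "d"), each = 3)
    if (anova_oneway(v, g)$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Tukey HSD flags exactly the shifted group's pairs", {
  set.seed(95)
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  g <- rep(c("a", "b", "far"), each = 5)
  tk <- tukey_hsd(v, g)
  far <- tk$group1 == "far" | tk$group2 == "far"
  expect_true(all(tk$significant[far]))
  expect_false(any(tk$significant[!far]))
  # p-values do not depend on pair order conventions
  expect_setequal(paste(pmin(tk$group1, tk$group2), pmax(tk$group1, tk$group2)),
                  c("a b", "a far", "b far"))

  same <- tukey_hsd(rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_false(any(same$significant))
  expect_identical(nrow(tukey_hsd(rnorm(5), rep("a", 5))), 0L)
})
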