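# Ordination and permutation statistics on transformed expression:
# PCA over the most variable genes, one-way PERMANOVA with a
# permutation (or exhaustive-enumeration) p-value, the transcriptome
# plasticity distance to the 4 h control centroid, and classical one-way
# ANOVA with Tukey HSD on the plasticity values.

#' PCA of samples over the most variable genes
#'
#' Gene-centered principal component analysis of the samples (columns) of
#' a log-scale expression matrix, computed over the `n_top` highest-variance
#' genes (the ordination convention for transcriptome data).
#'
#' @param x Transformed expression matrix (genes x samples), e.g. from
#'   [vst_transform()].
#' @param n_top Number of top-variance genes to use (default 500; capped at
#'   the number of genes).
#' @param center Gene-wise centering flag.
#' @return A list: `scores` (samples x components), `var_explained`
#'   (fraction of variance per component, non-increasing).
#' @export
pca_samples <- function(x, n_top = 500L, center = TRUE) {
  if (ncol(x) < 2L) stop("PCA needs >= 2 samples", call. = FALSE)
  v <- apply(x, 1L, stats::var)
  if (all(v == 0)) stop("constant matrix: no variance to decompose",
                        call. = FALSE)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(x)))]
  pc <- stats::prcomp(t(x[top, , drop = FALSE]), center = center,
                      scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, var_explained = ve)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

.permanova_f <- function(d2, groups) {
  n <- length(groups)
  a <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = ss_between / ss_total)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from total and within-group sums of squared distances
#' (Anderson's statistic), with a p-value from free permutation of the
#' group labels: `p = (1 + #[F* >= F]) / (n_perm + 1)`. With
#' `n_perm = "exhaustive"` all label permutations (including the identity)
#' are enumerated and `p = #[F* >= F] / n!` exactly.
#'
#' @param d Distance matrix (square symmetric non-negative, or a `dist`).
#' @param groups Group labels, one per sample; >= 2 distinct groups.
#' @param n_perm Number of random permutations (default 999) or
#'   `"exhaustive"` (only for small n).
#' @param seed Optional seed making the permutation p-value deterministic.
#' @return A list: `pseudo_f`, `r2`, `p`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(d < 0)) {
    stop("d must be a square symmetric non-negative distance matrix",
         call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) {
    stop("one group label per sample required", call. = FALSE)
  }
  if (length(unique(groups)) < 2L) {
    stop("all samples in one group: PERMANOVA undefined", call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    warning("group(s) with a single member; pseudo-F computed but weakly ",
            "supported", call. = FALSE)
  }
  d2 <- d^2
  obs <- .permanova_f(d2, groups)
  tol <- 1e-9 * max(1, abs(obs[["f"]]))
  n <- length(groups)
  if (identical(n_perm, "exhaustive")) {
    if (n > 9L) stop("exhaustive enumeration limited to n <= 9", call. = FALSE)
    perms <- .permutations(n)
    fs <- apply(perms, 1L, function(idx) {
      .permanova_f(d2, groups[idx])[["f"]]
    })
    p <- mean(fs >= obs[["f"]] - tol)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    fs <- vapply(seq_len(n_perm), function(i) {
      .permanova_f(d2, sample(groups))[["f"]]
    }, numeric(1))
    p <- (1 + sum(fs >= obs[["f"]] - tol)) / (n_perm + 1)
    n_used <- as.integer(n_perm)
  }
  list(pseudo_f = unname(obs[["f"]]), r2 = unname(obs[["r2"]]),
       p = p, n_permutations = n_used)
}

#' Transcriptome plasticity distance
#'
#' Euclidean distance of each sample's expression profile from the centroid
#' of the reference group (all 4 h control samples by default), computed in
#' the full transformed gene space or, optionally, in the plane of the
#' first two principal components.
#'
#' @param x Transformed expression matrix (genes x samples).
#' @param meta Metadata for its samples.
#' @param reference_treatment,reference_timepoint_h Reference group.
#' @param space `"full"` (default) or `"pc"` (first two PC scores).
#' @param n_top Top-variance gene count for the PC option.
#' @return Data.frame `sample_id`, `distance`, `treatment`, `timepoint_h`,
#'   `group` (treatment x timepoint label).
#' @export
plasticity_distance <- function(x, meta, reference_treatment = "control",
                                reference_timepoint_h = 4L,
                                space = c("full", "pc"), n_top = 500L) {
  space <- match.arg(space)
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  ref <- which(meta$treatment == reference_treatment &
                 meta$timepoint_h == reference_timepoint_h)
  if (length(ref) == 0L) {
    stop("empty reference group (", reference_treatment, ", ",
         reference_timepoint_h, " h)", call. = FALSE)
  }
  if (space == "pc") {
    pc <- pca_samples(x, n_top = n_top)
    prof <- t(pc$scores[, 1:2, drop = FALSE])
  } else {
    prof <- x
  }
  centroid <- rowMeans(prof[, ref, drop = FALSE])
  dist <- sqrt(colSums((prof - centroid)^2))
  data.frame(sample_id = meta$sample_id, distance = unname(dist),
             treatment = meta$treatment, timepoint_h = meta$timepoint_h,
             group = paste0(meta$treatment, "_", meta$timepoint_h, "h"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classical one-way ANOVA
#'
#' @param values Numeric response (e.g. plasticity distances).
#' @param groups Group labels (>= 2 groups, each with >= 2 members).
#' @return A list `f`, `p`, `flagged` (TRUE when the degenerate
#'   all-identical case forced the p = 1 convention).
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs >= 2 members", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    return(list(f = 0, p = 1, flagged = TRUE))
  }
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1L]]
  list(f = sm[["F value"]][1L], p = sm[["Pr(>F)"]][1L], flagged = FALSE)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-based pairwise group comparisons with family-wise
#' control, via [stats::TukeyHSD()].
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param alpha Family-wise significance level for the `significant` flag.
#' @return Data.frame `group1`, `group2`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`; empty for a single group.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  empty <- data.frame(group1 = character(0), group2 = character(0),
                      diff = numeric(0), lwr = numeric(0), upr = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (nlevels(groups) < 2L) return(empty)
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  # zero residual variance everywhere yields NaN adjusted p; report as 1
  tk[, "p adj"][is.nan(tk[, "p adj"])] <- 1
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group1 = vapply(pairs, `[`, character(1), 1L),
    group2 = vapply(pairs, `[`, character(1), 2L),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Plasticity analysis for one species
#'
#' Composes [plasticity_distance()], [anova_oneway()] and [tukey_hsd()]
#' over treatment x timepoint groups.
#'
#' @param x Transformed expression matrix (genes x samples).
#' @param meta Metadata for its samples.
#' @param ... Passed to [plasticity_distance()].
#' @return A list `distances`, `anova`, `tukey`.
#' @export
plasticity_analysis <- function(x, meta, ...) {
  d <- plasticity_distance(x, meta, ...)
  an <- anova_oneway(d$distance, d$group)
  tk <- tukey_hsd(d$distance, d$group)
  list(distances = d, anova = an, tukey = tk)
}
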