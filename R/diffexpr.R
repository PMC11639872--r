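# Two-group negative-binomial differential expression, exact-test style:
# libraries are rescaled to a common effective depth, a single common
# dispersion is estimated by maximizing the conditional likelihood given
# per-group totals, and each gene's p-value comes from the conditional
# distribution of the group-A total given the overall total. Thresholds
# follow the strict convention |log2FC| >= 4 and FDR < 0.05.

#' Rescale count columns to a common effective depth
#'
#' Counts are multiplied by `target / effective_lib` per sample and rounded
#' half-to-even. This is a documented approximation to full
#' quantile-to-quantile NB adjustment: it equalizes depths so the
#' conditional test's equal-proportion assumption holds, and the
#' enumeration-oracle tests pin the behaviour where it matters.
#'
#' @param counts Count matrix.
#' @param eff_lib Effective library sizes (library size x normalization
#'   factor); defaults to raw column sums.
#' @param target Common depth (default: geometric mean of `eff_lib`).
#' @return Integer matrix of pseudo-counts at common depth.
#' @export
equalize_depth <- function(counts, eff_lib = colSums(counts),
                           target = exp(mean(log(eff_lib)))) {
  if (any(eff_lib <= 0)) stop("effective library sizes must be positive",
                              call. = FALSE)
  out <- round(sweep(counts, 2L, target / eff_lib, "*"))
  storage.mode(out) <- "integer"
  out
}

.cond_loglik <- function(phi, counts, group_cols) {
  r <- 1 / phi
  ll <- 0
  for (cols in group_cols) {
    y <- counts[, cols, drop = FALSE]
    n <- length(cols)
    z <- rowSums(y)
    ll <- ll + sum(lgamma(y + r)) + length(z) * (lgamma(n * r) - n * lgamma(r)) -
      sum(lgamma(z + n * r))
  }
  ll
}

#' Estimate a single common NB dispersion
#'
#' Maximizes, over phi, the sum across genes of the NB conditional
#' log-likelihood given per-group totals, computed on pseudo-counts
#' equalized to a common depth (qCML-style). Groups with fewer than two
#' replicates carry no information and are ignored; with no replicated
#' group at all this errors and suggests a fixed-dispersion override.
#'
#' @param counts Count matrix.
#' @param groups Factor/character vector of group labels per sample.
#' @param eff_lib Effective library sizes (default raw column sums).
#' @param phi_max Upper search bound for phi.
#' @return Estimated dispersion (>= 0; exactly 0 when the conditional
#'   likelihood is maximized at the boundary, e.g. identical replicates).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       eff_lib = colSums(counts),
                                       phi_max = 5) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) {
    stop("groups must have one label per sample", call. = FALSE)
  }
  reps <- table(groups)
  usable <- names(reps)[reps >= 2L]
  if (length(usable) == 0L) {
    stop("no group has >= 2 replicates; dispersion is not estimable ",
         "(supply a fixed dispersion to the caller instead)", call. = FALSE)
  }
  eq <- equalize_depth(counts, eff_lib)
  group_cols <- lapply(usable, function(g) which(groups == g))
  informative <- rowSums(eq) > 0
  eq <- eq[informative, , drop = FALSE]
  if (nrow(eq) == 0L) return(0)
  obj <- function(t) .cond_loglik(exp(t), eq, group_cols)
  opt <- stats::optimize(obj, interval = c(log(1e-6), log(phi_max)),
                         maximum = TRUE, tol = 1e-6)
  at_zero <- obj(log(1e-8))
  if (at_zero >= opt$objective - 1e-8) return(0)
  phi <- exp(opt$maximum)
  if (phi <= 1.5e-6) 0 else phi
}

.exact_cond_pvalue <- function(za, z, n_a, n_b, phi) {
  if (z == 0L) return(1)
  if (phi <= 0) {
    pr <- n_a / (n_a + n_b)
    lower <- stats::pbinom(za, z, pr)
    upper <- stats::pbinom(za - 1L, z, pr, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }
  r <- 1 / phi
  x <- 0:z
  lp <- lgamma(x + n_a * r) - lfactorial(x) +
    lgamma(z - x + n_b * r) - lfactorial(z - x)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  lower <- sum(p[x <= za])
  upper <- sum(p[x >= za])
  min(1, 2 * min(lower, upper))
}

#' Exact conditional NB test between two groups
#'
#' Counts are equalized to a common effective depth; for each gene the
#' two-sided p-value is computed from the conditional distribution of the
#' group-A total given the overall total under a common-mean NB model with
#' dispersion `phi` (two-sided by doubling the smaller tail, capped at 1;
#' `phi = 0` reduces to the binomial conditional test). A gene with zero
#' total in both groups gets p = 1.
#'
#' @param counts_a,counts_b Integer count matrices (genes x replicates)
#'   with matching rows; group A is the reference (control).
#' @param dispersion Common NB dispersion phi (>= 0).
#' @param lib_sizes_a,lib_sizes_b Effective library sizes per column
#'   (default raw column sums).
#' @return Named numeric vector of two-sided p-values per gene.
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion,
                          lib_sizes_a = colSums(counts_a),
                          lib_sizes_b = colSums(counts_b)) {
  if (nrow(counts_a) != nrow(counts_b)) {
    stop("count matrices must have matching genes", call. = FALSE)
  }
  if (any(abs(counts_a - round(counts_a)) > 0) ||
      any(abs(counts_b - round(counts_b)) > 0)) {
    stop("exact test requires integer counts", call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  eff <- c(lib_sizes_a, lib_sizes_b)
  target <- exp(mean(log(eff)))
  eq_a <- equalize_depth(counts_a, lib_sizes_a, target)
  eq_b <- equalize_depth(counts_b, lib_sizes_b, target)
  za <- rowSums(eq_a)
  zb <- rowSums(eq_b)
  z <- za + zb
  n_a <- ncol(counts_a)
  n_b <- ncol(counts_b)
  p <- vapply(seq_along(z), function(i) {
    .exact_cond_pvalue(za[i], z[i], n_a, n_b, dispersion)
  }, numeric(1))
  names(p) <- rownames(counts_a)
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, via
#' [stats::p.adjust()] after validating the inputs.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values, same order and names.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify differential expression status
#'
#' `up` iff log2FC >= +`lfc_min` and FDR < `fdr_max`; `down` iff
#' log2FC <= -`lfc_min` and FDR < `fdr_max`; otherwise `ns`.
#'
#' @param log2fc,fdr Finite numeric vectors.
#' @param lfc_min Absolute log2 fold-change threshold (default 4).
#' @param fdr_max FDR threshold (strict; default 0.05).
#' @return Character vector in `{up, down, ns}`.
#' @export
classify_de <- function(log2fc, fdr, lfc_min = 4, fdr_max = 0.05) {
  ifelse(fdr < fdr_max & log2fc >= lfc_min, "up",
         ifelse(fdr < fdr_max & log2fc <= -lfc_min, "down", "ns"))
}

#' Time-matched control-vs-heated DE analysis for one species
#'
#' Applies the expression filter (>`min_cpm` CPM in >= `min_libraries`
#' libraries), computes TMM-effective library sizes, estimates a common
#' dispersion across the treatment x timepoint cells, and runs the exact
#' conditional test for each timepoint's control-vs-heated comparison.
#' Reported log2 fold changes use a prior count on TMM-scaled group mean
#' counts.
#'
#' @param counts Count matrix for one species' libraries.
#' @param meta Metadata rows matching those libraries.
#' @param min_cpm,min_libraries Expression-filter parameters.
#' @param lfc_min,fdr_max Classification thresholds.
#' @param dispersion Optional fixed dispersion (otherwise estimated).
#' @param prior Prior count for fold changes.
#' @return A list: `results` (data.frame gene_id, timepoint_h, log2fc,
#'   pvalue, fdr, status), `dispersion`, `retained` (filtered gene ids),
#'   `tmm` (normalization factors).
#' @export
run_de <- function(counts, meta, min_cpm = 2, min_libraries = 2L,
                   lfc_min = 4, fdr_max = 0.05, dispersion = NULL,
                   prior = 0.5) {
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("metadata missing for some count columns", call. = FALSE)
  }
  keep <- expression_filter(cpm(counts), min_cpm, min_libraries)
  filt <- counts[keep, , drop = FALSE]
  tmm <- tmm_factors(filt)
  eff <- colSums(filt) * tmm
  if (is.null(dispersion)) {
    cells <- interaction(meta$treatment, meta$timepoint_h, drop = TRUE)
    dispersion <- estimate_common_dispersion(filt, cells, eff_lib = eff)
  }
  norm <- sweep(filt, 2L, eff / mean(eff), "/")
  res <- lapply(sort(unique(meta$timepoint_h)), function(tp) {
    a <- which(meta$treatment == "control" & meta$timepoint_h == tp)
    b <- which(meta$treatment == "heated" & meta$timepoint_h == tp)
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    p <- nb_exact_test(filt[, a, drop = FALSE], filt[, b, drop = FALSE],
                       dispersion, eff[a], eff[b])
    fdr <- bh_adjust(p)
    lfc <- log2fc_with_prior(rowMeans(norm[, a, drop = FALSE]),
                             rowMeans(norm[, b, drop = FALSE]), prior)
    data.frame(gene_id = rownames(filt), timepoint_h = tp,
               log2fc = lfc, pvalue = p, fdr = fdr,
               status = classify_de(lfc, fdr, lfc_min, fdr_max),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  list(results = do.call(rbind, res), dispersion = dispersion,
       retained = keep, tmm = tmm)
}

#' Count up/down-regulated genes per stratum
#'
#' @param results DE results data.frame (`gene_id`, `timepoint_h`,
#'   `status`, optionally `species`).
#' @param bins Optional named vector mapping gene ids to origin bins
#'   (host/symbiont); when supplied, counts are additionally stratified by
#'   origin.
#' @return Data.frame with `n_up`, `n_down` per (species x) timepoint
#'   (x origin).
#' @export
summarize_deg_counts <- function(results, bins = NULL) {
  strata <- list(timepoint_h = results$timepoint_h)
  if (!is.null(results$species)) strata$species <- results$species
  if (!is.null(bins)) strata$origin <- unname(bins[results$gene_id])
  up <- stats::aggregate(list(n_up = results$status == "up"), strata, sum)
  down <- stats::aggregate(list(n_down = results$status == "down"), strata, sum)
  out <- merge(up, down)
  out$n_up <- as.integer(out$n_up)
  out$n_down <- as.integer(out$n_down)
  out[do.call(order, out[setdiff(colnames(out), c("n_up", "n_down"))]), ,
      drop = FALSE]
}

#' Heated-to-control relative expression as a TPM ratio
#'
#' Mean TPM over heated samples divided by mean TPM over time-matched
#' control samples; a zero denominator triggers a prior of 0.5 added to
#' both means, flagged in the output.
#'
#' @param tpm_matrix TPM matrix.
#' @param meta Metadata for its samples.
#' @param gene_set Genes to report (must exist in the matrix).
#' @param timepoint_h The time-matched comparison to use.
#' @param prior Prior added to both means when the control mean is zero.
#' @return Data.frame `gene_id`, `ratio`, `flagged`.
#' @export
relative_expression_ratio <- function(tpm_matrix, meta, gene_set,
                                      timepoint_h, prior = 0.5) {
  missing_genes <- setdiff(gene_set, rownames(tpm_matrix))
  if (length(missing_genes)) {
    stop("gene(s) absent from the TPM matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(colnames(tpm_matrix), meta$sample_id), , drop = FALSE]
  a <- which(meta$treatment == "control" & meta$timepoint_h == timepoint_h)
  b <- which(meta$treatment == "heated" & meta$timepoint_h == timepoint_h)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both control and heated groups must be non-empty at ",
         timepoint_h, " h", call. = FALSE)
  }
  mc <- rowMeans(tpm_matrix[gene_set, a, drop = FALSE])
  mh <- rowMeans(tpm_matrix[gene_set, b, drop = FALSE])
  flagged <- mc == 0
  ratio <- ifelse(flagged, (mh + prior) / (mc + prior), mh / mc)
  data.frame(gene_id = gene_set, ratio = ratio, flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}
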