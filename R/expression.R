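# Normalization and transformation: counts per million, transcripts per
# million, the expression filter, TMM composition factors, median-of-ratios
# size factors, a variance-stabilizing log transform, and fold changes with
# a prior count.

#' Counts per million
#'
#' @param counts Count matrix (genes x samples) with positive library sizes.
#' @return Numeric matrix of CPM values; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  libs <- colSums(counts)
  if (any(libs <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libs <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2L, libs, "/") * 1e6
}

#' Transcripts per million
#'
#' Length-normalized rates `count / length` rescaled so each column sums
#' to 1e6.
#'
#' @param counts Count matrix.
#' @param lengths Named (or positionally matching) vector of transcript
#'   lengths in nt; every gene must have a positive length.
#' @return Numeric matrix of TPM values.
#' @export
tpm <- function(counts, lengths) {
  if (!is.null(names(lengths))) {
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts) || anyNA(lengths)) {
    stop("missing length for gene(s): ",
         paste(utils::head(rownames(counts)[is.na(lengths)], 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  rate <- counts / lengths
  colsum <- colSums(rate)
  colsum[colsum == 0] <- 1  # all-zero library stays all-zero
  sweep(rate, 2L, colsum, "/") * 1e6
}

#' Minimum-expression filter
#'
#' Retains a gene iff its CPM exceeds `min_cpm` (strictly) in at least
#' `min_libraries` libraries.
#'
#' @param cpm_matrix CPM matrix from [cpm()].
#' @param min_cpm CPM threshold (strict inequality; default 2).
#' @param min_libraries Minimum number of qualifying libraries (default 2).
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(cpm_matrix, min_cpm = 2, min_libraries = 2L) {
  n_pass <- rowSums(cpm_matrix > min_cpm)
  rownames(cpm_matrix)[n_pass >= min_libraries]
}

#' Trimmed mean of M-values normalization factors
#'
#' Composition-correction factors computed from pairwise log-ratios to a
#' reference sample: genes with zero counts in either sample are excluded,
#' the log-ratios (M) are trimmed 30% on each side and the average
#' log-intensities (A) 5% on each side, and the factor is the weighted mean
#' of surviving M values (inverse asymptotic-variance weights). Factors are
#' rescaled to geometric mean 1. The reference is the sample whose CPM
#' 75th percentile is closest to the mean of those percentiles.
#'
#' @param counts Count matrix (>= 2 samples, no all-zero sample).
#' @param ref_sample Optional reference sample id (default: auto-pick).
#' @param logratio_trim,sum_trim Trim fractions on M and A.
#' @return Named numeric vector of normalization factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  if (ncol(counts) < 2L) stop("TMM needs >= 2 samples", call. = FALSE)
  libs <- colSums(counts)
  if (any(libs == 0)) {
    stop("all-zero sample: ", paste(colnames(counts)[libs == 0],
                                    collapse = ", "), call. = FALSE)
  }
  q75 <- apply(sweep(counts, 2L, libs, "/"), 2L, stats::quantile, probs = 0.75)
  if (is.null(ref_sample)) {
    ref_sample <- colnames(counts)[which.min(abs(q75 - mean(q75)))]
  }
  r <- counts[, ref_sample]
  nr <- libs[ref_sample]
  f <- vapply(seq_len(ncol(counts)), function(k) {
    x <- counts[, k]
    nk <- libs[k]
    keep <- x > 0 & r > 0
    if (!any(keep)) return(1)
    xk <- x[keep]; xr <- r[keep]
    m <- log2((xk / nk) / (xr / nr))
    a <- 0.5 * log2((xk / nk) * (xr / nr))
    # delta-method variance of M; weights are its inverse
    v <- (nk - xk) / (nk * xk) + (nr - xr) / (nr * xr)
    fin <- is.finite(m) & is.finite(a) & v > 0
    m <- m[fin]; a <- a[fin]; v <- v[fin]
    if (length(m) == 0L) return(1)
    # rank-based double trim (30% on M, 5% on A)
    nn <- length(m)
    lo_m <- floor(nn * logratio_trim) + 1
    hi_m <- nn + 1 - lo_m
    lo_a <- floor(nn * sum_trim) + 1
    hi_a <- nn + 1 - lo_a
    rm_ <- rank(m); ra_ <- rank(a)
    keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep2)) return(1)
    2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, numeric(1))
  names(f) <- colnames(counts)
  f / exp(mean(log(f)))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' geometric-mean pseudo-reference, computed over genes with positive
#' counts in all samples.
#'
#' @param counts Count matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors_median_ratio <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; cannot form the ",
         "geometric-mean reference (consider filtering samples or using ",
         "TMM-scaled library sizes instead)", call. = FALSE)
  }
  x <- counts[pos, , drop = FALSE]
  logref <- rowMeans(log(x))
  f <- apply(x, 2L, function(col) exp(stats::median(log(col) - logref)))
  names(f) <- colnames(counts)
  f
}

#' Variance-stabilizing log transform
#'
#' Depth-corrected log-scale values `log2(count / size_factor + 1)`,
#' playing the role of a regularized log transform for ordination,
#' PERMANOVA, and the plasticity distance. Size factors default to the
#' median-of-ratios factors.
#'
#' @param counts Count matrix.
#' @param size_factors Optional per-sample factors (default computed by
#'   [size_factors_median_ratio()]).
#' @return Numeric matrix of log2-scale values, same shape as `counts`.
#' @export
vst_transform <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  log2(sweep(counts, 2L, size_factors, "/") + 1)
}

#' Log2 fold change with a prior count
#'
#' `log2((mean_b + prior) / (mean_a + prior))`: the prior avoids infinite
#' fold changes for zero-containing means and is symmetric, so swapping the
#' groups flips the sign.
#'
#' @param mean_a,mean_b Non-negative group means (reference group first).
#' @param prior Prior count added to both means (default 0.5).
#' @return Numeric vector of log2 fold changes (b over a).
#' @export
log2fc_with_prior <- function(mean_a, mean_b, prior = 0.5) {
  if (any(mean_a < 0) || any(mean_b < 0)) {
    stop("means must be non-negative", call. = FALSE)
  }
  log2((mean_b + prior) / (mean_a + prior))
}
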