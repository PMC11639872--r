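# Independent oracles, written from the published definitions of each
# statistic (not from the package's code paths), used to pin behaviour.

# Conditional two-sided exact p-value by enumeration of the conditional
# pmf via dnbinom (the mean cancels under equal per-sample means, so any
# positive mu gives the same conditional distribution).
oracle_exact_p <- function(za, z, n_a, n_b, phi, mu = 10) {
  if (z == 0) return(1)
  x <- 0:z
  joint <- if (phi > 0) {
    stats::dnbinom(x, size = n_a / phi, mu = n_a * mu) *
      stats::dnbinom(z - x, size = n_b / phi, mu = n_b * mu)
  } else {
    stats::dpois(x, n_a * mu) * stats::dpois(z - x, n_b * mu)
  }
  p <- joint / sum(joint)
  lower <- sum(p[x <= za])
  upper <- sum(p[x >= za])
  min(1, 2 * min(lower, upper))
}

# Brute-force TMM: plain-loop weighted trimmed mean of M-values with
# rank-based double trimming, reference = sample whose CPM 75th
# percentile is closest to the mean of those percentiles.
oracle_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  libs <- colSums(counts)
  f75 <- apply(counts, 2, function(col) {
    stats::quantile(col / sum(col), 0.75, names = FALSE)
  })
  ref <- which.min(abs(f75 - mean(f75)))
  out <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts))) {
    ms <- c(); as_ <- c(); vs <- c()
    for (g in seq_len(nrow(counts))) {
      xk <- counts[g, k]; xr <- counts[g, ref]
      if (xk > 0 && xr > 0) {
        ms <- c(ms, log2((xk / libs[k]) / (xr / libs[ref])))
        as_ <- c(as_, 0.5 * log2((xk / libs[k]) * (xr / libs[ref])))
        vs <- c(vs, (libs[k] - xk) / (libs[k] * xk) +
                  (libs[ref] - xr) / (libs[ref] * xr))
      }
    }
    if (length(ms) == 0) { out[k] <- 1; next }
    n <- length(ms)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(ms) >= lo_m & rank(ms) <= hi_m &
      rank(as_) >= lo_a & rank(as_) <= hi_a
    out[k] <- if (any(keep)) {
      2^(sum(ms[keep] / vs[keep]) / sum(1 / vs[keep]))
    } else 1
  }
  names(out) <- colnames(counts)
  out / exp(mean(log(out)))
}

# Median-of-ratios size factors computed the long way (log-scale median
# of per-gene ratios to the geometric-mean reference, genes positive in
# all samples).
oracle_size_factors <- function(counts) {
  keep <- rep(TRUE, nrow(counts))
  for (g in seq_len(nrow(counts))) {
    if (any(counts[g, ] == 0)) keep[g] <- FALSE
  }
  x <- counts[keep, , drop = FALSE]
  out <- numeric(ncol(x))
  for (k in seq_len(ncol(x))) {
    ratios <- numeric(nrow(x))
    for (g in seq_len(nrow(x))) {
      ratios[g] <- log(x[g, k]) - mean(log(x[g, ]))
    }
    out[k] <- exp(stats::median(ratios))
  }
  out
}

# PERMANOVA pseudo-F via Gower double-centering and projection traces
# (a different algebraic route than pairwise within-group sums).
oracle_permanova_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- length(unique(groups))
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% (d^2) %*% j
  x <- stats::model.matrix(~ factor(groups))
  h <- x %*% solve(crossprod(x)) %*% t(x)
  ss_b <- sum(diag(h %*% g %*% h))
  ss_w <- sum(diag((diag(n) - h) %*% g %*% (diag(n) - h)))
  (ss_b / (a - 1)) / (ss_w / (n - a))
}

# All permutations of 1..n (recursive, independent of the package's).
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  out
}

# Exhaustive-permutation PERMANOVA p using the Gower-trace F.
oracle_permanova_p <- function(d, groups) {
  f_obs <- oracle_permanova_f(d, groups)
  perms <- oracle_perms(length(groups))
  fs <- apply(perms, 1, function(idx) oracle_permanova_f(d, groups[idx]))
  mean(fs >= f_obs - 1e-9 * max(1, abs(f_obs)))
}
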