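# Frontloading classification: an SRG is frontloaded when its basal
# (control) expression exceeds the transcriptome median while its response
# to heat stays small (|log2FC| < 2 at both timepoints); low-basal SRGs
# that are upregulated under heat are the contrasting "responsive" class.

#' Basal (constitutive) expression per gene
#'
#' Mean normalized expression across all control libraries (both
#' timepoints), the operational definition of expression "at 28 degC".
#'
#' @param norm_matrix Normalized expression matrix (CPM by default
#'   elsewhere in the pipeline).
#' @param meta Metadata for its samples.
#' @return Named numeric vector of per-gene basal values.
#' @export
basal_expression <- function(norm_matrix, meta) {
  meta <- meta[match(colnames(norm_matrix), meta$sample_id), , drop = FALSE]
  ctl <- which(meta$treatment == "control")
  if (length(ctl) == 0L) stop("no control samples", call. = FALSE)
  rowMeans(norm_matrix[, ctl, drop = FALSE])
}

#' Frontloading rule for a single gene (vectorized)
#'
#' TRUE iff basal expression strictly exceeds the transcriptome median and
#' the absolute log2 fold change under heat is strictly below `lfc_max` at
#' both timepoints.
#'
#' @param basal Basal expression value(s).
#' @param transcriptome_median Median basal expression of all genes.
#' @param log2fc_4h,log2fc_24h Heated-vs-control log2 fold changes.
#' @param lfc_max Stability bound (strict; default 2).
#' @return Logical vector.
#' @export
classify_frontloaded <- function(basal, transcriptome_median,
                                 log2fc_4h, log2fc_24h, lfc_max = 2) {
  basal > transcriptome_median &
    abs(log2fc_4h) < lfc_max & abs(log2fc_24h) < lfc_max
}

#' Frontloading calls for the SRG catalog of one species
#'
#' Computes basal expression from control libraries, the transcriptome
#' median over all genes in the matrix, pulls per-timepoint fold changes
#' and DE status from the DE results, and flags each SRG as frontloaded or
#' low-basal-responsive (basal at or below the median and significantly
#' upregulated at either timepoint). The two flags are mutually exclusive
#' by construction. Genes without fold-change estimates (filtered out of
#' the DE analysis) are treated as showing no response (log2FC 0): a gene
#' too weakly expressed to test cannot exceed the stability bound.
#'
#' @param norm_matrix Normalized expression matrix for all genes of the
#'   species (unit configurable upstream: CPM by default).
#' @param meta Metadata for its samples.
#' @param de_results DE results data.frame with `gene_id`, `timepoint_h`,
#'   `log2fc`, `status`.
#' @param catalog SRG catalog (`gene_id`, `family`, `category`) restricted
#'   to this species.
#' @param lfc_max Stability bound (default 2).
#' @param timepoint_rule `"both"` (default: stable at 4 h AND 24 h) or
#'   `"either"` (stable at at least one timepoint).
#' @return Data.frame, one row per SRG: `gene_id`, `family`, `category`,
#'   `basal_expr`, `transcriptome_median`, `log2fc_4h`, `log2fc_24h`,
#'   `status_4h`, `status_24h`, `frontloaded`, `low_basal_responsive`.
#' @export
frontloading_calls <- function(norm_matrix, meta, de_results, catalog,
                               lfc_max = 2,
                               timepoint_rule = c("both", "either")) {
  timepoint_rule <- match.arg(timepoint_rule)
  absent <- setdiff(catalog$gene_id, rownames(norm_matrix))
  if (length(absent)) {
    message(length(absent), " catalog gene(s) absent from the expression ",
            "matrix (e.g. dropped at binning); excluded from the calls")
    catalog <- catalog[!catalog$gene_id %in% absent, , drop = FALSE]
  }
  basal <- basal_expression(norm_matrix, meta)
  med <- stats::median(basal)
  tps <- sort(unique(de_results$timepoint_h))
  get_col <- function(tp, col, default) {
    d <- de_results[de_results$timepoint_h == tp, , drop = FALSE]
    v <- d[[col]][match(catalog$gene_id, d$gene_id)]
    v[is.na(v)] <- default
    v
  }
  fc4 <- get_col(tps[1L], "log2fc", 0)
  fc24 <- if (length(tps) > 1L) get_col(tps[2L], "log2fc", 0) else fc4
  st4 <- get_col(tps[1L], "status", "ns")
  st24 <- if (length(tps) > 1L) get_col(tps[2L], "status", "ns") else st4
  b <- unname(basal[catalog$gene_id])
  stable <- if (timepoint_rule == "both") {
    abs(fc4) < lfc_max & abs(fc24) < lfc_max
  } else {
    abs(fc4) < lfc_max | abs(fc24) < lfc_max
  }
  front <- b > med & stable
  low_resp <- b <= med & (st4 == "up" | st24 == "up")
  data.frame(
    gene_id = catalog$gene_id, family = catalog$family,
    category = catalog$category,
    basal_expr = b, transcriptome_median = med,
    log2fc_4h = fc4, log2fc_24h = fc24,
    status_4h = st4, status_24h = st24,
    frontloaded = front, low_basal_responsive = low_resp,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Distribution summary of SRG expression
#'
#' Medians of the all-gene and SRG basal-expression distributions, counts
#' of SRGs above/below the transcriptome median, and mean absolute log2
#' fold change over SRGs at each timepoint.
#'
#' @param norm_matrix Normalized expression matrix (all genes).
#' @param meta Metadata for its samples.
#' @param catalog SRG catalog for this species.
#' @param de_results DE results data.frame.
#' @return A list: `median_all`, `median_srg`, `n_above`, `n_below`,
#'   `mean_abs_log2fc` (named by timepoint).
#' @export
srg_expression_summary <- function(norm_matrix, meta, catalog, de_results) {
  basal <- basal_expression(norm_matrix, meta)
  med_all <- stats::median(basal)
  srg_basal <- basal[intersect(catalog$gene_id, names(basal))]
  fc <- vapply(sort(unique(de_results$timepoint_h)), function(tp) {
    d <- de_results[de_results$timepoint_h == tp &
                      de_results$gene_id %in% catalog$gene_id, , drop = FALSE]
    if (nrow(d) == 0L) NA_real_ else mean(abs(d$log2fc))
  }, numeric(1))
  names(fc) <- paste0(sort(unique(de_results$timepoint_h)), "h")
  list(median_all = med_all,
       median_srg = stats::median(srg_basal),
       n_above = sum(srg_basal > med_all),
       n_below = sum(srg_basal <= med_all),
       mean_abs_log2fc = fc)
}

#' Summaries of low-basal (responsive) SRGs
#'
#' For SRGs with basal expression at or below the transcriptome median:
#' mean absolute log2 fold change at each timepoint; and, for the subset
#' additionally upregulated (status `up` at that timepoint), the mean
#' log2 fold change overall and per SRG family.
#'
#' @param calls Calls data.frame from [frontloading_calls()].
#' @return A list: `low_basal` (data.frame timepoint_h, n,
#'   mean_abs_log2fc), `upregulated` (data.frame timepoint_h, n,
#'   mean_log2fc), `upregulated_by_family` (data.frame family,
#'   timepoint_h, n, mean_log2fc). Components are empty data.frames when
#'   the subsets are empty.
#' @export
responsive_srg_summary <- function(calls) {
  low <- calls[calls$basal_expr <= calls$transcriptome_median, , drop = FALSE]
  tps <- c(4L, 24L)
  fc_cols <- c("log2fc_4h", "log2fc_24h")
  st_cols <- c("status_4h", "status_24h")
  if (nrow(low) == 0L) {
    empty <- data.frame(timepoint_h = integer(0), n = integer(0))
    return(list(low_basal = cbind(empty, mean_abs_log2fc = numeric(0)),
                upregulated = cbind(empty, mean_log2fc = numeric(0)),
                upregulated_by_family = data.frame(
                  family = character(0), timepoint_h = integer(0),
                  n = integer(0), mean_log2fc = numeric(0))))
  }
  low_basal <- data.frame(
    timepoint_h = tps, n = nrow(low),
    mean_abs_log2fc = vapply(fc_cols, function(cc) mean(abs(low[[cc]])),
                             numeric(1)),
    row.names = NULL)
  up_rows <- lapply(seq_along(tps), function(i) {
    u <- low[low[[st_cols[i]]] == "up", , drop = FALSE]
    data.frame(timepoint_h = tps[i], n = nrow(u),
               mean_log2fc = if (nrow(u)) mean(u[[fc_cols[i]]]) else NA_real_)
  })
  fam_rows <- lapply(seq_along(tps), function(i) {
    u <- low[low[[st_cols[i]]] == "up", , drop = FALSE]
    if (nrow(u) == 0L) return(NULL)
    ag <- stats::aggregate(list(mean_log2fc = u[[fc_cols[i]]]),
                           list(family = u$family), mean)
    ag$n <- as.integer(table(u$family)[ag$family])
    ag$timepoint_h <- tps[i]
    ag[, c("family", "timepoint_h", "n", "mean_log2fc")]
  })
  list(low_basal = low_basal,
       upregulated = do.call(rbind, up_rows),
       upregulated_by_family = do.call(rbind, fam_rows))
}

#' Per-family frontloading report with enrichment flags
#'
#' Counts frontloaded genes per SRG family and tests each family for
#' enrichment of frontloaded genes relative to the catalog-wide
#' frontloaded fraction with a one-sided hypergeometric test,
#' BH-adjusted across families.
#'
#' @param calls Calls data.frame from [frontloading_calls()].
#' @param q_max Enrichment flag threshold on the BH-adjusted p (default
#'   0.05).
#' @return Data.frame `family`, `category`, `n_genes`, `n_frontloaded`,
#'   `p_enrich`, `q_enrich`, `enriched`.
#' @export
frontloading_report <- function(calls, q_max = 0.05) {
  fams <- unique(calls$family)
  n_total <- nrow(calls)
  k_total <- sum(calls$frontloaded)
  rows <- lapply(fams, function(fa) {
    sub <- calls[calls$family == fa, , drop = FALSE]
    n <- nrow(sub)
    k <- sum(sub$frontloaded)
    p <- stats::phyper(k - 1L, k_total, n_total - k_total, n,
                       lower.tail = FALSE)
    data.frame(family = fa, category = sub$category[1L], n_genes = n,
               n_frontloaded = k, p_enrich = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_enrich <- stats::p.adjust(out$p_enrich, method = "BH")
  out$enriched <- out$q_enrich < q_max & out$n_frontloaded > 0L
  out[order(-out$n_frontloaded), , drop = FALSE]
}
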