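# Isoform-level cleanup of a de novo assembly quantified with RSEM:
# drop isoforms that carry no expression (zero IsoPct), keep one
# representative isoform per transcript, and retain coding sequences only.

.check_isoform_table <- function(records) {
  need <- c("transcript_id", "isoform_id", "iso_pct", "length", "is_coding")
  missing_cols <- setdiff(need, colnames(records))
  if (length(missing_cols)) {
    stop("isoform table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(records$iso_pct < 0 | records$iso_pct > 100 * 1e6, na.rm = TRUE)) {
    stop("iso_pct must be non-negative", call. = FALSE)
  }
  if (any(records$length < 1, na.rm = TRUE)) {
    stop("isoform length must be >= 1", call. = FALSE)
  }
  records
}

#' Drop isoforms with zero combined IsoPct
#'
#' Removes isoform records whose combined isoform percentage (summed across
#' libraries) is zero; transcripts whose isoforms are all unexpressed vanish
#' entirely and are reported via message.
#'
#' @param records Isoform data.frame with columns `transcript_id`,
#'   `isoform_id`, `iso_pct` (combined across libraries), `length`,
#'   `is_coding`.
#' @return The filtered data.frame.
#' @export
drop_zero_isopct <- function(records) {
  .check_isoform_table(records)
  keep <- records$iso_pct > 0
  lost <- setdiff(unique(records$transcript_id),
                  unique(records$transcript_id[keep]))
  if (length(lost)) {
    message(length(lost), " transcript(s) removed entirely (all isoforms ",
            "at zero IsoPct): ", paste(utils::head(lost, 5), collapse = ", "),
            if (length(lost) > 5) ", ..." else "")
  }
  records[keep, , drop = FALSE]
}

#' Select one representative isoform per transcript
#'
#' Keeps, per transcript, the isoform with the highest combined IsoPct;
#' ties are broken by longest length, and any remaining ties by
#' lexicographic isoform id (reported via message). Records with zero
#' IsoPct must already have been removed.
#'
#' @param records Isoform data.frame (see [drop_zero_isopct()]).
#' @return A data.frame with exactly one row per transcript.
#' @export
select_representative_isoform <- function(records) {
  .check_isoform_table(records)
  if (nrow(records) == 0L) return(records)
  ord <- order(records$transcript_id, -records$iso_pct, -records$length,
               records$isoform_id)
  sorted <- records[ord, , drop = FALSE]
  first <- !duplicated(sorted$transcript_id)
  # report transcripts whose winner was decided lexicographically
  runner <- which(!first)
  if (length(runner)) {
    prev <- runner - 1L
    tied <- runner[first[prev] &
                     sorted$transcript_id[runner] == sorted$transcript_id[prev] &
                     sorted$iso_pct[runner] == sorted$iso_pct[prev] &
                     sorted$length[runner] == sorted$length[prev]]
    if (length(tied)) {
      message(length(tied), " transcript(s) resolved by lexicographic ",
              "isoform id tie-break")
    }
  }
  out <- sorted[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain protein-coding isoform records only
#'
#' @param records Isoform data.frame with logical `is_coding`.
#' @return The coding subset; an empty result triggers a warning.
#' @export
coding_filter <- function(records) {
  .check_isoform_table(records)
  out <- records[as.logical(records$is_coding), , drop = FALSE]
  if (nrow(out) == 0L && nrow(records) > 0L) {
    warning("no protein-coding isoforms survive the filter", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Full isoform-selection pipeline
#'
#' Composes [drop_zero_isopct()], [select_representative_isoform()] and
#' [coding_filter()]; the composition is idempotent.
#'
#' @param records Isoform data.frame.
#' @return One coding representative isoform per surviving transcript.
#' @export
filter_isoforms <- function(records) {
  coding_filter(select_representative_isoform(drop_zero_isopct(records)))
}

#' Read RSEM isoforms.results files into the isoform-table layout
#'
#' Maps RSEM's columns onto the pipeline's isoform records: RSEM's
#' `transcript_id` becomes `isoform_id`, its `gene_id` becomes
#' `transcript_id` (the parent), and `IsoPct` values are summed across the
#' supplied per-library files to form the combined IsoPct.
#'
#' @param paths One or more isoforms.results paths (one per library).
#' @param is_coding Optional logical vector or named coding flags per
#'   isoform id; defaults to TRUE for all (coding prediction is an
#'   upstream input, not computed here).
#' @return An isoform data.frame usable with [filter_isoforms()].
#' @export
read_rsem_isoforms <- function(paths, is_coding = NULL) {
  tabs <- lapply(paths, function(p) {
    df <- .read_tsv(p)
    need <- c("transcript_id", "gene_id", "length", "IsoPct")
    if (!all(need %in% colnames(df))) {
      stop("RSEM isoform file missing column(s): ",
           paste(setdiff(need, colnames(df)), collapse = ", "), call. = FALSE)
    }
    df[need]
  })
  all_tab <- do.call(rbind, tabs)
  agg <- stats::aggregate(IsoPct ~ transcript_id + gene_id + length,
                          data = all_tab, FUN = sum)
  out <- data.frame(
    transcript_id = agg$gene_id,
    isoform_id = agg$transcript_id,
    iso_pct = agg$IsoPct,
    length = as.integer(agg$length),
    stringsAsFactors = FALSE
  )
  out$is_coding <- if (is.null(is_coding)) {
    TRUE
  } else if (!is.null(names(is_coding))) {
    unname(is_coding[out$isoform_id])
  } else {
    is_coding
  }
  out
}
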