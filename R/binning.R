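# Host/symbiont transcript binning from best sequence-similarity hits:
# a transcript is host if its best surviving hit is to Cnidaria, symbiont
# if to Dinophyceae, and dropped otherwise (contaminant or no hit).

.rank_hits <- function(hits) {
  order(hits$evalue, -hits$pct_identity, -hits$bitscore, hits$subject_id)
}

#' Best hit for a single query
#'
#' Discards hits above the e-value cutoff and ranks survivors by e-value
#' ascending, percent identity descending, bitscore descending, and
#' subject id lexicographic (the standard best-hit convention: lowest
#' e-value primary, identity resolving exact ties).
#'
#' @param hits Hit data.frame (rows for one query).
#' @param evalue_max E-value cutoff (default 1e-5).
#' @return The single best hit row, or `NULL` if none survives.
#' @export
best_hit <- function(hits, evalue_max = 1e-5) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits[.rank_hits(hits)[1L], , drop = FALSE]
}

#' Best hit per query over a whole hit table
#'
#' Vectorized form of [best_hit()].
#'
#' @param hits Hit data.frame for many queries.
#' @param evalue_max E-value cutoff.
#' @return A data.frame with one row per query that has a surviving hit.
#' @export
best_hits_per_query <- function(hits, evalue_max = 1e-5) {
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, hits$evalue, -hits$pct_identity,
               -hits$bitscore, hits$subject_id)
  sorted <- hits[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign every gene to the host, symbiont, or dropped bin
#'
#' @param gene_ids Character vector of all genes to bin (genes without any
#'   hit are assigned `dropped`).
#' @param hits Hit table with taxon labels (`Cnidaria`/`Dinophyceae`
#'   already resolved; matching is by exact label).
#' @param evalue_max E-value cutoff for [best_hits_per_query()].
#' @return A data.frame `gene_id`, `bin`, `best_subject`, `best_taxon`,
#'   `best_evalue`; every input gene receives exactly one bin.
#' @export
assign_bins <- function(gene_ids, hits, evalue_max = 1e-5) {
  best <- best_hits_per_query(hits, evalue_max = evalue_max)
  idx <- match(gene_ids, best$query_id)
  taxon <- best$subject_taxon[idx]
  bin <- ifelse(is.na(taxon), "dropped",
                ifelse(taxon == "Cnidaria", "host",
                       ifelse(taxon == "Dinophyceae", "symbiont", "dropped")))
  data.frame(
    gene_id = gene_ids,
    bin = bin,
    best_subject = best$subject_id[idx],
    best_taxon = taxon,
    best_evalue = best$evalue[idx],
    stringsAsFactors = FALSE
  )
}

#' Summarize symbiont reference-genome affiliations
#'
#' For transcripts in the symbiont bin, tallies the reference label
#' (e.g. Smic/Bmin/Cgor/Dtre/Fkaw) of the best hit in the
#' Symbiodiniaceae-genome search and reports counts and fractions of the
#' symbiont bin with a best reference hit.
#'
#' @param assignments Bin assignment data.frame from [assign_bins()].
#' @param sym_hits Hit table against Symbiodiniaceae references, with
#'   `subject_taxon` holding the reference label.
#' @param evalue_max E-value cutoff.
#' @return A data.frame `reference`, `n`, `fraction` (fractions sum to 1);
#'   empty with a warning when the symbiont bin is empty.
#' @export
affiliation_summary <- function(assignments, sym_hits, evalue_max = 1e-5) {
  sym_genes <- assignments$gene_id[assignments$bin == "symbiont"]
  empty <- data.frame(reference = character(0), n = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
  if (length(sym_genes) == 0L) {
    warning("empty symbiont bin: no affiliations to summarize", call. = FALSE)
    return(empty)
  }
  best <- best_hits_per_query(
    sym_hits[sym_hits$query_id %in% sym_genes, , drop = FALSE],
    evalue_max = evalue_max)
  if (nrow(best) == 0L) {
    warning("no symbiont transcript has a reference best hit", call. = FALSE)
    return(empty)
  }
  tab <- sort(table(best$subject_taxon), decreasing = TRUE)
  data.frame(reference = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
}

#' Per-bin G+C content
#'
#' GC percent per bin computed as (G+C)/(A+C+G+T) over all assigned
#' sequences pooled, with ambiguous bases excluded from the denominator.
#'
#' @param sequences A [Biostrings::DNAStringSet] (or FASTA path) named by
#'   gene id.
#' @param assignments Bin assignment data.frame from [assign_bins()].
#' @return Named numeric vector of GC percentages per bin present.
#' @export
gc_content <- function(sequences, assignments) {
  if (is.character(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  bins <- setdiff(unique(assignments$bin), "dropped")
  if (length(sequences) == 0L) stop("no sequences supplied", call. = FALSE)
  out <- vapply(bins, function(b) {
    ids <- intersect(assignments$gene_id[assignments$bin == b],
                     names(sequences))
    if (length(ids) == 0L) return(NA_real_)
    freq <- Biostrings::letterFrequency(sequences[ids], c("A", "C", "G", "T"))
    tot <- sum(freq)
    if (tot == 0) stop("zero-length sequence set in bin ", b, call. = FALSE)
    100 * sum(freq[, c("C", "G")]) / tot
  }, numeric(1))
  names(out) <- bins
  out
}
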