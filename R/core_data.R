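# Canonical tabular dialect for the whole pipeline: tab-delimited UTF-8,
# '#' comment lines ignored, header row present. Matches RSEM/OrthoFinder
# conventions.

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample count matrix
#'
#' Reads a tab-delimited count matrix whose first column holds gene
#' identifiers and whose header row holds sample identifiers. Counts must be
#' non-negative integers; fractional values within `round_tol` of an integer
#' (e.g. RSEM expected counts) are rounded half-to-even with a warning,
#' because the downstream exact test requires integer counts.
#'
#' @param path Path to a TSV file (`#` comment lines are ignored).
#' @param round_tol Maximum absolute deviation from an integer before a
#'   value is considered malformed rather than an expected count. Values
#'   within the tolerance of an integer pass silently; larger fractional
#'   values are rounded half-to-even with a warning.
#' @return An integer matrix with gene ids as rownames and sample ids as
#'   colnames. Every column sum (library size) is positive.
#' @export
read_count_matrix <- function(path, round_tol = 1e-8) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("no data rows in count matrix: ", path, call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    line <- which(ids == dup)[2L] + 1L
    stop("duplicate gene id '", dup, "' at line ", line, " of ", path,
         call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids in header of ", path, call. = FALSE)
  }
  if (!is.numeric(m)) {
    num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
    line <- which(rowSums(is.na(num)) > 0)[1L] + 1L
    stop("malformed (non-numeric) count at line ", line, " of ", path,
         call. = FALSE)
  }
  if (anyNA(m)) {
    line <- which(apply(is.na(m), 1L, any))[1L] + 1L
    stop("malformed (missing) count at line ", line, " of ", path,
         call. = FALSE)
  }
  if (any(m < 0)) {
    line <- which(apply(m < 0, 1L, any))[1L] + 1L
    stop("negative count at line ", line, " of ", path, call. = FALSE)
  }
  frac <- abs(m - round(m))
  if (any(frac > round_tol)) {
    warning("non-integer counts rounded half-to-even (expected-count input)",
            call. = FALSE)
  }
  m <- round(m)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_count_matrix(m)
  m
}

#' Validate a count matrix
#'
#' Asserts the count-matrix invariants: integer-valued, non-negative,
#' unique gene and sample identifiers, and positive library sizes.
#'
#' @param counts Matrix with gene rownames and sample colnames.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_count_matrix <- function(counts) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 0)) {
    stop("counts must be integers", call. = FALSE)
  }
  libs <- colSums(counts)
  if (any(libs <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[libs <= 0], collapse = ", "), call. = FALSE)
  }
  invisible(counts)
}

#' Write a count matrix as TSV
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @param id_column Name for the gene-id column (first column).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, id_column = "gene_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  .write_tsv(df, path)
}

#' Read a numeric matrix (e.g. CPM/TPM/vst values) from TSV
#'
#' Like [read_count_matrix()] but without the integer constraint; used for
#' normalized matrices.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("no data rows in matrix: ", path, call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path, call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    stop("malformed numeric matrix in ", path, call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write a numeric matrix as TSV
#' @param x Numeric matrix with rownames/colnames.
#' @param path Output path.
#' @param id_column Name for the row-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  .write_tsv(df, path)
}

.TREATMENTS <- c("control", "heated")

#' Read per-sample design metadata
#'
#' Expects columns `sample_id`, `species`, `colony`, `treatment`,
#' `timepoint_h`. Treatment labels are canonicalized case-insensitively to
#' `control`/`heated`.
#'
#' @param path Path to a metadata TSV.
#' @param timepoints Declared set of exposure durations in hours.
#' @return A data.frame of validated sample metadata.
#' @export
read_sample_metadata <- function(path, timepoints = c(4L, 24L)) {
  df <- .read_tsv(path)
  validate_sample_metadata(df, timepoints = timepoints)
}

#' Validate sample metadata
#'
#' @param meta A data.frame with the metadata columns.
#' @param timepoints Declared set of exposure durations in hours.
#' @return The canonicalized metadata data.frame.
#' @export
validate_sample_metadata <- function(meta, timepoints = c(4L, 24L)) {
  need <- c("sample_id", "species", "colony", "treatment", "timepoint_h")
  missing_cols <- setdiff(need, colnames(meta))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id: ",
         meta$sample_id[duplicated(meta$sample_id)][1L], call. = FALSE)
  }
  meta$treatment <- tolower(trimws(as.character(meta$treatment)))
  bad <- setdiff(unique(meta$treatment), .TREATMENTS)
  if (length(bad)) {
    stop("unknown treatment level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  meta$timepoint_h <- as.integer(meta$timepoint_h)
  bad_tp <- setdiff(unique(meta$timepoint_h), timepoints)
  if (length(bad_tp)) {
    stop("timepoint_h outside declared set {",
         paste(timepoints, collapse = ", "), "}: ",
         paste(bad_tp, collapse = ", "), call. = FALSE)
  }
  meta$species <- as.character(meta$species)
  meta$colony <- as.character(meta$colony)
  meta
}

#' Write sample metadata as TSV
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) .write_tsv(meta, path)

#' Cross-check a count matrix against its design metadata
#'
#' Asserts that the sample sets of counts and metadata match exactly and
#' summarizes replication per design cell (species x treatment x timepoint).
#' Cells with no replicates are flagged with a warning entry rather than an
#' error, so incomplete designs are visible but loadable.
#'
#' @param meta Validated sample metadata.
#' @param counts Validated count matrix.
#' @return A list with `cells` (data.frame of per-cell replicate counts) and
#'   `warnings` (character vector; empty when the design is complete).
#' @export
validate_design <- function(meta, counts) {
  validate_count_matrix(counts)
  orphans_counts <- setdiff(colnames(counts), meta$sample_id)
  orphans_meta <- setdiff(meta$sample_id, colnames(counts))
  if (length(orphans_counts)) {
    stop("sample(s) in counts absent from metadata: ",
         paste(orphans_counts, collapse = ", "), call. = FALSE)
  }
  if (length(orphans_meta)) {
    stop("sample(s) in metadata absent from counts: ",
         paste(orphans_meta, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(species = unique(meta$species),
                      treatment = .TREATMENTS,
                      timepoint_h = sort(unique(meta$timepoint_h)),
                      stringsAsFactors = FALSE)
  grid$n_replicates <- mapply(function(sp, tr, tp) {
    sum(meta$species == sp & meta$treatment == tr & meta$timepoint_h == tp)
  }, grid$species, grid$treatment, grid$timepoint_h)
  warn <- character(0)
  empty <- grid$n_replicates == 0L
  if (any(empty)) {
    warn <- sprintf("design cell with 0 replicates: %s/%s/%dh",
                    grid$species[empty], grid$treatment[empty],
                    grid$timepoint_h[empty])
  }
  list(cells = grid, warnings = warn)
}

#' Read a BLAST tabular hit file
#'
#' Reads 12-column outfmt-6 (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`) with an optional 13th taxon
#' column (phylum/class label such as `Cnidaria`/`Dinophyceae`, or a
#' reference-genome label such as `Dtre`). A header line is optional; files
#' without one are detected by column count and typing.
#'
#' @param path Path to the hit table.
#' @return A data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `evalue`, `bitscore`, and `subject_taxon` (NA when the
#'   13th column is absent).
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- grepl("qseqid|query_id", first)
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 12L) {
    stop("hit table must have >= 12 outfmt-6 columns: ", path, call. = FALSE)
  }
  out <- data.frame(
    query_id = as.character(df[[1L]]),
    subject_id = as.character(df[[2L]]),
    pct_identity = as.numeric(df[[3L]]),
    evalue = as.numeric(df[[11L]]),
    bitscore = as.numeric(df[[12L]]),
    subject_taxon = if (ncol(df) >= 13L) as.character(df[[13L]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(out$pct_identity < 0 | out$pct_identity > 100, na.rm = TRUE)) {
    stop("pct_identity outside [0, 100] in ", path, call. = FALSE)
  }
  if (any(out$evalue < 0, na.rm = TRUE)) {
    stop("negative e-value in ", path, call. = FALSE)
  }
  out
}

#' Write a hit table in outfmt-6 + taxon layout
#' @param hits Hit data.frame from [read_hit_table()] or the simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  df <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = hits$pct_identity, length = hits$length %||% 100L,
    mismatch = hits$mismatch %||% 0L, gapopen = hits$gapopen %||% 0L,
    qstart = 1L, qend = hits$length %||% 100L,
    sstart = 1L, send = hits$length %||% 100L,
    evalue = hits$evalue, bitscore = hits$bitscore,
    staxon = hits$subject_taxon, stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a protein-domain annotation table
#'
#' Simplified HMMER/PFAM-style table with columns `gene_id`,
#' `domain_accession`, `domain_evalue`.
#'
#' @param path Path to the domain TSV.
#' @return A validated data.frame.
#' @export
read_domain_table <- function(path) {
  df <- .read_tsv(path)
  need <- c("gene_id", "domain_accession", "domain_evalue")
  if (!all(need %in% colnames(df))) {
    stop("domain table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$domain_evalue <- as.numeric(df$domain_evalue)
  if (any(df$domain_evalue < 0, na.rm = TRUE)) {
    stop("negative domain e-value in ", path, call. = FALSE)
  }
  df[need]
}

#' Read an SRG family definition table
#'
#' Columns: `family` (unique name), `category` (one of chemical, pathogen,
#' wounding), `accessions` (comma-separated PFAM-style accessions defining
#' the family).
#'
#' @param path Path to the family TSV.
#' @return A data.frame with list-column `accessions` expanded into a
#'   comma-separated string; helper [family_accession_list()] splits it.
#' @export
read_srg_families <- function(path) {
  df <- .read_tsv(path)
  need <- c("family", "category", "accessions")
  if (!all(need %in% colnames(df))) {
    stop("SRG family table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_srg_families(df[need])
}

#' Validate an SRG family definition table
#' @param families Data.frame with columns family, category, accessions.
#' @return The validated data.frame.
#' @export
validate_srg_families <- function(families) {
  if (anyDuplicated(families$family)) {
    stop("duplicate SRG family names", call. = FALSE)
  }
  bad <- setdiff(unique(families$category),
                 c("chemical", "pathogen", "wounding"))
  if (length(bad)) {
    stop("unknown SRG category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  acc <- family_accession_list(families)
  if (any(lengths(acc) == 0L)) {
    stop("family with empty defining-domain set: ",
         paste(families$family[lengths(acc) == 0L], collapse = ", "),
         call. = FALSE)
  }
  families
}

#' Split the comma-separated accession column of a family table
#' @param families SRG family definition data.frame.
#' @return Named list of accession character vectors, one per family, in
#'   file order (which is also the assignment priority order).
#' @export
family_accession_list <- function(families) {
  acc <- strsplit(as.character(families$accessions), ",")
  acc <- lapply(acc, function(a) trimws(a[nzchar(trimws(a))]))
  names(acc) <- families$family
  acc
}

#' Read an orthogroup gene-count table
#'
#' OrthoFinder `Orthogroups.GeneCount`-style: first column orthogroup id,
#' remaining columns per-species gene counts (a trailing `Total` column, if
#' present, is dropped).
#'
#' @param path Path to the orthogroup count TSV.
#' @return Integer matrix, orthogroups x species.
#' @export
read_orthogroup_counts <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("orthogroup table needs species columns", call. = FALSE)
  if (tolower(colnames(df)[ncol(df)]) == "total") df <- df[, -ncol(df)]
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate orthogroup ids", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate species columns", call. = FALSE)
  if (!is.numeric(m) || anyNA(m) || any(m < 0)) {
    stop("orthogroup counts must be non-negative numbers", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}
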