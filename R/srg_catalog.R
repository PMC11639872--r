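# Stress-response-gene cataloguing: a gene is assigned to an SRG family
# iff it carries at least one of the family's defining protein domains at
# a sufficiently good e-value. Family abundances are expressed relative to
# the total predicted peptide count of each species and compared across
# taxonomic groups with a transparent linear model on log abundances.

#' Assign genes to SRG families from domain annotations
#'
#' A gene is assigned to a family iff it carries >= 1 defining domain with
#' `domain_evalue <= evalue_max`. Genes matching several families receive
#' the first family in the definition table's order (priority by file
#' order, reported via message), so the catalog is a function: each gene
#' maps to at most one family.
#'
#' @param domains Domain annotation data.frame (`gene_id`,
#'   `domain_accession`, `domain_evalue`).
#' @param families SRG family definition table.
#' @param evalue_max Domain e-value cutoff (default 1e-5).
#' @return A data.frame `gene_id`, `family`, `category` (one row per
#'   assigned gene).
#' @export
assign_srg_families <- function(domains, families, evalue_max = 1e-5) {
  families <- validate_srg_families(families)
  acc_list <- family_accession_list(families)
  if (!all(grepl("^PF\\d+", unlist(acc_list)))) {
    warning("family accession(s) not in PFAM-style PFxxxxx format",
            call. = FALSE)
  }
  ok <- domains[domains$domain_evalue <= evalue_max, , drop = FALSE]
  acc2fam <- rep(names(acc_list), lengths(acc_list))
  names(acc2fam) <- unlist(acc_list)
  ok$family <- acc2fam[ok$domain_accession]
  ok <- ok[!is.na(ok$family), , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(data.frame(gene_id = character(0), family = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  prio <- match(ok$family, families$family)
  ord <- order(ok$gene_id, prio)
  sorted <- ok[ord, , drop = FALSE]
  first <- !duplicated(sorted$gene_id)
  multi <- unique(sorted$gene_id[stats::ave(prio[ord], sorted$gene_id,
                                            FUN = function(x) length(unique(x))) > 1])
  if (length(multi)) {
    message(length(multi), " gene(s) matched several families; kept the ",
            "highest-priority family (definition file order)")
  }
  out <- sorted[first, c("gene_id", "family"), drop = FALSE]
  out$category <- families$category[match(out$family, families$family)]
  rownames(out) <- NULL
  out
}

#' Per-species SRG family counts and relative abundances
#'
#' Abundance of a family in a species is its gene count divided by the
#' species' total number of predicted peptides.
#'
#' @param catalog Catalog data.frame from [assign_srg_families()], with an
#'   additional `species` column, or a single-species catalog combined
#'   with `total_peptides` as a scalar.
#' @param total_peptides Named integer vector of total predicted peptides
#'   per species (or scalar for a single-species catalog).
#' @param families Family definition table (fixes the family universe so
#'   zero-member families appear with abundance 0).
#' @return A data.frame `species`, `family`, `category`, `n`, `abundance`.
#' @export
srg_relative_abundance <- function(catalog, total_peptides,
                                   families = NULL) {
  if (is.null(catalog$species)) {
    catalog$species <- if (!is.null(names(total_peptides))) {
      names(total_peptides)[1L]
    } else "species"
  }
  if (is.null(names(total_peptides))) {
    names(total_peptides) <- unique(catalog$species)[seq_along(total_peptides)]
  }
  if (any(total_peptides <= 0)) {
    stop("total_peptides must be positive for every species", call. = FALSE)
  }
  fams <- if (!is.null(families)) families$family else unique(catalog$family)
  cats <- if (!is.null(families)) {
    families$category[match(fams, families$family)]
  } else {
    catalog$category[match(fams, catalog$family)]
  }
  grid <- expand.grid(species = names(total_peptides), family = fams,
                      stringsAsFactors = FALSE)
  grid$category <- cats[match(grid$family, fams)]
  grid$n <- mapply(function(sp, fa) {
    sum(catalog$species == sp & catalog$family == fa)
  }, grid$species, grid$family)
  grid$abundance <- grid$n / as.numeric(total_peptides[grid$species])
  grid
}

#' Associate SRG family abundances with taxonomic groups
#'
#' For each family, fits an ordinary least-squares model of
#' log-transformed relative abundance (with a half-minimum pseudocount for
#' zeros) on a group indicator, reports the effect (log-abundance
#' difference, sign included), its p-value, and Benjamini-Hochberg q-values
#' across families. Families with zero variance are flagged not testable.
#' This is a transparent stand-in for multivariable association frameworks
#' used for compositional data; the conventional q < 0.25 screening
#' threshold is recorded in the output attribute `"q_threshold"`.
#'
#' @param abundances Data.frame from [srg_relative_abundance()].
#' @param groups Named character vector mapping species to group labels
#'   (e.g. superfamily Robusta/Complexa).
#' @param q_threshold Screening threshold stored with the result.
#' @return A data.frame `family`, `effect`, `p`, `q`, `testable`.
#' @export
group_association <- function(abundances, groups, q_threshold = 0.25) {
  abundances$group <- groups[abundances$species]
  if (any(is.na(abundances$group))) {
    stop("species without a group label: ",
         paste(unique(abundances$species[is.na(abundances$group)]),
               collapse = ", "), call. = FALSE)
  }
  if (length(unique(abundances$group)) < 2L) {
    stop("need >= 2 groups for association testing", call. = FALSE)
  }
  pos <- abundances$abundance[abundances$abundance > 0]
  pseudo <- if (length(pos)) min(pos) / 2 else 1e-8
  fams <- unique(abundances$family)
  res <- lapply(fams, function(fa) {
    d <- abundances[abundances$family == fa, , drop = FALSE]
    y <- log(d$abundance + pseudo)
    g <- factor(d$group)
    if (stats::var(y) == 0 || any(table(g) < 2L)) {
      return(data.frame(family = fa, effect = if (stats::var(y) == 0) 0 else NA_real_,
                        p = NA_real_, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(y ~ g)
    sm <- summary(fit)$coefficients
    data.frame(family = fa, effect = sm[2L, "Estimate"],
               p = sm[2L, "Pr(>|t|)"], testable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  out$q[out$testable] <- stats::p.adjust(out$p[out$testable], method = "BH")
  attr(out, "q_threshold") <- q_threshold
  out[, c("family", "effect", "p", "q", "testable")]
}

#' Pearson correlation of orthogroup gene-count profiles between species
#'
#' @param og Orthogroup x species integer matrix
#'   (see [read_orthogroup_counts()]).
#' @return Symmetric species x species correlation matrix with unit
#'   diagonal; species with zero-variance profiles get NA rows/columns
#'   (correlation undefined) with a warning.
#' @export
orthogroup_correlation <- function(og) {
  if (nrow(og) < 2L) stop("need >= 2 orthogroups", call. = FALSE)
  v <- apply(og, 2L, stats::var)
  r <- suppressWarnings(stats::cor(og, method = "pearson"))
  if (any(v == 0)) {
    warning("zero-variance orthogroup profile for: ",
            paste(colnames(og)[v == 0], collapse = ", "),
            "; correlation undefined (NA)", call. = FALSE)
    r[v == 0, ] <- NA_real_
    r[, v == 0] <- NA_real_
  }
  diag(r) <- ifelse(v > 0, 1, NA_real_)
  r
}
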