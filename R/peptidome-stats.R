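## Descriptive immunopeptidome comparisons: how much of each sample's
## repertoire is shared across samples, pairwise Venn overlaps, length
## distributions, and the expression profile of peptide source genes.

#' Cross-sample peptide sharing
#'
#' For a list of named peptide sets (deduplicated internally), counts per
#' sample how many peptides occur in at least one other sample versus are
#' unique to it, plus a global table of how many samples contain each
#' peptide.
#'
#' @param samples named list of character vectors (or `surrogate_peptidome`
#'   objects); at least two.
#' @return list with `per_sample` (data.frame: `sample`, `n_peptides`,
#'   `n_shared`, `n_unique`, `fraction_shared`) and `peptide_counts`
#'   (data.frame: `peptide`, `n_samples`).
#' @export
sharing_counts <- function(samples) {
  if (length(samples) < 2L) {
    stop("sharing analysis needs at least two samples", call. = FALSE)
  }
  sets <- lapply(samples, function(s) {
    if (inherits(s, "surrogate_peptidome")) s$peptides
    else sort(unique(toupper(as.character(s))))
  })
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("sample", seq_along(sets))
  }
  tab <- table(unlist(sets, use.names = FALSE))
  peptide_counts <- data.frame(peptide = names(tab),
                               n_samples = as.integer(tab),
                               stringsAsFactors = FALSE, row.names = NULL)
  per_sample <- do.call(rbind, lapply(names(sets), function(nm) {
    pep <- sets[[nm]]
    shared <- sum(tab[pep] >= 2L)
    data.frame(sample = nm, n_peptides = length(pep),
               n_shared = shared, n_unique = length(pep) - shared,
               fraction_shared = if (length(pep)) shared / length(pep)
                                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  row.names(per_sample) <- NULL
  list(per_sample = per_sample, peptide_counts = peptide_counts)
}

#' Pairwise overlap (Venn counts) of two peptide sets
#'
#' @param a,b character vectors or `surrogate_peptidome` objects.
#' @return named integer vector `c(a_only, shared, b_only)`.
#' @export
pairwise_overlap <- function(a, b) {
  pa <- if (inherits(a, "surrogate_peptidome")) a$peptides
        else unique(toupper(as.character(a)))
  pb <- if (inherits(b, "surrogate_peptidome")) b$peptides
        else unique(toupper(as.character(b)))
  shared <- length(intersect(pa, pb))
  c(a_only = length(pa) - shared, shared = shared,
    b_only = length(pb) - shared)
}

#' Peptide length distribution
#' @param peptides character vector or `surrogate_peptidome`.
#' @return data.frame with columns `length` and `count`.
#' @export
length_distribution <- function(peptides) {
  pep <- if (inherits(peptides, "surrogate_peptidome")) peptides$peptides
         else unique(toupper(as.character(peptides)))
  tab <- table(nchar(pep))
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' C-terminal residue composition
#' @param peptides character vector or `surrogate_peptidome`.
#' @return data.frame with columns `residue` and `count`, all 20 letters.
#' @export
cterm_composition <- function(peptides) {
  pep <- if (inherits(peptides, "surrogate_peptidome")) peptides$peptides
         else unique(toupper(as.character(peptides)))
  last <- substr(pep, nchar(pep), nchar(pep))
  tab <- table(factor(last, levels = AA_STANDARD))
  data.frame(residue = AA_STANDARD, count = as.integer(tab))
}

#' Source-gene expression profile of a peptidome
#'
#' Maps every peptide to its source proteins by exact substring search
#' against the reference proteome; a multi-mapping peptide takes the maximum
#' TPM over its source genes (the most plausible source under abundance
#' bias). Returns per-peptide TPM values, log10(TPM + eps) for density
#' plotting, a Gaussian kernel density estimate, and the unmapped-peptide
#' count.
#'
#' @param peptidome `surrogate_peptidome` or character vector.
#' @param reference proteome data.frame.
#' @param expr expression data.frame.
#' @param eps pseudo-count added before log10 (default 0.01).
#' @return list with `values` (data.frame: `peptide`, `tpm`, `log10_tpm`),
#'   `density` (a [stats::density()] object over `log10_tpm`, `NULL` if
#'   fewer than 2 values) and `n_unmapped`.
#' @export
source_gene_tpm <- function(peptidome, reference, expr, eps = 0.01) {
  pep <- if (inherits(peptidome, "surrogate_peptidome")) peptidome$peptides
         else unique(toupper(as.character(peptidome)))
  sequences <- stats::setNames(reference$sequence, reference$protein_id)
  gene_of <- stats::setNames(reference$gene_id, reference$protein_id)
  rows <- lapply(pep, function(p) {
    occ <- locate_occurrences(p, sequences)
    if (nrow(occ) == 0L) return(NULL)
    genes <- unique(gene_of[occ$protein_id])
    tpms <- tpm_lookup(expr, genes)
    if (all(is.na(tpms))) return(NULL)
    data.frame(peptide = p, tpm = max(tpms, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  mapped <- do.call(rbind, rows)
  n_unmapped <- length(pep) - NROW(mapped)
  if (is.null(mapped)) {
    mapped <- data.frame(peptide = character(0), tpm = numeric(0))
  }
  mapped$log10_tpm <- log10(mapped$tpm + eps)
  dens <- if (nrow(mapped) >= 2L) stats::density(mapped$log10_tpm) else NULL
  list(values = mapped, density = dens, n_unmapped = n_unmapped)
}

#' Write peptidome summary tables
#'
#' Emits the sharing, overlap, length and source-gene TPM tables as TSVs
#' under a common path prefix.
#'
#' @param samples named list of peptide sets (>= 2 for sharing/overlap;
#'   overlap is written for the first pair).
#' @param reference proteome data.frame, or `NULL` to skip the TPM profile.
#' @param expr expression data.frame, or `NULL` to skip the TPM profile.
#' @param out_prefix path prefix for output files.
#' @return invisible character vector of files written.
#' @export
write_peptidome_stats <- function(samples, reference = NULL, expr = NULL,
                                  out_prefix) {
  written <- character(0)
  tsv <- function(df, suffix) {
    p <- paste0(out_prefix, suffix)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
  }
  if (length(samples) >= 2L) {
    sh <- sharing_counts(samples)
    tsv(sh$per_sample, "_sharing.tsv")
    ov <- pairwise_overlap(samples[[1L]], samples[[2L]])
    tsv(data.frame(set = names(ov), count = as.integer(ov)), "_overlap.tsv")
  }
  for (nm in names(samples)) {
    tsv(length_distribution(samples[[nm]]),
        paste0("_lengths_", nm, ".tsv"))
  }
  if (!is.null(reference) && !is.null(expr)) {
    for (nm in names(samples)) {
      prof <- source_gene_tpm(samples[[nm]], reference, expr)
      tsv(prof$values, paste0("_tpm_", nm, ".tsv"))
    }
  }
  invisible(written)
}
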