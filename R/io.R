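## Readers and writers for every external file the pipeline touches. All other
## modules operate on the in-memory types returned here: a proteome data.frame,
## a mutation data.frame, a surrogate_peptidome, and plain lookup tables.

#' Read a reference proteome from FASTA
#'
#' Headers are either `>protein_id` or `>protein_id|gene_id`; anything after
#' the first whitespace is ignored. An optional sidecar TSV
#' (columns `protein_id`, `gene_id`) overrides header-derived gene ids. When no
#' gene id is available the protein id is used.
#'
#' @param path FASTA file.
#' @param gene_map optional TSV mapping `protein_id` to `gene_id`.
#' @return data.frame with columns `protein_id`, `gene_id`, `sequence`
#'   (uppercase, 20 standard letters only).
#' @export
read_proteome <- function(path, gene_map = NULL) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  headers <- sub("\\s.*$", "", names(aa))
  parts <- strsplit(headers, "|", fixed = TRUE)
  protein_id <- vapply(parts, `[`, "", 1L)
  gene_id <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L], "")
  sequence <- toupper(as.character(aa))

  dup <- duplicated(protein_id)
  if (any(dup)) {
    stop("duplicate protein_id in ", path, ": ",
         paste(unique(protein_id[dup]), collapse = ", "), call. = FALSE)
  }
  bad <- !is_standard_aa(sequence) | nchar(sequence) == 0L
  if (any(bad)) {
    i <- which(bad)[1L]
    off <- first_bad_offset(sequence[i])
    stop("non-standard residue in record '", protein_id[i], "' at offset ",
         off, call. = FALSE)
  }

  if (!is.null(gene_map)) {
    gm <- utils::read.delim(gene_map, stringsAsFactors = FALSE)
    stopifnot(all(c("protein_id", "gene_id") %in% names(gm)))
    hit <- match(protein_id, gm$protein_id)
    gene_id[!is.na(hit)] <- gm$gene_id[hit[!is.na(hit)]]
  }

  data.frame(protein_id = protein_id, gene_id = gene_id, sequence = sequence,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a proteome to FASTA
#'
#' Uses the `>protein_id|gene_id` header dialect that [read_proteome()]
#' parses; round-trips losslessly.
#'
#' @param proteome data.frame from [read_proteome()].
#' @param path output file.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- paste(proteome$protein_id, proteome$gene_id, sep = "|")
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a missense-mutation table
#'
#' Expects a TSV with header columns `protein_id`, `position` (1-based residue
#' index), `ref_aa`, `alt_aa`, `gene_id`, `label` (e.g. `"STT3A p.Q294R"`).
#' Rows are validated: positions must be positive integers, amino acids must
#' be standard one-letter codes, and silent rows (`ref_aa == alt_aa`) are
#' rejected.
#'
#' @param path TSV file.
#' @return validated data.frame of missense mutations.
#' @export
read_mutations <- function(path) {
  stopifnot(file.exists(path))
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = ".")
  need <- c("protein_id", "position", "ref_aa", "alt_aa", "gene_id", "label")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop("mutation table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- m[need]
  pos <- suppressWarnings(as.integer(m$position))
  bad_pos <- is.na(pos) | pos < 1L | pos != suppressWarnings(as.numeric(m$position))
  m$ref_aa <- toupper(m$ref_aa)
  m$alt_aa <- toupper(m$alt_aa)
  bad_aa <- !(m$ref_aa %in% AA_STANDARD) | !(m$alt_aa %in% AA_STANDARD)
  silent <- !bad_aa & m$ref_aa == m$alt_aa
  problems <- bad_pos | bad_aa | silent
  if (any(problems)) {
    i <- which(problems)[1L]
    why <- if (bad_pos[i]) "position is not a positive integer"
           else if (bad_aa[i]) "ref_aa/alt_aa not a standard amino-acid letter"
           else "ref_aa equals alt_aa (not a missense change)"
    stop("mutation table row ", i, ": ", why, call. = FALSE)
  }
  m$position <- pos
  validate_mutations(m)
}

## Shared validation for mutation data.frames built in memory.
validate_mutations <- function(m) {
  stopifnot(is.data.frame(m),
            all(c("protein_id", "position", "ref_aa", "alt_aa",
                  "gene_id", "label") %in% names(m)))
  m$position <- as.integer(m$position)
  stopifnot(all(m$position >= 1L),
            all(m$ref_aa %in% AA_STANDARD),
            all(m$alt_aa %in% AA_STANDARD),
            all(m$ref_aa != m$alt_aa))
  row.names(m) <- NULL
  m
}

#' Write a missense-mutation table
#' @param mutations data.frame as returned by [read_mutations()].
#' @param path output TSV.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(
    mutations[c("protein_id", "position", "ref_aa", "alt_aa", "gene_id", "label")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a surrogate immunopeptidome
#'
#' Accepts either a plain list (one peptide per line) or a TSV with a named
#' sequence column. Peptides are uppercased and deduplicated; peptides with
#' non-standard letters (B, J, O, U, X, Z, ...) are dropped with a warning by
#' default, since MS search exports routinely contain them, or rejected in
#' strict mode.
#'
#' @param path input file.
#' @param hla_class `"I"` or `"II"`.
#' @param sample_label free-text label carried through reports.
#' @param column sequence column name when the file is a TSV (auto-detected
#'   among `peptide`, `sequence`, `Sequence` when `NULL`).
#' @param strict error (rather than drop) on non-standard letters.
#' @return a `surrogate_peptidome`: list with `peptides` (sorted unique
#'   character vector), `hla_class`, `sample_label`, and drop counts
#'   `n_dropped_duplicates`, `n_dropped_nonstandard`.
#' @export
read_peptides <- function(path, hla_class, sample_label = basename(path),
                          column = NULL, strict = FALSE) {
  stopifnot(file.exists(path))
  assert_hla_class(hla_class)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty peptide file: ", path, call. = FALSE)

  if (grepl("\t", lines[1L]) || !is.null(column)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (is.null(column)) {
      column <- intersect(c("peptide", "sequence", "Sequence"), names(tab))[1L]
      if (is.na(column)) {
        stop("no peptide sequence column found in ", path, call. = FALSE)
      }
    }
    raw <- tab[[column]]
  } else {
    raw <- lines
  }
  peptidome(raw, hla_class, sample_label, strict = strict)
}

#' Build a surrogate peptidome from an in-memory character vector
#'
#' Same normalization as [read_peptides()]: uppercase, deduplicate, drop (or
#' reject under `strict`) peptides containing non-standard letters.
#'
#' @inheritParams read_peptides
#' @param peptides character vector of peptide sequences.
#' @return a `surrogate_peptidome` object.
#' @export
peptidome <- function(peptides, hla_class, sample_label = "peptidome",
                      strict = FALSE) {
  assert_hla_class(hla_class)
  pep <- toupper(trimws(as.character(peptides)))
  pep <- pep[nzchar(pep)]
  ok <- is_standard_aa(pep)
  if (any(!ok)) {
    if (strict) {
      stop("peptide with non-standard letter: ", pep[!ok][1L], call. = FALSE)
    }
    warning(sum(!ok), " peptide(s) with non-standard letters dropped",
            call. = FALSE)
  }
  kept <- pep[ok]
  uniq <- sort(unique(kept))
  structure(
    list(peptides = uniq,
         hla_class = hla_class,
         sample_label = sample_label,
         n_dropped_duplicates = length(kept) - length(uniq),
         n_dropped_nonstandard = sum(!ok)),
    class = "surrogate_peptidome")
}

#' @export
print.surrogate_peptidome <- function(x, ...) {
  cat("surrogate_peptidome '", x$sample_label, "': ", length(x$peptides),
      " unique peptides, HLA class ", x$hla_class, "\n", sep = "")
  invisible(x)
}

#' Write a peptide list (one sequence per line)
#' @param x a `surrogate_peptidome` or character vector.
#' @param path output file.
#' @export
write_peptides <- function(x, path) {
  pep <- if (inherits(x, "surrogate_peptidome")) x$peptides else as.character(x)
  writeLines(pep, path)
  invisible(path)
}

#' Read a gene-expression (TPM) table
#'
#' TSV with header columns `gene_id` and `tpm`; TPM values must be
#' non-negative and gene ids unique.
#'
#' @param path TSV file.
#' @return data.frame with columns `gene_id`, `tpm`.
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "tpm") %in% names(e)))
  e$tpm <- as.numeric(e$tpm)
  if (anyNA(e$tpm) || any(e$tpm < 0)) {
    stop("expression table contains missing or negative TPM values",
         call. = FALSE)
  }
  if (anyDuplicated(e$gene_id)) {
    stop("duplicate gene_id in expression table", call. = FALSE)
  }
  e[c("gene_id", "tpm")]
}

#' Write a gene-expression table
#' @param expr data.frame with `gene_id` and `tpm`.
#' @param path output TSV.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr[c("gene_id", "tpm")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## TPM lookup; NA for genes absent from the table.
tpm_lookup <- function(expr, gene_id) {
  expr$tpm[match(gene_id, expr$gene_id)]
}

#' Read a precomputed percentile-rank (%rank) score table
#'
#' TSV with header columns `peptide`, `allele`, `rank` — the export format of
#' external MHC-binding predictors. Lower %rank means stronger predicted
#' binding. Keys `(peptide, allele)` must be unique and ranks non-negative.
#'
#' @param path TSV file.
#' @return data.frame with columns `peptide`, `allele`, `rank`.
#' @export
read_rank_table <- function(path) {
  stopifnot(file.exists(path))
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide", "allele", "rank") %in% names(r)))
  r$peptide <- toupper(r$peptide)
  r$rank <- as.numeric(r$rank)
  if (anyNA(r$rank) || any(r$rank < 0)) {
    stop("rank table contains missing or negative %rank values", call. = FALSE)
  }
  if (anyDuplicated(r[c("peptide", "allele")])) {
    stop("duplicate (peptide, allele) key in rank table", call. = FALSE)
  }
  r[c("peptide", "allele", "rank")]
}

#' Write candidate neoantigens to TSV
#'
#' One row per collapsed candidate, ordered by protein id, then the smallest
#' covered mutation position, then the representative mutant sequence.
#' Member peptides are comma-joined; missing TPM is written as `"."`.
#'
#' @param candidates data.frame from [run_nessie()] or [collapse_matches()].
#' @param path output TSV.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("mutant_peptide", "wt_counterpart", "all_member_peptides",
            "protein_id", "gene_id", "covered_positions", "substitutions",
            "tpm", "hla_class", "filter_flags")
  if (nrow(candidates) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
  } else {
    out <- data.frame(
      mutant_peptide = candidates$representative_mut,
      wt_counterpart = candidates$representative_wt,
      all_member_peptides = vapply(candidates$members_wt, paste,
                                   "", collapse = ","),
      protein_id = candidates$protein_id,
      gene_id = candidates$gene_id,
      covered_positions = candidates$covered_positions,
      substitutions = candidates$substitutions,
      tpm = ifelse(is.na(candidates$tpm), ".",
                   format(candidates$tpm, trim = TRUE, scientific = FALSE)),
      hla_class = candidates$hla_class,
      filter_flags = candidates$filter_flags,
      stringsAsFactors = FALSE)
    ord <- order(out$protein_id,
                 as.integer(sub(",.*$", "", out$covered_positions)),
                 out$mutant_peptide)
    out <- out[ord, , drop = FALSE]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
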