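## The NESSIE search itself: length-filter the surrogate peptidome, keep
## peptides found anywhere in the wild-type proteome but nowhere in the
## mutant proteome, substitute the mutant residues, collapse N-/C-terminal
## length variants of the same substitution, and apply the tumor-expression
## filter. Everything here is deterministic.

#' Keep only class-appropriate peptide lengths
#'
#' HLA class I retains 8- to 12-mers, class II 10- to 25-mers; `bounds`
#' overrides the class defaults (e.g. for mixed-class fixtures).
#'
#' @param peptidome a `surrogate_peptidome`.
#' @param bounds optional `c(min, max)` override.
#' @return filtered `surrogate_peptidome`; the number removed is recorded in
#'   its `n_length_filtered` field.
#' @export
length_filter <- function(peptidome, bounds = NULL) {
  stopifnot(inherits(peptidome, "surrogate_peptidome"))
  if (is.null(bounds)) bounds <- class_length_bounds(peptidome$hla_class)
  stopifnot(length(bounds) == 2L, bounds[1L] <= bounds[2L])
  len <- nchar(peptidome$peptides)
  keep <- len >= bounds[1L] & len <= bounds[2L]
  out <- peptidome
  out$peptides <- peptidome$peptides[keep]
  out$n_length_filtered <- sum(!keep)
  out
}

#' Locate every exact occurrence of a peptide in a set of protein sequences
#'
#' Enumerates all matches, including overlapping ones, in deterministic order
#' (protein id, then start position, both ascending).
#'
#' @param peptide non-empty peptide string.
#' @param sequences named character vector (protein_id -> sequence).
#' @return data.frame with columns `protein_id` and `start` (1-based).
#' @export
locate_occurrences <- function(peptide, sequences) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nchar(peptide) > 0L)
  if (!length(sequences)) {
    return(data.frame(protein_id = character(0), start = integer(0)))
  }
  ids <- sort(names(sequences))
  subject <- Biostrings::AAStringSet(unname(sequences[ids]))
  hits <- Biostrings::vmatchPattern(peptide, subject)
  starts <- Biostrings::startIndex(hits)
  n <- lengths(starts)
  data.frame(
    protein_id = rep(ids, n),
    start = as.integer(unlist(lapply(starts, sort), use.names = FALSE)),
    stringsAsFactors = FALSE, row.names = NULL)
}

## Map I->L when isoleucine/leucine-equivalent matching is requested; MS
## cannot distinguish the isobaric pair. Reporting always uses the original
## sequences.
il_fold <- function(x) chartr("I", "L", x)

#' Find wild-type counterpart matches of the surrogate peptidome
#'
#' A surrogate peptide qualifies when its complete sequence occurs at least
#' once anywhere in the wild-type proteome of the mutated proteins and never
#' in the mutant proteome. Membership is proteome-wide and literal: a peptide
#' occurring in an unchanged region of any mutant protein is excluded even if
#' another of its occurrences covers a mutation. For qualifying peptides one
#' match per wild-type occurrence is returned; by construction (pure
#' substitutions, equal lengths) every such occurrence covers at least one
#' mutation site, and this is asserted at run time.
#'
#' @param peptidome a length-filtered `surrogate_peptidome`.
#' @param pair a `proteome_pair`.
#' @param il_equivalent treat I and L as one letter during matching
#'   (isobaric under MS); reported sequences stay literal.
#' @return data.frame with columns `peptide`, `protein_id`, `start`, and a
#'   list-column `covered_sites` of integer mutation positions.
#' @export
find_counterparts <- function(peptidome, pair, il_equivalent = FALSE) {
  stopifnot(inherits(peptidome, "surrogate_peptidome"),
            inherits(pair, "proteome_pair"))
  wt <- pair$wt
  mt <- pair$mt
  if (il_equivalent) {
    wt_search <- il_fold(wt)
    mt_search <- il_fold(mt)
  } else {
    wt_search <- wt
    mt_search <- mt
  }

  rows <- vector("list", length(peptidome$peptides))
  k <- 0L
  for (pep in peptidome$peptides) {
    query <- if (il_equivalent) il_fold(pep) else pep
    occ_wt <- locate_occurrences(query, wt_search)
    if (nrow(occ_wt) == 0L) next
    occ_mt <- locate_occurrences(query, mt_search)
    if (nrow(occ_mt) > 0L) next
    len <- nchar(pep)
    for (i in seq_len(nrow(occ_wt))) {
      pid <- occ_wt$protein_id[i]
      start <- occ_wt$start[i]
      s <- sites_for_protein(pair, pid)
      covered <- s$position[s$position >= start & s$position <= start + len - 1L]
      if (!length(covered)) {
        stop("internal consistency failure: wild-type-only occurrence of '",
             pep, "' in '", pid, "' covers no mutation site; ",
             "proteome pair may contain indels or be corrupted",
             call. = FALSE)
      }
      k <- k + 1L
      rows[[k]] <- list(peptide = pep, protein_id = pid, start = start,
                        covered_sites = sort(covered))
    }
  }
  rows <- rows[seq_len(k)]
  out <- data.frame(
    peptide = vapply(rows, `[[`, "", "peptide"),
    protein_id = vapply(rows, `[[`, "", "protein_id"),
    start = vapply(rows, `[[`, 1L, "start"),
    stringsAsFactors = FALSE)
  out$covered_sites <- lapply(rows, `[[`, "covered_sites")
  out
}

#' Mutant form of a matched wild-type peptide
#'
#' Substitutes the mutant residues by reading the same coordinates from the
#' mutant protein; the result differs from the wild-type peptide at exactly
#' the covered mutation sites.
#'
#' @param match one-row slice of the [find_counterparts()] result (or a list
#'   with `peptide`, `protein_id`, `start`).
#' @param pair a `proteome_pair`.
#' @return the mutant peptide string.
#' @export
#' @examples
#' ref <- data.frame(protein_id = "P1", gene_id = "G1",
#'                   sequence = "AAKLNPQQFEVAA")
#' mut <- data.frame(protein_id = "P1", position = 8L, ref_aa = "Q",
#'                   alt_aa = "R", gene_id = "G1", label = "p.Q8R")
#' pair <- build_proteome_pair(ref, mut)
#' mutant_peptide(list(peptide = "KLNPQQFEV", protein_id = "P1", start = 3L),
#'                pair)  # "KLNPQRFEV"
mutant_peptide <- function(match, pair) {
  pep <- match$peptide[[1L]]
  pid <- match$protein_id[[1L]]
  start <- match$start[[1L]]
  substr(pair$mt[[pid]], start, start + nchar(pep) - 1L)
}

#' Collapse length variants into candidate neoantigens
#'
#' Overlapping peptides carrying the same amino-acid substitution(s) but
#' differing in N-/C-terminal flanking residues are counted as one candidate:
#' matches are grouped by protein and by the exact set of covered mutation
#' positions, and the representative member is the longest peptide
#' (lexicographically smallest on ties).
#'
#' @param matches data.frame from [find_counterparts()].
#' @param pair a `proteome_pair`.
#' @param hla_class `"I"` or `"II"`, carried into the candidate table.
#' @return candidate data.frame, one row per group, with representative
#'   wild-type/mutant sequences, member list-columns, covered positions and
#'   substitution labels, ordered by protein id then first covered position
#'   then representative mutant sequence.
#' @export
collapse_matches <- function(matches, pair, hla_class) {
  assert_hla_class(hla_class)
  empty <- data.frame(
    protein_id = character(0), gene_id = character(0),
    covered_positions = character(0), substitutions = character(0),
    representative_wt = character(0), representative_mut = character(0),
    n_members = integer(0), tpm = numeric(0), hla_class = character(0),
    filter_flags = character(0), stringsAsFactors = FALSE)
  empty$members_wt <- list()
  empty$members_mut <- list()
  empty$member_starts <- list()
  if (is.null(matches) || nrow(matches) == 0L) return(empty)

  key <- paste(matches$protein_id,
               vapply(matches$covered_sites, paste, "", collapse = ","))
  groups <- split(seq_len(nrow(matches)), key)

  rows <- lapply(groups, function(idx) {
    sub <- matches[idx, , drop = FALSE]
    pid <- sub$protein_id[1L]
    covered <- sub$covered_sites[[1L]]
    sites <- sites_for_protein(pair, pid)
    sites <- sites[sites$position %in% covered, , drop = FALSE]
    muts <- vapply(seq_len(nrow(sub)), function(i) {
      mutant_peptide(sub[i, , drop = FALSE], pair)
    }, "")
    ## one row per distinct (wt peptide, start); a peptide matching at two
    ## starts with identical covered sets contributes each occurrence
    ord <- order(-nchar(sub$peptide), sub$peptide, sub$start)
    rep_i <- ord[1L]
    list(protein_id = pid,
         gene_id = sites$gene_id[1L],
         covered_positions = paste(covered, collapse = ","),
         substitutions = paste0(sites$ref_aa, sites$position, sites$alt_aa,
                                collapse = ","),
         representative_wt = sub$peptide[rep_i],
         representative_mut = muts[rep_i],
         members_wt = sub$peptide[ord],
         members_mut = muts[ord],
         member_starts = sub$start[ord],
         n_members = length(idx))
  })

  out <- data.frame(
    protein_id = vapply(rows, `[[`, "", "protein_id"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    covered_positions = vapply(rows, `[[`, "", "covered_positions"),
    substitutions = vapply(rows, `[[`, "", "substitutions"),
    representative_wt = vapply(rows, `[[`, "", "representative_wt"),
    representative_mut = vapply(rows, `[[`, "", "representative_mut"),
    n_members = vapply(rows, `[[`, 1L, "n_members"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$members_wt <- lapply(rows, `[[`, "members_wt")
  out$members_mut <- lapply(rows, `[[`, "members_mut")
  out$member_starts <- lapply(rows, `[[`, "member_starts")
  out$tpm <- NA_real_
  out$hla_class <- hla_class
  out$filter_flags <- "PASS"
  first_pos <- as.integer(sub(",.*$", "", out$covered_positions))
  out <- out[order(out$protein_id, first_pos, out$representative_mut), ,
             drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Apply the tumor-expression filter to candidate neoantigens
#'
#' Candidates whose source-gene TPM is at or below the threshold are flagged
#' `LOW_EXPRESSION` and excluded from the PASS set (the boundary itself is
#' excluded: TPM must exceed the threshold). Genes absent from the table are
#' flagged `NO_EXPRESSION_DATA` and retained by default, protecting against
#' gene-id join failures; `strict` excludes them too. All candidates are
#' returned with their flags and a logical `pass` column.
#'
#' @param candidates candidate data.frame from [collapse_matches()].
#' @param expr expression data.frame ([read_expression()]).
#' @param threshold TPM threshold; default 1.
#' @param strict exclude candidates lacking expression data.
#' @return the candidate data.frame with `tpm`, `filter_flags` and `pass`
#'   filled in.
#' @export
expression_filter <- function(candidates, expr, threshold = 1.0,
                              strict = FALSE) {
  if (nrow(candidates) == 0L) {
    candidates$pass <- logical(0)
    return(candidates)
  }
  candidates$tpm <- tpm_lookup(expr, candidates$gene_id)
  flags <- ifelse(is.na(candidates$tpm), "NO_EXPRESSION_DATA",
                  ifelse(candidates$tpm <= threshold, "LOW_EXPRESSION",
                         "PASS"))
  candidates$filter_flags <- flags
  candidates$pass <- flags == "PASS" |
    (flags == "NO_EXPRESSION_DATA" & !strict)
  candidates
}

#' Run the full NESSIE pipeline
#'
#' Composes length filtering, paired-proteome construction, counterpart
#' matching, mutant substitution, length-variant collapsing and the
#' expression filter, and returns both the full candidate table and a run
#' report of per-stage counts. Fully deterministic: identical inputs give
#' identical outputs.
#'
#' @param peptidome a `surrogate_peptidome`.
#' @param reference proteome data.frame.
#' @param mutations mutation data.frame.
#' @param expr expression data.frame, or `NULL` to skip the filter (all
#'   candidates then flagged `NO_EXPRESSION_DATA`).
#' @param tpm_threshold TPM threshold for the expression filter.
#' @param length_bounds optional `c(min, max)` override of the class length
#'   filter.
#' @param il_equivalent isoleucine/leucine-equivalent matching.
#' @param strict_expression exclude candidates lacking expression data.
#' @return list with `candidates` (all candidates, flagged), `pass`
#'   (the PASS subset) and `report` (named list of stage counts and
#'   parameters).
#' @export
run_nessie <- function(peptidome, reference, mutations, expr = NULL,
                       tpm_threshold = 1.0, length_bounds = NULL,
                       il_equivalent = FALSE, strict_expression = FALSE) {
  stopifnot(inherits(peptidome, "surrogate_peptidome"))
  n_in <- length(peptidome$peptides)
  filtered <- length_filter(peptidome, bounds = length_bounds)
  pair <- build_proteome_pair(reference, mutations)
  matches <- find_counterparts(filtered, pair, il_equivalent = il_equivalent)
  n_matched_peptides <- length(unique(matches$peptide))
  candidates <- collapse_matches(matches, pair, peptidome$hla_class)
  if (is.null(expr)) {
    candidates$pass <- rep(!strict_expression, nrow(candidates))
    candidates$filter_flags <- rep("NO_EXPRESSION_DATA", nrow(candidates))
  } else {
    candidates <- expression_filter(candidates, expr,
                                    threshold = tpm_threshold,
                                    strict = strict_expression)
  }
  report <- list(
    tool = "nessier",
    version = as.character(utils::packageVersion("nessier")),
    hla_class = peptidome$hla_class,
    sample_label = peptidome$sample_label,
    parameters = list(tpm_threshold = tpm_threshold,
                      length_bounds = if (is.null(length_bounds))
                        class_length_bounds(peptidome$hla_class)
                      else as.integer(length_bounds),
                      il_equivalent = il_equivalent,
                      strict_expression = strict_expression),
    counts = list(
      peptides_in = n_in,
      peptides_length_filtered_out = filtered$n_length_filtered,
      peptides_after_length_filter = length(filtered$peptides),
      mutations = nrow(pair$sites),
      mutated_proteins = length(pair$wt),
      counterpart_peptides = n_matched_peptides,
      counterpart_occurrences = nrow(matches),
      candidate_groups = nrow(candidates),
      expression_excluded = sum(candidates$filter_flags == "LOW_EXPRESSION"),
      no_expression_data = sum(candidates$filter_flags ==
                                 "NO_EXPRESSION_DATA"),
      pass = sum(candidates$pass)))
  stopifnot(report$counts$candidate_groups ==
              report$counts$pass + report$counts$expression_excluded +
              sum(candidates$filter_flags == "NO_EXPRESSION_DATA" &
                    !candidates$pass))
  list(candidates = candidates,
       pass = candidates[candidates$pass, , drop = FALSE],
       report = report)
}

#' Write a run report as JSON
#' @param report the `report` element of a [run_nessie()] result.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
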