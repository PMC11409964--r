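## The companion in silico candidate-counting rule: enumerate every 8- to
## 12-mer window of the mutant protein that contains the substituted residue,
## look the windows up in an externally supplied %rank table (one row per
## peptide x allele), take the best (minimum) %rank per mutation, and count
## mutations passing the weak-binder and expression thresholds. The binding
## predictor itself is always external; this module only consumes its output.

#' Enumerate mutant k-mer windows covering a substitution site
#'
#' For each window length, every substring of the mutant protein containing
#' the mutated position, clipped at the protein ends. An interior site in a
#' long protein yields k windows of length k (50 peptides for lengths 8-12).
#'
#' @param pair a `proteome_pair`.
#' @param mutation one-row mutation data.frame (or list with `protein_id`
#'   and `position`) present in the pair.
#' @param lengths integer vector of window lengths; default `8:12`.
#' @return data.frame with columns `peptide` and `site_offset` (1-based
#'   position of the substituted residue within the peptide), in
#'   deterministic order (length, then start ascending).
#' @export
enumerate_mutant_kmers <- function(pair, mutation, lengths = 8:12) {
  pid <- mutation$protein_id[[1L]]
  pos <- as.integer(mutation$position[[1L]])
  if (!pid %in% names(pair$mt)) {
    stop("mutation protein '", pid, "' not present in the proteome pair",
         call. = FALSE)
  }
  seq <- pair$mt[[pid]]
  n <- nchar(seq)
  stopifnot(pos >= 1L, pos <= n)
  out <- list()
  for (k in sort(unique(as.integer(lengths)))) {
    if (k > n) next
    starts <- max(1L, pos - k + 1L):min(pos, n - k + 1L)
    out[[length(out) + 1L]] <- data.frame(
      peptide = substring(seq, starts, starts + k - 1L),
      site_offset = pos - starts + 1L,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(peptide = character(0), site_offset = integer(0)))
  }
  do.call(rbind, out)
}

## %rank lookup over the (peptide, allele) grid; NA where absent.
rank_lookup <- function(table, peptides, alleles) {
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  hit <- match(paste(grid$peptide, grid$allele),
               paste(table$peptide, table$allele))
  grid$rank <- table$rank[hit]
  grid
}

#' Best-%rank summary of one mutation
#'
#' Scores every enumerated mutant window against every allele using the
#' supplied %rank table and keeps the best predicted binder (the minimum
#' %rank, since lower is stronger). A mutation is a candidate when its best
#' %rank is below the weak threshold and its gene TPM exceeds the TPM
#' threshold; the strong flag marks best %rank below the strong threshold.
#'
#' @param mutation one-row mutation data.frame.
#' @param pair a `proteome_pair`.
#' @param table rank data.frame ([read_rank_table()]).
#' @param alleles character vector of allele names to score.
#' @param expr expression data.frame, or `NULL` (TPM then treated as missing
#'   and the candidate rule requires expression, so `is_candidate` is FALSE).
#' @param weak,strong %rank thresholds (defaults 2.0 and 0.5).
#' @param tpm_threshold expression threshold (default 1).
#' @param lengths window lengths (default `8:12`).
#' @param missing `"strict"` errors on a (peptide, allele) pair absent from
#'   the table; `"lenient"` skips it with a warning.
#' @return one-row data.frame: `protein_id`, `position`, `label`, `gene_id`,
#'   `best_rank`, `best_peptide`, `best_allele`, `tpm`, `is_candidate`,
#'   `is_strong`.
#' @export
summarize_mutation <- function(mutation, pair, table, alleles, expr = NULL,
                               weak = 2.0, strong = 0.5, tpm_threshold = 1.0,
                               lengths = 8:12,
                               missing = c("strict", "lenient")) {
  missing <- match.arg(missing)
  stopifnot(strong < weak)
  kmers <- enumerate_mutant_kmers(pair, mutation, lengths = lengths)
  scored <- rank_lookup(table, kmers$peptide, alleles)
  if (anyNA(scored$rank)) {
    if (missing == "strict") {
      i <- which(is.na(scored$rank))[1L]
      stop("no %rank entry for peptide '", scored$peptide[i],
           "' on allele '", scored$allele[i], "'", call. = FALSE)
    }
    warning(sum(is.na(scored$rank)),
            " unscored (peptide, allele) pair(s) skipped", call. = FALSE)
    scored <- scored[!is.na(scored$rank), , drop = FALSE]
  }
  if (nrow(scored) == 0L) {
    stop("no scored windows for mutation at ", mutation$protein_id[[1L]],
         ":", mutation$position[[1L]], call. = FALSE)
  }
  best <- which.min(scored$rank)
  tpm <- if (is.null(expr)) NA_real_ else tpm_lookup(expr,
                                                     mutation$gene_id[[1L]])
  best_rank <- scored$rank[best]
  data.frame(
    protein_id = mutation$protein_id[[1L]],
    position = as.integer(mutation$position[[1L]]),
    label = mutation$label[[1L]],
    gene_id = mutation$gene_id[[1L]],
    best_rank = best_rank,
    best_peptide = scored$peptide[best],
    best_allele = scored$allele[best],
    tpm = tpm,
    is_candidate = best_rank < weak && !is.na(tpm) && tpm > tpm_threshold,
    is_strong = best_rank < strong,
    stringsAsFactors = FALSE)
}

#' Count in silico candidate neoantigens over a mutation set
#'
#' Applies [summarize_mutation()] to every mutation and counts candidates
#' (best %rank below the weak threshold with gene TPM above the expression
#' threshold) and the strong-binder subset.
#'
#' @inheritParams summarize_mutation
#' @param mutations mutation data.frame.
#' @return list with `n_candidates`, `n_strong` (strong binders among the
#'   candidates) and `summaries` (per-mutation data.frame).
#' @export
count_insilico_candidates <- function(mutations, pair, table, alleles,
                                      expr = NULL, weak = 2.0, strong = 0.5,
                                      tpm_threshold = 1.0, lengths = 8:12,
                                      missing = c("strict", "lenient")) {
  missing <- match.arg(missing)
  if (nrow(mutations) == 0L) {
    return(list(n_candidates = 0L, n_strong = 0L,
                summaries = data.frame()))
  }
  summaries <- do.call(rbind, lapply(seq_len(nrow(mutations)), function(i) {
    summarize_mutation(mutations[i, , drop = FALSE], pair, table, alleles,
                       expr = expr, weak = weak, strong = strong,
                       tpm_threshold = tpm_threshold, lengths = lengths,
                       missing = missing)
  }))
  row.names(summaries) <- NULL
  list(n_candidates = sum(summaries$is_candidate),
       n_strong = sum(summaries$is_candidate & summaries$is_strong),
       summaries = summaries)
}

#' Write enumerated mutant k-mers as FASTA for external scoring
#'
#' Emits every window of every mutation so an external binding predictor can
#' score them; the resulting table feeds back in via [read_rank_table()].
#'
#' @param mutations mutation data.frame.
#' @param pair a `proteome_pair`.
#' @param path output FASTA.
#' @param lengths window lengths (default `8:12`).
#' @export
write_mutant_kmers <- function(mutations, pair, path, lengths = 8:12) {
  all <- lapply(seq_len(nrow(mutations)), function(i) {
    k <- enumerate_mutant_kmers(pair, mutations[i, , drop = FALSE],
                                lengths = lengths)
    if (nrow(k)) {
      names <- paste0(mutations$protein_id[i], "_", mutations$position[i],
                      "_", seq_len(nrow(k)))
      stats::setNames(k$peptide, names)
    } else character(0)
  })
  flat <- unlist(all)
  aa <- Biostrings::AAStringSet(unname(flat))
  names(aa) <- names(flat)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Deterministic pseudo-%rank scorer for tests and demonstrations
#'
#' Hash-based stand-in for an external predictor: maps each (peptide, allele)
#' pair to a reproducible pseudo-random %rank in (0, 50]. Useful for
#' exercising the counting rule without licensed software; carries no
#' biological meaning.
#'
#' @param peptides character vector.
#' @param alleles character vector.
#' @return rank data.frame with one row per (peptide, allele).
#' @export
stub_rank_table <- function(peptides, alleles) {
  grid <- expand.grid(peptide = unique(peptides), allele = unique(alleles),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  h <- vapply(paste(grid$peptide, grid$allele), function(s) {
    codes <- utf8ToInt(s)
    acc <- 0
    for (c in codes) acc <- (acc * 131 + c) %% 1000003
    acc / 1000003
  }, 0, USE.NAMES = FALSE)
  grid$rank <- round(h * 50, 4) + 1e-4
  grid
}
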