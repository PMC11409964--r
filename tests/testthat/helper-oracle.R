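# Independent brute-force oracles, pure base R (substr loops), sharing no
# code with the package's Biostrings-backed matching path.

# All occurrence start positions of pep in one sequence, naive scan.
naive_scan <- function(pep, seq) {
  k <- nchar(pep)
  n <- nchar(seq)
  if (k > n) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    if (substr(seq, i, i + k - 1L) == pep) starts <- c(starts, i)
  }
  starts
}

naive_in <- function(pep, seqs) {
  for (s in seqs) if (length(naive_scan(pep, s))) return(TRUE)
  FALSE
}

# Mutant proteome by character-vector substitution (independent of
# build_proteome_pair's substr<- path).
oracle_pair <- function(reference, mutations) {
  ids <- unique(mutations$protein_id)
  wt <- stats::setNames(
    reference$sequence[match(ids, reference$protein_id)], ids)
  mt <- wt
  for (i in seq_len(nrow(mutations))) {
    pid <- mutations$protein_id[i]
    chars <- strsplit(mt[[pid]], "")[[1]]
    stopifnot(chars[mutations$position[i]] == mutations$ref_aa[i])
    chars[mutations$position[i]] <- mutations$alt_aa[i]
    mt[[pid]] <- paste(chars, collapse = "")
  }
  list(wt = wt, mt = mt)
}

# Full brute-force NESSIE: returns one row per candidate group in canonical
# form (protein, covered-position string, sorted members, representative
# pair, pass flag).
oracle_nessie <- function(peptides, reference, mutations, expression,
                          bounds, tpm_threshold = 1.0) {
  pr <- oracle_pair(reference, mutations)
  peptides <- sort(unique(toupper(peptides)))
  peptides <- peptides[nchar(peptides) >= bounds[1] &
                       nchar(peptides) <= bounds[2]]
  rows <- list()
  for (pep in peptides) {
    if (!naive_in(pep, pr$wt) || naive_in(pep, pr$mt)) next
    for (pid in names(pr$wt)) {
      for (start in naive_scan(pep, pr$wt[[pid]])) {
        end <- start + nchar(pep) - 1L
        here <- mutations[mutations$protein_id == pid &
                          mutations$position >= start &
                          mutations$position <= end, , drop = FALSE]
        stopifnot(nrow(here) > 0L)  # substitutions-only guarantee
        rows[[length(rows) + 1L]] <- list(
          pid = pid,
          sites = paste(sort(here$position), collapse = ","),
          wt = pep,
          mut = substr(pr$mt[[pid]], start, end),
          gene = here$gene_id[1L])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(key = character(0), members = character(0),
                      rep_wt = character(0), rep_mut = character(0),
                      pass = logical(0), stringsAsFactors = FALSE))
  }
  keys <- vapply(rows, function(r) paste(r$pid, r$sites), "")
  out <- do.call(rbind, lapply(split(seq_along(rows), keys), function(idx) {
    grp <- rows[idx]
    wts <- vapply(grp, `[[`, "", "wt")
    muts <- vapply(grp, `[[`, "", "mut")
    ord <- order(-nchar(wts), wts)
    tpm <- expression$tpm[match(grp[[1L]]$gene, expression$gene_id)]
    data.frame(key = paste(grp[[1L]]$pid, grp[[1L]]$sites),
               members = paste(sort(wts), collapse = ","),
               rep_wt = wts[ord[1L]], rep_mut = muts[ord[1L]],
               # default policy: missing expression data is retained
               pass = is.na(tpm) || tpm > tpm_threshold,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$key), , drop = FALSE]
  row.names(out) <- NULL
  out
}

# Canonicalize a run_nessie candidate table into the oracle's shape.
canon_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(data.frame(key = character(0), members = character(0),
                      rep_wt = character(0), rep_mut = character(0),
                      pass = logical(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    key = paste(candidates$protein_id,
                gsub(",", ",", candidates$covered_positions)),
    members = vapply(candidates$members_wt,
                     function(m) paste(sort(m), collapse = ","), ""),
    rep_wt = candidates$representative_wt,
    rep_mut = candidates$representative_mut,
    pass = candidates$pass,
    stringsAsFactors = FALSE)
  out <- out[order(out$key), , drop = FALSE]
  row.names(out) <- NULL
  out
}

# Brute-force enumeration of all substrings of a sequence containing pos.
oracle_windows <- function(seq, pos, lengths) {
  out <- character(0)
  n <- nchar(seq)
  for (k in sort(lengths)) {
    for (start in seq_len(max(0L, n - k + 1L))) {
      if (pos >= start && pos <= start + k - 1L) {
        out <- c(out, substr(seq, start, start + k - 1L))
      }
    }
  }
  out
}
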