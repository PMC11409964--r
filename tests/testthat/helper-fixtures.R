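# Fixtures built in code. The worked example embeds the four published
# wild-type/neoantigen peptide pairs (RTF9/RAF9, KQV9/KRV9, KII10/KVI10,
# KAY15/KVY15) in a five-protein toy proteome.

# Worked-example proteome: P1 carries its substitution OUTSIDE the embedded
# peptide (so RTF9 occurs in both proteomes and must be excluded), P2-P4
# carry theirs inside, P5's substitution is covered by no surrogate peptide.
worked_example <- function() {
  reference <- data.frame(
    protein_id = c("P1", "P2", "P3", "P4", "P5"),
    gene_id = c("G1", "G2", "G3", "G4", "G5"),
    sequence = c(
      paste0("MAAAGGG", "RYLTVAAVF", "WWCCHHKK"),
      paste0("MSSTTPP", "KLNPQQFEV", "DDEEFFHH"),
      paste0("MKKRR", "KLWDIINVNI", "SSTTYYA"),
      paste0("MPPLL", "KGEIAASIATHMRPY", "NNQQW"),
      "MHHWWCCDDEEKKLLNNPPQQRRSSTTVVYY"),
    stringsAsFactors = FALSE)
  mutations <- data.frame(
    protein_id = c("P1", "P2", "P3", "P4", "P5"),
    position = c(3L, 13L, 11L, 14L, 5L),
    ref_aa = c("A", "Q", "I", "A", "W"),
    alt_aa = c("G", "R", "V", "V", "F"),
    gene_id = c("G1", "G2", "G3", "G4", "G5"),
    label = c("G1 p.A3G", "G2 p.Q13R", "G3 p.I11V", "G4 p.A14V",
              "G5 p.W5F"),
    stringsAsFactors = FALSE)
  wt_peptides <- c("RYLTVAAVF", "KLNPQQFEV", "KLWDIINVNI",
                   "KGEIAASIATHMRPY")
  decoys <- c("WWCCHHKK", "DDEEFFHH", "NVNISSTT", "THMRPYNN")
  expression <- data.frame(gene_id = paste0("G", 1:5), tpm = 10,
                           stringsAsFactors = FALSE)
  list(reference = reference, mutations = mutations,
       peptidome = peptidome(c(wt_peptides, decoys), "I",
                             sample_label = "worked_example"),
       expression = expression,
       expected_mutants = c("KLNPQRFEV", "KLWDIVNVNI", "KGEIAASIVTHMRPY"))
}

# Single protein embedding RYLTVAAVF with its T->A substitution inside the
# peptide (the configuration reported for the original tumor/mucosa pair).
rtf9_inside <- function() {
  reference <- data.frame(protein_id = "PX", gene_id = "GX",
                          sequence = paste0("MGG", "RYLTVAAVF", "KK"),
                          stringsAsFactors = FALSE)
  mutations <- data.frame(protein_id = "PX", position = 7L, ref_aa = "T",
                          alt_aa = "A", gene_id = "GX",
                          label = "GX p.T7A", stringsAsFactors = FALSE)
  list(reference = reference, mutations = mutations)
}

# sample() treats a length-1 numeric as 1:n; always pick from the vector
sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

random_aa_string <- function(len) {
  paste(sample(nessier:::AA_STANDARD, len, replace = TRUE), collapse = "")
}

# Random proteome data.frame for round-trip tests.
random_proteome_df <- function(n, len_range = c(20L, 80L)) {
  data.frame(
    protein_id = sprintf("RP%03d", seq_len(n)),
    gene_id = sprintf("RG%03d", seq_len(n)),
    sequence = vapply(sample(seq(len_range[1L], len_range[2L]), n,
                             replace = TRUE),
                      random_aa_string, ""),
    stringsAsFactors = FALSE)
}

# Random mutation table against a proteome (distinct positions per protein).
random_mutations_df <- function(reference, n_mut_proteins, per_protein = 2L) {
  pids <- sample(reference$protein_id, n_mut_proteins)
  do.call(rbind, lapply(pids, function(pid) {
    seq_i <- reference$sequence[reference$protein_id == pid]
    k <- sample(per_protein, 1L)
    pos <- sort(sample(nchar(seq_i), min(k, nchar(seq_i))))
    ref <- substring(seq_i, pos, pos)
    alt <- vapply(ref, function(r) {
      sample(setdiff(nessier:::AA_STANDARD, r), 1L)
    }, "", USE.NAMES = FALSE)
    data.frame(protein_id = pid, position = pos, ref_aa = ref, alt_aa = alt,
               gene_id = reference$gene_id[reference$protein_id == pid],
               label = paste0(pid, " p.", ref, pos, alt),
               stringsAsFactors = FALSE)
  }))
}

# Adversarial random instance for oracle-equivalence tests: peptides drawn
# from wild-type regions across sites, from mutant sequences, from unmutated
# regions, and fully at random.
random_instance <- function(max_proteins = 10L, max_len = 200L,
                            max_mutations = 6L, max_peptides = 50L,
                            bounds = c(8L, 12L)) {
  n_prot <- sample(2:max_proteins, 1L)
  reference <- random_proteome_df(n_prot, c(30L, max_len))
  n_mut_prot <- sample(seq_len(min(n_prot, max(1L, max_mutations %/% 2L))),
                       1L)
  mutations <- random_mutations_df(reference, n_mut_prot)
  if (nrow(mutations) > max_mutations) {
    mutations <- mutations[sample(nrow(mutations), max_mutations), ,
                           drop = FALSE]
  }
  pair <- build_proteome_pair(reference, mutations)
  n_pep <- sample(5:max_peptides, 1L)
  peptides <- character(0)
  for (i in seq_len(n_pep)) {
    k <- sample(seq(bounds[1L], bounds[2L]), 1L)
    kind <- sample(c("wt_site", "mt_site", "unmut", "random"), 1L)
    pep <- switch(kind,
      wt_site = {
        si <- sample1(seq_len(nrow(mutations)))
        s <- pair$wt[[mutations$protein_id[si]]]
        pos <- mutations$position[si]
        start <- sample1(max(1L, pos - k + 1L):min(pos, nchar(s) - k + 1L))
        substr(s, start, start + k - 1L)
      },
      mt_site = {
        si <- sample1(seq_len(nrow(mutations)))
        s <- pair$mt[[mutations$protein_id[si]]]
        pos <- mutations$position[si]
        start <- sample1(max(1L, pos - k + 1L):min(pos, nchar(s) - k + 1L))
        substr(s, start, start + k - 1L)
      },
      unmut = {
        s <- reference$sequence[sample(n_prot, 1L)]
        start <- sample(nchar(s) - k + 1L, 1L)
        substr(s, start, start + k - 1L)
      },
      random = random_aa_string(k))
    peptides <- c(peptides, pep)
  }
  expression <- data.frame(gene_id = reference$gene_id,
                           tpm = stats::rlnorm(n_prot, 1, 2),
                           stringsAsFactors = FALSE)
  list(reference = reference, mutations = mutations,
       peptidome = peptidome(peptides, "I"), expression = expression,
       bounds = bounds)
}
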