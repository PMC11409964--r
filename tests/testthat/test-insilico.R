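pair_of <- function(seq, pos, alt = NULL) {
  ref_aa <- substr(seq, pos, pos)
  if (is.null(alt)) alt <- setdiff(c("A", "G"), ref_aa)[1L]
  ref <- data.frame(protein_id = "P1", gene_id = "G1", sequence = seq,
                    stringsAsFactors = FALSE)
  mut <- data.frame(protein_id = "P1", position = pos, ref_aa = ref_aa,
                    alt_aa = alt, gene_id = "G1",
                    label = paste0("p.", ref_aa, pos, alt),
                    stringsAsFactors = FALSE)
  list(pair = build_proteome_pair(ref, mut), mutation = mut)
}

test_that("window enumeration clips at protein ends and hits the
           combinatorial count", {
  set.seed(21)
  long <- random_aa_string(60L)

  # site at position 1: only one window per length
  p <- pair_of(long, 1L)
  k9 <- enumerate_mutant_kmers(p$pair, p$mutation, lengths = 9L)
  expect_equal(nrow(k9), 1L)
  expect_equal(k9$site_offset, 1L)

  # interior site: k windows of length k, 50 in total for lengths 8-12
  p <- pair_of(long, 30L)
  expect_equal(nrow(enumerate_mutant_kmers(p$pair, p$mutation,
                                           lengths = 9L)), 9L)
  all_w <- enumerate_mutant_kmers(p$pair, p$mutation)
  expect_equal(nrow(all_w), sum(8:12))
  # every window contains the substituted residue at the stated offset
  expect_true(all(substr(all_w$peptide, all_w$site_offset,
                         all_w$site_offset) == p$mutation$alt_aa))
})

test_that("window enumeration equals brute-force substring enumeration", {
  set.seed(22)
  for (rep in 1:15) {
    len <- sample(12:40, 1L)
    pos <- sample1(seq_len(len))
    p <- pair_of(random_aa_string(len), pos)
    got <- enumerate_mutant_kmers(p$pair, p$mutation)$peptide
    want <- oracle_windows(p$pair$mt[["P1"]], pos, 8:12)
    expect_equal(sort(got), sort(want))
  }
})

test_that("best rank is the minimum over windows and alleles", {
  set.seed(23)
  p <- pair_of(random_aa_string(40L), 20L)
  alleles <- c("HLA-A*02:01", "HLA-B*07:02")
  kmers <- enumerate_mutant_kmers(p$pair, p$mutation)
  table <- stub_rank_table(kmers$peptide, alleles)
  table$rank <- table$rank + 5  # keep everything above the weak threshold
  j <- sample(nrow(table), 1L)
  table$rank[j] <- 0.3
  expr <- data.frame(gene_id = "G1", tpm = 10)
  s <- summarize_mutation(p$mutation, p$pair, table, alleles, expr)
  expect_equal(s$best_rank, 0.3)
  expect_equal(s$best_peptide, table$peptide[j])
  expect_equal(s$best_allele, table$allele[j])
  expect_true(s$is_candidate && s$is_strong)

  # permutation invariance in allele and table order
  s2 <- summarize_mutation(p$mutation, p$pair,
                           table[sample(nrow(table)), ], rev(alleles), expr)
  expect_equal(s2$best_rank, s$best_rank)

  # naive min oracle on fully random tables
  for (rep in 1:10) {
    table$rank <- stats::runif(nrow(table), 0, 50)
    s3 <- summarize_mutation(p$mutation, p$pair, table, alleles, expr)
    expect_equal(s3$best_rank, min(table$rank))
  }
})

test_that("candidate rule needs rank below weak threshold AND expression", {
  set.seed(24)
  p <- pair_of(random_aa_string(40L), 20L)
  kmers <- enumerate_mutant_kmers(p$pair, p$mutation)
  table <- stub_rank_table(kmers$peptide, "HLA-A*02:01")
  table$rank <- stats::runif(nrow(table), 2.0, 50)  # all at/above weak
  s <- summarize_mutation(p$mutation, p$pair, table, "HLA-A*02:01",
                          data.frame(gene_id = "G1", tpm = 100))
  expect_false(s$is_candidate)  # rank fails regardless of TPM

  table$rank[1L] <- 0.1
  s <- summarize_mutation(p$mutation, p$pair, table, "HLA-A*02:01",
                          data.frame(gene_id = "G1", tpm = 0.5))
  expect_false(s$is_candidate)  # TPM fails despite strong rank
  expect_true(s$is_strong)
})

test_that("missing table entries error under strict and warn under lenient", {
  p <- pair_of("ACDEFGHIKLMNPQRSTVWY", 10L)
  # score only one of the enumerated mutant windows
  w <- enumerate_mutant_kmers(p$pair, p$mutation)
  table <- data.frame(peptide = w$peptide[1L], allele = "X", rank = 1)
  expect_error(
    summarize_mutation(p$mutation, p$pair, table, "X", missing = "strict"),
    "no %rank entry", fixed = TRUE)
  expect_warning(
    s <- summarize_mutation(p$mutation, p$pair, table, "X",
                            missing = "lenient"),
    "skipped")
  expect_equal(s$best_rank, 1)
})

test_that("planted rank tables are counted per the weak/strong and TPM
           rules", {
  set.seed(25)
  for (rep in 1:5) {
    ref <- random_proteome_df(8L, c(60L, 120L))
    muts <- random_mutations_df(ref, 5L, per_protein = 2L)
    pair <- build_proteome_pair(ref, muts)
    planted <- simulate_rank_table(pair, muts)
    expr <- data.frame(gene_id = ref$gene_id, tpm = 10)  # expression passes
    res <- count_insilico_candidates(muts, pair, planted$table,
                                     "HLA-A*02:01", expr)
    des <- planted$design
    clear <- des$planted_class != "entangled"
    got <- res$summaries[clear, ]
    expect_equal(got$best_rank, des$planted_best[clear])
    expect_equal(got$is_candidate, des$planted_class[clear] %in%
                   c("strong", "weak"))
    expect_equal(got$is_candidate & got$is_strong,
                 des$planted_class[clear] == "strong")
    expect_lte(res$n_strong, res$n_candidates)
  }
})

test_that("zero mutations count to zero and lowering the weak threshold is
           monotone", {
  p <- pair_of("ACDEFGHIKLMNPQRSTVWY", 10L)
  expr <- data.frame(gene_id = "G1", tpm = 10)
  empty <- count_insilico_candidates(p$mutation[0, ], p$pair,
                                     data.frame(peptide = character(0),
                                                allele = character(0),
                                                rank = numeric(0)),
                                     "X", expr)
  expect_equal(empty$n_candidates, 0L)

  set.seed(26)
  kmers <- enumerate_mutant_kmers(p$pair, p$mutation)
  table <- stub_rank_table(kmers$peptide, "X")
  table$rank <- stats::runif(nrow(table), 0, 4)
  counts <- vapply(c(3, 2, 1, 0.5, 0.1), function(w) {
    count_insilico_candidates(p$mutation, p$pair, table, "X", expr,
                              weak = w, strong = w / 4)$n_candidates
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("enumerated windows export as FASTA for external scoring", {
  p <- pair_of("ACDEFGHIKLMNPQRSTVWY", 10L)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_mutant_kmers(p$mutation, p$pair, f)
  back <- Biostrings::readAAStringSet(f)
  expect_equal(sort(as.character(back)),
               sort(enumerate_mutant_kmers(p$pair, p$mutation)$peptide),
               ignore_attr = TRUE)
})
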