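test_that("class length filter keeps 8-12-mers (I) and 10-25-mers (II)", {
  p1 <- peptidome(c("AAAAAAA", "CCCCCCCC", "DDDDDDDDDDDD",
                    "EEEEEEEEEEEEE"), "I")
  kept <- length_filter(p1)
  expect_equal(sort(nchar(kept$peptides)), c(8L, 12L))
  expect_equal(kept$n_length_filtered, 2L)

  p2 <- peptidome("KGEIAASIVTHMRPY", "II")  # 15-mer
  expect_equal(length_filter(p2)$peptides, "KGEIAASIVTHMRPY")

  empty <- peptidome(character(0), "I")
  expect_equal(length(length_filter(empty)$peptides), 0L)
})

test_that("occurrence search enumerates overlapping matches in order", {
  expect_equal(locate_occurrences("KLNPQQFEV", c(P1 = "AAKLNPQQFEVAA")),
               data.frame(protein_id = "P1", start = 3L))
  expect_equal(locate_occurrences("AA", c(P1 = "AAAA"))$start, 1:3)
  occ <- locate_occurrences("MM", c(B = "MMM", A = "ZMMZ"))
  expect_equal(occ$protein_id, c("A", "B", "B"))
  expect_equal(occ$start, c(2L, 1L, 2L))
})

test_that("occurrence search equals a naive scan on random inputs", {
  set.seed(11)
  for (rep in 1:20) {
    seqs <- stats::setNames(
      vapply(sample(20:60, 4L, replace = TRUE), random_aa_string, ""),
      paste0("S", 1:4))
    pep <- random_aa_string(sample(2:4, 1L))  # short: collisions likely
    got <- locate_occurrences(pep, seqs)
    want <- do.call(rbind, lapply(sort(names(seqs)), function(id) {
      s <- naive_scan(pep, seqs[[id]])
      if (length(s)) data.frame(protein_id = id, start = s)
    }))
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      row.names(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("counterpart search applies the wt-only membership rule", {
  # substitution inside the embedded peptide: wt-only, one match
  fx <- rtf9_inside()
  pair <- build_proteome_pair(fx$reference, fx$mutations)
  pep <- peptidome("RYLTVAAVF", "I")
  matches <- find_counterparts(pep, pair)
  expect_equal(nrow(matches), 1L)
  expect_equal(matches$covered_sites[[1L]], 7L)
  expect_equal(mutant_peptide(matches[1L, ], pair), "RYLAVAAVF")

  # peptide in an unmutated region occurs in both proteomes: no match
  wx <- worked_example()
  wpair <- build_proteome_pair(wx$reference, wx$mutations)
  both <- find_counterparts(peptidome("RYLTVAAVF", "I"), wpair)
  expect_equal(nrow(both), 0L)
})

test_that("published wild-type to mutant substitutions are exact", {
  wx <- worked_example()
  pair <- build_proteome_pair(wx$reference, wx$mutations)
  cases <- list(
    list(wt = "KLNPQQFEV", mut = "KLNPQRFEV"),
    list(wt = "KLWDIINVNI", mut = "KLWDIVNVNI"),
    list(wt = "KGEIAASIATHMRPY", mut = "KGEIAASIVTHMRPY"))
  for (cs in cases) {
    m <- find_counterparts(peptidome(cs$wt, "I"), pair)
    expect_equal(nrow(m), 1L)
    expect_equal(mutant_peptide(m[1L, ], pair), cs$mut)
  }
})

test_that("length variants over one site collapse to a single candidate", {
  wx <- worked_example()
  pair <- build_proteome_pair(wx$reference, wx$mutations)
  # three windows over the same A->V site of the 15-mer's protein
  variants <- c("KGEIAASIATHMRPY", "GEIAASIATHMRPY", "KGEIAASIATHMRP")
  m <- find_counterparts(peptidome(variants, "II"), pair)
  cand <- collapse_matches(m, pair, "II")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_members, 3L)
  # representative: longest member, lexicographic tie-break
  expect_equal(cand$representative_wt, "KGEIAASIATHMRPY")
  expect_equal(cand$representative_mut, "KGEIAASIVTHMRPY")
  expect_equal(sort(cand$members_wt[[1L]]), sort(variants))

  one <- collapse_matches(m[1L, ], pair, "II")
  expect_equal(one$n_members, 1L)
})

test_that("peptides covering different site sets form different candidates", {
  ref <- data.frame(protein_id = "P1", gene_id = "G1",
                    sequence = "MAAACDEFGHIKLMNPQRSTVWYYA",
                    stringsAsFactors = FALSE)
  mut <- data.frame(protein_id = c("P1", "P1"), position = c(10L, 14L),
                    ref_aa = c("H", "M"), alt_aa = c("Q", "W"),
                    gene_id = "G1", label = c("a", "b"),
                    stringsAsFactors = FALSE)
  pair <- build_proteome_pair(ref, mut)
  # one peptide spans both sites, one covers only the first
  pep <- peptidome(c("FGHIKLMN", "CDEFGHIK"), "I")
  cand <- collapse_matches(find_counterparts(pep, pair), pair, "I")
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$covered_positions, c("10", "10,14"))
})

test_that("expression filter excludes the TPM boundary and flags missing
           genes", {
  wx <- worked_example()
  pair <- build_proteome_pair(wx$reference, wx$mutations)
  m <- find_counterparts(length_filter(wx$peptidome, c(8L, 25L)), pair)
  cand <- collapse_matches(m, pair, "I")
  expr <- data.frame(gene_id = c("G2", "G3"), tpm = c(0.5, 1.0))
  out <- expression_filter(cand, expr)
  flags <- stats::setNames(out$filter_flags, out$gene_id)
  expect_equal(unname(flags["G2"]), "LOW_EXPRESSION")   # 0.5 <= 1
  expect_equal(unname(flags["G3"]), "LOW_EXPRESSION")   # boundary excluded
  expect_equal(unname(flags["G4"]), "NO_EXPRESSION_DATA")
  expect_true(out$pass[out$gene_id == "G4"])            # retained by default
  strict <- expression_filter(cand, expr, strict = TRUE)
  expect_false(any(strict$pass))
})

test_that("random TPM draws give PASS exactly above the threshold", {
  set.seed(12)
  wx <- worked_example()
  pair <- build_proteome_pair(wx$reference, wx$mutations)
  m <- find_counterparts(length_filter(wx$peptidome, c(8L, 25L)), pair)
  cand <- collapse_matches(m, pair, "I")
  for (rep in 1:25) {
    tpm <- round(stats::rlnorm(5, 0, 1.5), 3)
    expr <- data.frame(gene_id = paste0("G", 1:5), tpm = tpm)
    out <- expression_filter(cand, expr)
    expect_equal(out$pass, out$tpm > 1.0)
  }
})

test_that("full pipeline equals the brute-force oracle on random instances", {
  set.seed(13)
  for (rep in 1:30) {
    inst <- random_instance()
    res <- run_nessie(inst$peptidome, inst$reference, inst$mutations,
                      inst$expression, length_bounds = inst$bounds)
    want <- oracle_nessie(inst$peptidome$peptides, inst$reference,
                          inst$mutations, inst$expression, inst$bounds)
    expect_equal(canon_candidates(res$candidates), want)
  }
})

test_that("adding mutant-proteome peptides never changes the output and
           raising the threshold never grows the PASS set", {
  set.seed(14)
  inst <- random_instance()
  pair <- build_proteome_pair(inst$reference, inst$mutations)
  res0 <- run_nessie(inst$peptidome, inst$reference, inst$mutations,
                     inst$expression, length_bounds = inst$bounds)
  # peptides drawn from mutant sequences are rejected by membership
  mt_peps <- vapply(1:10, function(i) {
    s <- pair$mt[[sample1(seq_along(pair$mt))]]
    start <- sample1(seq_len(nchar(s) - 9L))
    substr(s, start, start + 8L)
  }, "")
  aug <- peptidome(c(inst$peptidome$peptides, mt_peps), "I")
  res1 <- run_nessie(aug, inst$reference, inst$mutations, inst$expression,
                     length_bounds = inst$bounds)
  expect_equal(canon_candidates(res1$candidates),
               canon_candidates(res0$candidates))

  n_pass <- vapply(c(0.5, 1, 2, 5, 50), function(thr) {
    r <- run_nessie(inst$peptidome, inst$reference, inst$mutations,
                    inst$expression, tpm_threshold = thr,
                    length_bounds = inst$bounds)
    nrow(r$pass)
  }, 1)
  expect_true(all(diff(n_pass) <= 0))
})

test_that("isoleucine/leucine-equivalent mode folds matching but reports
           literal sequences", {
  ref <- data.frame(protein_id = "P1", gene_id = "G1",
                    sequence = "MAAKLWDIINVNIGG", stringsAsFactors = FALSE)
  mut <- data.frame(protein_id = "P1", position = 9L, ref_aa = "I",
                    alt_aa = "V", gene_id = "G1", label = "p.I9V",
                    stringsAsFactors = FALSE)
  # peptide differs from the protein only by I<->L swaps
  pep <- peptidome("KIWDLINVNI", "I")
  pair <- build_proteome_pair(ref, mut)
  expect_equal(nrow(find_counterparts(pep, pair)), 0L)
  m <- find_counterparts(pep, pair, il_equivalent = TRUE)
  expect_equal(nrow(m), 1L)
  expect_equal(mutant_peptide(m[1L, ], pair), "KLWDIVNVNI")  # wt coordinates
})

test_that("pipeline runs are deterministic and empty inputs give empty
           reports", {
  wx <- worked_example()
  r1 <- run_nessie(wx$peptidome, wx$reference, wx$mutations, wx$expression,
                   length_bounds = c(8L, 25L))
  r2 <- run_nessie(wx$peptidome, wx$reference, wx$mutations, wx$expression,
                   length_bounds = c(8L, 25L))
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(r1$report, r2$report)

  none <- run_nessie(peptidome(character(0), "I"), wx$reference,
                     wx$mutations, wx$expression)
  expect_equal(nrow(none$candidates), 0L)
  expect_equal(none$report$counts$peptides_in, 0L)
  expect_equal(none$report$counts$pass, 0L)
})
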