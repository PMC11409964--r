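## Ground-truthed synthetic inputs: a random proteome with implanted
## single-residue substitutions, a surrogate peptidome containing wild-type
## counterpart peptides (plus length variants to exercise collapsing) and
## decoys of each failure class, a log-normal TPM table, and optionally a
## planted %rank table. Every decoy's intended failure mode is verified by
## running the membership tests, not assumed; accidental qualifiers are
## redrawn.

#' Simulation parameters
#'
#' Defaults emulate a desk-scale version of the study inputs: a small
#' reference proteome, a handful of mutated proteins with one or two missense
#' changes each, counterpart peptides of class-appropriate length with length
#' variants, wild-type-region and mutant-region decoys, and log-normal
#' gene-level TPM with a fixed fraction of low-expressed mutated genes.
#'
#' @param n_proteins number of reference proteins.
#' @param protein_length_range `c(min, max)` protein lengths.
#' @param n_mutated_proteins proteins receiving mutations.
#' @param mutations_per_protein `c(min, max)` substitutions per mutated
#'   protein.
#' @param hla_class `"I"` or `"II"`.
#' @param n_counterpart_peptides implanted wild-type counterparts (one core
#'   peptide per distinct site, cycling over sites).
#' @param length_variants_per_site extra N-/C-shifted windows per counterpart
#'   (exercises collapsing).
#' @param n_decoy_peptides peptides from unmutated regions (occur in both
#'   proteomes; must be rejected).
#' @param n_mt_decoys peptides drawn from mutant sequences across a site
#'   (occur in the mutant proteome; must be rejected).
#' @param tpm_meanlog,tpm_sdlog log-normal TPM parameters.
#' @param fraction_low_expression fraction of mutated genes forced to
#'   TPM <= tpm threshold (their candidates must be expression-filtered).
#' @param tpm_threshold expression threshold the truth is computed against.
#' @return list of validated parameters.
#' @export
sim_params <- function(n_proteins = 30L,
                       protein_length_range = c(150L, 400L),
                       n_mutated_proteins = 6L,
                       mutations_per_protein = c(1L, 2L),
                       hla_class = "I",
                       n_counterpart_peptides = 8L,
                       length_variants_per_site = 2L,
                       n_decoy_peptides = 10L,
                       n_mt_decoys = 10L,
                       tpm_meanlog = 1, tpm_sdlog = 2,
                       fraction_low_expression = 0.25,
                       tpm_threshold = 1.0) {
  assert_hla_class(hla_class)
  stopifnot(n_proteins >= 1L, n_mutated_proteins >= 1L,
            n_mutated_proteins <= n_proteins,
            protein_length_range[1L] >= 30L,
            protein_length_range[1L] <= protein_length_range[2L],
            mutations_per_protein[1L] >= 1L,
            n_counterpart_peptides >= 0L, length_variants_per_site >= 0L,
            n_decoy_peptides >= 0L, n_mt_decoys >= 0L,
            fraction_low_expression >= 0, fraction_low_expression <= 1)
  bounds <- class_length_bounds(hla_class)
  if (protein_length_range[1L] < bounds[2L]) {
    stop("proteins must be at least as long as the longest class-legal ",
         "peptide (", bounds[2L], ")", call. = FALSE)
  }
  as.list(environment())
}

random_protein <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

## A window of class-legal length containing `pos`, clipped at sequence ends.
random_window <- function(len_seq, pos, bounds) {
  k <- sample(seq(bounds[1L], bounds[2L]), 1L)
  lo <- max(1L, pos - k + 1L)
  hi <- min(pos, len_seq - k + 1L)
  start <- if (lo >= hi) lo else sample(seq(lo, hi), 1L)
  c(start = start, k = k)
}

occurs_anywhere <- function(peptide, sequences) {
  any(vapply(sequences, function(s) grepl(peptide, s, fixed = TRUE), TRUE))
}

#' Generate a ground-truthed synthetic dataset
#'
#' Draws a random proteome, implants missense mutations, builds the surrogate
#' peptidome (counterparts + length variants + decoys), samples log-normal
#' TPM, and records the expected NESSIE output (`truth`). Counterparts are
#' verified to occur in the wild-type proteome, cover their site, and be
#' absent from every mutant sequence; wild-type-region decoys are verified
#' present in the mutant proteome; mutant decoys are substrings of a mutant
#' sequence across a site. Reproducible: same seed, same params, same output.
#'
#' @param params from [sim_params()].
#' @param seed integer RNG seed.
#' @return list with `reference`, `mutations`, `peptidome`, `expression`,
#'   `peptide_labels` (data.frame peptide -> class), and `truth` (data.frame
#'   of expected candidate groups: `protein_id`, `covered_positions`,
#'   `members_wt` / `members_mut` list-columns, `tpm`, `expect_pass`).
#' @export
simulate_dataset <- function(params = sim_params(), seed = 1L) {
  set.seed(seed)
  bounds <- class_length_bounds(params$hla_class)

  ## reference proteome
  lens <- sample(seq(params$protein_length_range[1L],
                     params$protein_length_range[2L]),
                 params$n_proteins, replace = TRUE)
  ids <- sprintf("PROT%03d", seq_len(params$n_proteins))
  genes <- sprintf("GENE%03d", seq_len(params$n_proteins))
  reference <- data.frame(
    protein_id = ids, gene_id = genes,
    sequence = vapply(lens, random_protein, ""),
    stringsAsFactors = FALSE)

  ## mutations: distinct positions per protein, spaced away from ends enough
  ## for full windows (clipping is still exercised by random window starts)
  mut_ids <- sample(ids, params$n_mutated_proteins)
  muts <- do.call(rbind, lapply(mut_ids, function(pid) {
    seq_i <- reference$sequence[reference$protein_id == pid]
    n_mut <- sample(seq(params$mutations_per_protein[1L],
                        params$mutations_per_protein[2L]), 1L)
    pos <- sort(sample(seq_len(nchar(seq_i)), n_mut))
    ref <- substring(seq_i, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(AA_STANDARD, r), 1L), "",
                  USE.NAMES = FALSE)
    data.frame(protein_id = pid, position = pos, ref_aa = ref, alt_aa = alt,
               gene_id = reference$gene_id[reference$protein_id == pid],
               label = paste0(pid, " p.", ref, pos, alt),
               stringsAsFactors = FALSE)
  }))
  row.names(muts) <- NULL
  pair <- build_proteome_pair(reference, muts)

  ## expression: log-normal TPM; a designated fraction of mutated genes is
  ## forced at or below the threshold
  tpm <- stats::rlnorm(params$n_proteins, params$tpm_meanlog,
                       params$tpm_sdlog)
  expression <- data.frame(gene_id = genes, tpm = tpm,
                           stringsAsFactors = FALSE)
  mut_genes <- unique(muts$gene_id)
  n_low <- round(params$fraction_low_expression * length(mut_genes))
  low_genes <- if (n_low > 0L) sample(mut_genes, n_low) else character(0)
  expression$tpm[expression$gene_id %in% low_genes] <-
    stats::runif(sum(expression$gene_id %in% low_genes), 0,
                 params$tpm_threshold)
  high <- setdiff(mut_genes, low_genes)
  idx_high <- expression$gene_id %in% high &
    expression$tpm <= params$tpm_threshold
  expression$tpm[idx_high] <- params$tpm_threshold +
    stats::rlnorm(sum(idx_high), params$tpm_meanlog, 1)

  ## counterpart peptides: cycle over mutation sites; each site used gets one
  ## core window plus length variants, all covering exactly that one site and
  ## verified absent from every mutant sequence
  counterparts <- list()
  site_order <- sample(seq_len(nrow(muts)))
  n_sites_used <- min(params$n_counterpart_peptides, nrow(muts))
  used_sites <- site_order[seq_len(n_sites_used)]
  for (si in used_sites) {
    pid <- muts$protein_id[si]
    pos <- muts$position[si]
    wtseq <- pair$wt[[pid]]
    others <- muts$position[muts$protein_id == pid & muts$position != pos]
    fam <- character(0)
    tries <- 0L
    while (length(fam) < 1L + params$length_variants_per_site &&
           tries < 500L) {
      tries <- tries + 1L
      w <- random_window(nchar(wtseq), pos, bounds)
      end <- w["start"] + w["k"] - 1L
      if (any(others >= w["start"] & others <= end)) next  # single-site family
      pep <- substr(wtseq, w["start"], end)
      if (pep %in% fam) next
      if (occurs_anywhere(pep, pair$mt)) next   # must be wt-only
      fam <- c(fam, pep)
    }
    if (!length(fam)) next
    counterparts[[length(counterparts) + 1L]] <-
      list(site = si, peptides = fam)
  }

  ## decoys from unmutated regions: must occur in the mutant proteome too
  decoys_wt <- character(0)
  tries <- 0L
  while (length(decoys_wt) < params$n_decoy_peptides && tries < 2000L) {
    tries <- tries + 1L
    i <- sample(params$n_proteins, 1L)
    seq_i <- reference$sequence[i]
    k <- sample(seq(bounds[1L], bounds[2L]), 1L)
    start <- sample(seq_len(nchar(seq_i) - k + 1L), 1L)
    pep <- substr(seq_i, start, start + k - 1L)
    sites_i <- muts$position[muts$protein_id == reference$protein_id[i]]
    if (any(sites_i >= start & sites_i <= start + k - 1L)) next
    if (!occurs_anywhere(pep, pair$mt)) next  # verify the failure mode
    if (pep %in% decoys_wt) next
    decoys_wt <- c(decoys_wt, pep)
  }

  ## decoys from mutant sequences across a site: occur in the mutant
  ## proteome, so the search must reject them
  decoys_mt <- character(0)
  tries <- 0L
  while (length(decoys_mt) < params$n_mt_decoys && tries < 2000L &&
         nrow(muts) > 0L) {
    tries <- tries + 1L
    si <- sample(nrow(muts), 1L)
    pid <- muts$protein_id[si]
    mtseq <- pair$mt[[pid]]
    w <- random_window(nchar(mtseq), muts$position[si], bounds)
    pep <- substr(mtseq, w["start"], w["start"] + w["k"] - 1L)
    if (!occurs_anywhere(pep, pair$mt)) next
    if (pep %in% decoys_mt) next
    decoys_mt <- c(decoys_mt, pep)
  }

  counter_peps <- unlist(lapply(counterparts, `[[`, "peptides"))
  all_peps <- c(counter_peps, decoys_wt, decoys_mt)
  labels <- data.frame(
    peptide = all_peps,
    class = c(rep("counterpart", length(counter_peps)),
              rep("decoy_wt_unmutated_region", length(decoys_wt)),
              rep("decoy_in_mt", length(decoys_mt))),
    stringsAsFactors = FALSE)
  ## a peptide drawn twice keeps its first (counterpart-first) label
  labels <- labels[!duplicated(labels$peptide), , drop = FALSE]

  pepd <- peptidome(all_peps, params$hla_class,
                    sample_label = sprintf("sim_seed%d", seed))

  ## expected candidate groups: one per used site with a surviving family
  truth <- do.call(rbind, lapply(counterparts, function(cp) {
    si <- cp$site
    pid <- muts$protein_id[si]
    pos <- muts$position[si]
    g <- muts$gene_id[si]
    tpm_g <- expression$tpm[expression$gene_id == g]
    members <- sort(cp$peptides)
    df <- data.frame(protein_id = pid,
                     covered_positions = as.character(pos),
                     gene_id = g, tpm = tpm_g,
                     expect_pass = tpm_g > params$tpm_threshold,
                     stringsAsFactors = FALSE)
    df$members_wt <- list(members)
    df$members_mut <- list(vapply(members, function(p) {
      occ <- locate_occurrences(p, pair$wt[pid])
      mutant_peptide(list(peptide = p, protein_id = pid,
                          start = occ$start[1L]), pair)
    }, "", USE.NAMES = FALSE))
    df
  }))
  if (!is.null(truth)) row.names(truth) <- NULL

  list(reference = reference, mutations = muts, peptidome = pepd,
       expression = expression, peptide_labels = labels,
       truth = truth, pair = pair, params = params, seed = seed)
}

#' Write a simulated dataset to disk in the package file dialects
#'
#' @param sim result of [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return invisible named character vector of files written.
#' @export
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteome = file.path(out_dir, "proteome.fasta"),
    mutations = file.path(out_dir, "mutations.tsv"),
    peptides = file.path(out_dir, "peptides.txt"),
    expression = file.path(out_dir, "expression.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_proteome(sim$reference, paths["proteome"])
  write_mutations(sim$mutations, paths["mutations"])
  write_peptides(sim$peptidome, paths["peptides"])
  write_expression(sim$expression, paths["expression"])
  truth_flat <- if (is.null(sim$truth)) {
    data.frame(protein_id = character(0), covered_positions = character(0),
               gene_id = character(0), tpm = numeric(0),
               expect_pass = logical(0), members_wt = character(0),
               members_mut = character(0))
  } else {
    data.frame(
      sim$truth[c("protein_id", "covered_positions", "gene_id", "tpm",
                  "expect_pass")],
      members_wt = vapply(sim$truth$members_wt, paste, "", collapse = ","),
      members_mut = vapply(sim$truth$members_mut, paste, "", collapse = ","))
  }
  utils::write.table(truth_flat, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Plant a %rank table with a designed candidate structure
#'
#' Builds a rank table covering every mutant k-mer window of every mutation
#' for the given alleles, then assigns each mutation a designed best %rank:
#' strong binders below the strong threshold, weak binders between the
#' thresholds, and non-binders above the weak threshold. All other entries
#' are filled well above the weak threshold. The returned design records
#' each mutation's intended class so counting can be checked against it.
#'
#' @param pair a `proteome_pair`.
#' @param mutations mutation data.frame.
#' @param alleles character vector of alleles.
#' @param p_strong,p_weak probabilities of the strong / weak classes (the
#'   remainder are non-binders).
#' @param weak,strong the thresholds the design is planted around.
#' @param lengths window lengths.
#' @return list with `table` (rank data.frame) and `design` (data.frame:
#'   `protein_id`, `position`, `planted_class`, `planted_best`). Mutations
#'   whose window sets intersect another mutation's (sites closer than the
#'   longest window on one protein) are marked `entangled` and carry no
#'   planted class, since a shared window's score cannot be set for both
#'   independently.
#' @export
simulate_rank_table <- function(pair, mutations, alleles = "HLA-A*02:01",
                                p_strong = 0.3, p_weak = 0.3,
                                weak = 2.0, strong = 0.5, lengths = 8:12) {
  n <- nrow(mutations)
  windows <- lapply(seq_len(n), function(i) {
    enumerate_mutant_kmers(pair, mutations[i, , drop = FALSE],
                           lengths = lengths)$peptide
  })
  counts <- table(unlist(lapply(windows, unique)))
  entangled <- vapply(windows, function(w) any(counts[unique(w)] > 1L), TRUE)

  classes <- ifelse(entangled, "entangled",
                    sample(c("strong", "weak", "none"), n, replace = TRUE,
                           prob = c(p_strong, p_weak,
                                    1 - p_strong - p_weak)))
  design <- data.frame(protein_id = mutations$protein_id,
                       position = mutations$position,
                       planted_class = classes,
                       planted_best = NA_real_,
                       stringsAsFactors = FALSE)
  tabs <- vector("list", n)
  for (i in seq_len(n)) {
    grid <- expand.grid(peptide = unique(windows[[i]]), allele = alleles,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    grid$rank <- stats::runif(nrow(grid), weak + 1, 50)
    if (!entangled[i]) {
      ## planted value always undercuts the (weak+1, 50) fillers, so the
      ## mutation's best %rank is the planted one in every class
      best <- switch(classes[i],
                     strong = stats::runif(1, 0, strong * 0.99),
                     weak = stats::runif(1, strong * 1.01, weak * 0.99),
                     none = stats::runif(1, weak * 1.01, weak + 1))
      grid$rank[sample(nrow(grid), 1L)] <- best
      design$planted_best[i] <- best
    }
    tabs[[i]] <- grid
  }
  table <- do.call(rbind, tabs)
  key <- paste(table$peptide, table$allele)
  table <- table[!duplicated(key), , drop = FALSE]
  row.names(table) <- NULL
  list(table = table, design = design)
}
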