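## Tandem IVTT screening-construct design. Each candidate peptide becomes a
## self-contained expression unit -- T7 promoter, ribosome-binding site,
## ATG + FLAG tag, peptide codons, stop codon, 3'UTR stem-loop -- so a single
## vector carrying up to ten units can be translated as a pool, or one unit
## excised with its flanking restriction-site pair and translated alone.
## Enterokinase cleaves after the FLAG's DDDDK, releasing the peptide with no
## extra N-terminal residues.

FLAG_PEPTIDE <- "DYKDDDDK"

## E. coli K-12 codon usage, occurrences per thousand codons. Used to pick
## the most-frequent codon per residue; the IVTT kit is an E. coli
## reconstituted system.
ecoli_codon_usage <- function() {
  usage <- c(
    TTT = 22.2, TTC = 16.6, TTA = 13.9, TTG = 13.7,
    CTT = 11.0, CTC = 11.0, CTA = 3.9,  CTG = 52.6,
    ATT = 30.3, ATC = 25.1, ATA = 4.4,  ATG = 27.9,
    GTT = 18.3, GTC = 15.3, GTA = 10.9, GTG = 26.4,
    TCT = 8.5,  TCC = 8.6,  TCA = 7.2,  TCG = 8.9,
    CCT = 7.0,  CCC = 5.5,  CCA = 8.4,  CCG = 23.2,
    ACT = 9.0,  ACC = 23.4, ACA = 7.1,  ACG = 14.4,
    GCT = 15.3, GCC = 25.5, GCA = 20.1, GCG = 33.6,
    TAT = 16.2, TAC = 12.2, TAA = 2.0,  TAG = 0.2,
    CAT = 12.9, CAC = 9.7,  CAA = 15.3, CAG = 28.8,
    AAT = 17.7, AAC = 21.7, AAA = 33.6, AAG = 10.3,
    GAT = 32.1, GAC = 19.1, GAA = 39.4, GAG = 17.8,
    TGT = 5.2,  TGC = 6.4,  TGA = 1.0,  TGG = 15.2,
    CGT = 20.9, CGC = 22.0, CGA = 3.6,  CGG = 5.4,
    AGT = 8.8,  AGC = 16.1, AGA = 2.1,  AGG = 1.2,
    GGT = 24.7, GGC = 29.6, GGA = 8.0,  GGG = 11.1)
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon = names(usage),
             aa = unname(gc[names(usage)]),
             frequency = unname(usage),
             stringsAsFactors = FALSE)
}

#' Default codon-usage table (E. coli K-12)
#'
#' Per-thousand codon frequencies with the amino acid each codon encodes
#' (stop codons as `*`). Any table with columns `codon`, `aa`, `frequency`
#' covering the 20 standard residues can substitute.
#'
#' @return data.frame with columns `codon`, `aa`, `frequency`.
#' @export
default_codon_table <- function() ecoli_codon_usage()

#' Default restriction-enzyme catalog
#'
#' Common non-degenerate 6- and 8-cutters as a named character vector
#' (enzyme name -> recognition sequence).
#'
#' @return named character vector.
#' @export
default_enzyme_catalog <- function() {
  c(EcoRI = "GAATTC", BamHI = "GGATCC", HindIII = "AAGCTT", XhoI = "CTCGAG",
    SalI = "GTCGAC", XbaI = "TCTAGA", NotI = "GCGGCCGC", SpeI = "ACTAGT",
    KpnI = "GGTACC", SacI = "GAGCTC", PstI = "CTGCAG", NheI = "GCTAGC",
    BglII = "AGATCT", MluI = "ACGCGT", AflII = "CTTAAG", AgeI = "ACCGGT",
    ApaI = "GGGCCC", AvrII = "CCTAGG", BsrGI = "TGTACA", ClaI = "ATCGAT",
    NcoI = "CCATGG", NdeI = "CATATG", SphI = "GCATGC", StuI = "AGGCCT")
}

#' Default regulatory-element sequences
#'
#' Canonical T7 promoter, an E. coli ribosome-binding-site region, TAA stop
#' and a T7-terminator-class 3'UTR stem-loop. All fully configurable; the
#' construct anatomy, not these exact bases, is what the design fixes.
#'
#' @return named list with `t7_promoter`, `rbs`, `stop_codon`, `stem_loop`.
#' @export
default_ivtt_elements <- function() {
  list(t7_promoter = "TAATACGACTCACTATAGGG",
       rbs = "TTTAAGAAGGAGATATACC",
       stop_codon = "TAA",
       stem_loop = "TAGCATAACCCCTTGGGGCCTCTAAACGGGTCTTGAGGGGTTTTTTG")
}

## Translate a coding DNA string (standard genetic code); stops as "*".
translate_cds <- function(nt) {
  stopifnot(nchar(nt) %% 3L == 0L)
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Reverse-translate a peptide to DNA
#'
#' Deterministic by default: each residue gets its most-frequent codon in the
#' usage table (ties broken alphabetically). With `randomize = TRUE` codons
#' are drawn proportionally to usage under the current RNG state, which
#' avoids long repeated-codon runs in homopolymeric stretches.
#'
#' @param peptide peptide string (standard residues only).
#' @param codon_table data.frame with `codon`, `aa`, `frequency`.
#' @param randomize sample codons by usage instead of taking the maximum.
#' @return nucleotide string; translating it back yields `peptide`.
#' @export
#' @examples
#' reverse_translate("MW")  # "ATGTGG"
reverse_translate <- function(peptide, codon_table = default_codon_table(),
                              randomize = FALSE) {
  residues <- strsplit(toupper(peptide), "")[[1L]]
  bad <- setdiff(residues, AA_STANDARD)
  if (length(bad)) {
    stop("cannot reverse-translate non-standard residue(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  codons <- vapply(residues, function(aa) {
    rows <- codon_table[codon_table$aa == aa, , drop = FALSE]
    if (!nrow(rows)) stop("codon table lacks residue ", aa, call. = FALSE)
    rows <- rows[order(-rows$frequency, rows$codon), , drop = FALSE]
    if (randomize) {
      sample(rows$codon, 1L, prob = rows$frequency)
    } else {
      rows$codon[1L]
    }
  }, "", USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

#' Assemble one tandem-IVTT neoantigen unit
#'
#' Concatenates T7 promoter, RBS, `ATG` + FLAG codons + peptide codons, stop
#' codon and 3'UTR stem-loop. The coding frame is checked to translate to
#' `M` + FLAG + peptide, and when a flanking site pair is supplied, neither
#' recognition sequence may occur inside the insert.
#'
#' @param peptide peptide string.
#' @param index unit index within the design (integer).
#' @param site_pair optional named character vector of length 2 (5' and 3'
#'   enzyme recognition sequences, names = enzyme names).
#' @param elements regulatory elements ([default_ivtt_elements()]).
#' @param codon_table codon-usage table.
#' @param randomize passed to [reverse_translate()].
#' @return an `ivtt_unit`: list with `peptide`, `index`, `nt_insert`,
#'   `coding`, `site_5p`, `site_3p`.
#' @export
build_unit <- function(peptide, index, site_pair = NULL,
                       elements = default_ivtt_elements(),
                       codon_table = default_codon_table(),
                       randomize = FALSE) {
  coding <- paste0("ATG",
                   reverse_translate(FLAG_PEPTIDE, codon_table, randomize),
                   reverse_translate(peptide, codon_table, randomize))
  nt <- paste0(elements$t7_promoter, elements$rbs, coding,
               elements$stop_codon, elements$stem_loop)
  if (!grepl("^[ACGT]+$", nt)) {
    stop("unit insert contains non-ACGT characters; check element sequences",
         call. = FALSE)
  }
  got <- translate_cds(coding)
  want <- paste0("M", FLAG_PEPTIDE, toupper(peptide))
  if (got != want) {
    stop("coding-frame check failed for unit ", index, ": translated '",
         got, "', expected '", want, "'", call. = FALSE)
  }
  unit <- structure(
    list(peptide = toupper(peptide), index = as.integer(index),
         nt_insert = nt, coding = coding,
         site_5p = NULL, site_3p = NULL),
    class = "ivtt_unit")
  if (!is.null(site_pair)) unit <- set_unit_sites(unit, site_pair)
  unit
}

set_unit_sites <- function(unit, site_pair) {
  stopifnot(length(site_pair) == 2L, !is.null(names(site_pair)))
  for (i in 1:2) {
    if (grepl(site_pair[[i]], unit$nt_insert, fixed = TRUE)) {
      stop("restriction site ", names(site_pair)[i], " (", site_pair[[i]],
           ") occurs inside the insert of unit ", unit$index,
           "; reassign sites", call. = FALSE)
    }
  }
  unit$site_5p <- site_pair[1L]
  unit$site_3p <- site_pair[2L]
  unit
}

#' Pack units into tandem vectors
#'
#' Greedy sequential packing preserving input order, at most `capacity`
#' units per vector. Vector names are `V01, V02, ...`, zero-padded to at
#' least width 2.
#'
#' @param units list of `ivtt_unit` objects (or any list; order preserved).
#' @param capacity maximum units per vector (default 10).
#' @return named list of vectors, each a list of units.
#' @export
#' @examples
#' length(pack_vectors(as.list(1:126)))  # 13
pack_vectors <- function(units, capacity = 10L) {
  stopifnot(capacity >= 1L)
  n <- length(units)
  n_vec <- ceiling(n / capacity)
  if (n_vec == 0L) return(stats::setNames(list(), character(0)))
  width <- max(2L, nchar(as.character(n_vec)))
  names <- sprintf(paste0("V%0", width, "d"), seq_len(n_vec))
  idx <- split(seq_len(n), ceiling(seq_len(n) / capacity))
  stats::setNames(lapply(idx, function(i) units[i]), names)
}

#' Assign unique flanking restriction sites to one vector's units
#'
#' Adjacent units share a site (n units need n + 1 enzymes), so every unit
#' gets a distinct (5', 3') pair and any single unit can be excised by
#' digesting with its pair. Enzymes whose recognition sequence occurs inside
#' any insert of the vector are skipped; assignment follows catalog order and
#' is deterministic.
#'
#' @param units list of `ivtt_unit` objects forming one vector.
#' @param enzyme_catalog named character vector (enzyme -> recognition
#'   sequence).
#' @return the units with `site_5p`/`site_3p` filled in.
#' @export
assign_sites <- function(units, enzyme_catalog = default_enzyme_catalog()) {
  if (!length(units)) return(units)
  inserts <- vapply(units, `[[`, "", "nt_insert")
  usable <- enzyme_catalog[!vapply(enzyme_catalog, function(site) {
    any(grepl(site, inserts, fixed = TRUE))
  }, TRUE)]
  need <- length(units) + 1L
  if (length(usable) < need) {
    stop("enzyme catalog exhausted: ", length(units), " unit(s) need ",
         need, " collision-free enzymes, only ", length(usable),
         " available; supply at least ", need - length(usable), " more",
         call. = FALSE)
  }
  for (i in seq_along(units)) {
    units[[i]] <- set_unit_sites(units[[i]], usable[c(i, i + 1L)])
  }
  units
}

#' Design a complete tandem-IVTT screen
#'
#' Builds one expression unit per peptide, packs them into vectors of at
#' most `capacity` units, and assigns collision-free flanking restriction
#' sites within each vector. The full insert of a vector is the alternation
#' site/unit/site/.../site.
#'
#' @param peptides character vector of candidate peptides, in screen order.
#' @param capacity units per vector (default 10).
#' @param codon_table,enzyme_catalog,elements configuration; see the
#'   corresponding `default_*()` functions.
#' @param randomize randomized codon choice (uses the current RNG state).
#' @return an `ivtt_design`: list with `vectors` (named list; each has
#'   `name`, `units`, `insert`) and `manifest` (data.frame: `vector`,
#'   `unit_index`, `peptide`, `site_5p`, `site_3p`).
#' @export
design_ivtt <- function(peptides, capacity = 10L,
                        codon_table = default_codon_table(),
                        enzyme_catalog = default_enzyme_catalog(),
                        elements = default_ivtt_elements(),
                        randomize = FALSE) {
  units <- lapply(seq_along(peptides), function(i) {
    build_unit(peptides[[i]], i, elements = elements,
               codon_table = codon_table, randomize = randomize)
  })
  packed <- pack_vectors(units, capacity)
  vectors <- lapply(names(packed), function(nm) {
    vunits <- assign_sites(packed[[nm]], enzyme_catalog)
    sites <- c(vapply(vunits, function(u) u$site_5p[[1L]], ""),
               vunits[[length(vunits)]]$site_3p[[1L]])
    inserts <- vapply(vunits, `[[`, "", "nt_insert")
    insert <- paste0(paste0(sites[seq_along(vunits)], inserts,
                            collapse = ""),
                     sites[length(sites)])
    list(name = nm, units = vunits, insert = insert)
  })
  names(vectors) <- names(packed)
  manifest <- do.call(rbind, lapply(vectors, function(v) {
    data.frame(vector = v$name,
               unit_index = vapply(v$units, `[[`, 1L, "index"),
               peptide = vapply(v$units, `[[`, "", "peptide"),
               site_5p = vapply(v$units, function(u) names(u$site_5p), ""),
               site_3p = vapply(v$units, function(u) names(u$site_3p), ""),
               stringsAsFactors = FALSE)
  }))
  if (is.null(manifest)) {
    manifest <- data.frame(vector = character(0), unit_index = integer(0),
                           peptide = character(0), site_5p = character(0),
                           site_3p = character(0))
  }
  row.names(manifest) <- NULL
  structure(list(vectors = vectors, manifest = manifest),
            class = "ivtt_design")
}

#' @export
print.ivtt_design <- function(x, ...) {
  cat("ivtt_design: ", nrow(x$manifest), " unit(s) in ",
      length(x$vectors), " vector(s)\n", sep = "")
  invisible(x)
}

#' Write an IVTT design to disk
#'
#' Emits per-vector insert FASTA files and the TSV manifest.
#'
#' @param design an `ivtt_design`.
#' @param out_prefix path prefix.
#' @return invisible character vector of files written.
#' @export
write_ivtt_design <- function(design, out_prefix) {
  written <- character(0)
  if (length(design$vectors)) {
    fasta <- paste0(out_prefix, "_vectors.fasta")
    seqs <- Biostrings::DNAStringSet(
      vapply(design$vectors, `[[`, "", "insert"))
    names(seqs) <- names(design$vectors)
    Biostrings::writeXStringSet(seqs, fasta, width = 70L)
    written <- c(written, fasta)
  }
  manifest <- paste0(out_prefix, "_manifest.tsv")
  utils::write.table(design$manifest, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(written, manifest))
}
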