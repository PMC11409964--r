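## Construction of the paired wild-type / mutant proteomes. Only mutated
## proteins enter the pair: the wild-type side is exactly the subset of the
## reference carrying at least one mutation, and the mutant side carries all
## of a protein's substitutions applied simultaneously to one sequence.

#' Build the paired wild-type/mutant proteomes for a mutation set
#'
#' Every mutation must name a protein present in the reference, lie within
#' its length, and agree with the reference residue at its position. All
#' substitutions on the same protein are applied to a single mutant sequence;
#' applying them one-per-record would leave wild-type peptides spanning one
#' site still discoverable in the record built for another site, breaking the
#' found-in-wt-but-not-in-mt criterion. Unmutated proteins are excluded from
#' both sides.
#'
#' @param reference proteome data.frame ([read_proteome()]).
#' @param mutations mutation data.frame ([read_mutations()]).
#' @return a `proteome_pair`: list with `wt` and `mt` (named character vectors
#'   over the same protein ids, equal lengths per protein) and `sites` (the
#'   validated per-protein mutation table, ordered by protein then position).
#' @export
#' @examples
#' ref <- data.frame(protein_id = "P1", gene_id = "G1",
#'                   sequence = "AAKLNPQQFEVAA")
#' mut <- data.frame(protein_id = "P1", position = 8L, ref_aa = "Q",
#'                   alt_aa = "R", gene_id = "G1", label = "G1 p.Q8R")
#' pair <- build_proteome_pair(ref, mut)
#' pair$mt[["P1"]]  # "AAKLNPQRFEVAA"
build_proteome_pair <- function(reference, mutations) {
  mutations <- validate_mutations(mutations)
  unknown <- setdiff(mutations$protein_id, reference$protein_id)
  if (length(unknown)) {
    stop("mutation names protein absent from the reference: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  key <- paste(mutations$protein_id, mutations$position)
  if (anyDuplicated(key)) {
    stop("conflicting substitutions at the same protein position: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  mutations <- mutations[order(mutations$protein_id, mutations$position), ,
                         drop = FALSE]
  row.names(mutations) <- NULL

  ids <- unique(mutations$protein_id)
  refseq <- stats::setNames(reference$sequence, reference$protein_id)
  wt <- refseq[ids]
  mt <- wt
  for (i in seq_len(nrow(mutations))) {
    pid <- mutations$protein_id[i]
    pos <- mutations$position[i]
    seq_len_i <- nchar(wt[[pid]])
    if (pos > seq_len_i) {
      stop("position ", pos, " out of range for protein '", pid,
           "' (length ", seq_len_i, ")", call. = FALSE)
    }
    observed <- substr(wt[[pid]], pos, pos)
    if (observed != mutations$ref_aa[i]) {
      stop("reference residue mismatch for '", pid, "' position ", pos,
           ": expected ", mutations$ref_aa[i], ", observed ", observed,
           call. = FALSE)
    }
    substr(mt[[pid]], pos, pos) <- mutations$alt_aa[i]
  }
  structure(list(wt = wt, mt = mt, sites = mutations),
            class = "proteome_pair")
}

#' @export
print.proteome_pair <- function(x, ...) {
  cat("proteome_pair: ", length(x$wt), " mutated protein(s), ",
      nrow(x$sites), " substitution site(s)\n", sep = "")
  invisible(x)
}

#' Mutation sites falling on one protein
#' @param pair a `proteome_pair`.
#' @param protein_id protein identifier.
#' @return rows of `pair$sites` for that protein, ordered by position.
#' @export
sites_for_protein <- function(pair, protein_id) {
  pair$sites[pair$sites$protein_id == protein_id, , drop = FALSE]
}

#' Write the paired proteomes as two FASTA files
#'
#' Emits the wild-type subset and the mutant sequences in the package FASTA
#' dialect, with gene ids taken from the mutation table.
#'
#' @param pair a `proteome_pair`.
#' @param path_wt,path_mt output FASTA paths.
#' @export
write_proteome_pair <- function(pair, path_wt, path_mt) {
  ids <- names(pair$wt)
  gene <- pair$sites$gene_id[match(ids, pair$sites$protein_id)]
  write_proteome(data.frame(protein_id = ids, gene_id = gene,
                            sequence = unname(pair$wt)), path_wt)
  write_proteome(data.frame(protein_id = ids, gene_id = gene,
                            sequence = unname(pair$mt)), path_mt)
  invisible(c(path_wt, path_mt))
}
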