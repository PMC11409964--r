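# nessier

Candidate tumor neoantigen selection using a **surrogate immunopeptidome**:
an HLA-eluted peptide repertoire from autologous *non-tumor* material
(normal mucosa, PBMC-derived LCL, spleen) stands in for the tumor's own
immunopeptidome, so no fresh or frozen tumor tissue is needed beyond what
mutation calling already uses. The approach is HLA-agnostic and works for
both HLA class I and class II ligands.

## The selection rule

Given a reference proteome, a table of somatic missense mutations (protein
coordinates, e.g. `p.Q294R`), a surrogate peptide list, and tumor gene
expression (TPM):

1. Build the paired proteomes: the **wild-type subset** W (only proteins
   carrying ≥ 1 mutation) and the **mutant proteome** M (the same proteins
   with all substitutions applied simultaneously per protein).
2. Keep surrogate peptides of class-appropriate length (8–12 for HLA-I,
   10–25 for HLA-II). A peptide *p* is a **wild-type counterpart** iff

   *p* ⊑ W  and  *p* ⋢ M

   (exact substring membership, proteome-wide). For pure substitutions,
   every qualifying occurrence necessarily covers ≥ 1 mutated residue.
3. Substitute: the candidate neoantigen is the mutant-protein substring at
   the same coordinates; it differs from *p* at exactly the covered sites.
4. Collapse length variants: peptides with the same covered-site set on the
   same protein count as **one** candidate (representative = longest
   member).
5. Exclude candidates whose source-gene TPM ≤ 1.

The package also provides the companion in silico counting rule (best
%rank over all 8–12-mer mutant windows × alleles from an external
predictor's score table; candidate iff %rank < 2.0 and TPM > 1, strong
binder at < 0.5), descriptive immunopeptidome statistics (cross-sample
sharing, pairwise overlap, length distributions, source-gene TPM density),
a tandem-IVTT screening-construct designer (≤ 10 units per vector, unique
flanking restriction sites), and a ground-truthed synthetic-data generator.

## Worked example

A toy five-protein proteome embeds four published wild-type ligands.
Three proteins carry the substitution *inside* the embedded peptide; one
(`P1`) carries it *outside*, so its peptide survives unchanged in the
mutant proteome and must be rejected; a fifth mutation is covered by no
surrogate peptide. Four decoy peptides come from unmutated regions.

```r
library(nessier)

reference <- data.frame(
  protein_id = c("P1","P2","P3","P4","P5"), gene_id = paste0("G", 1:5),
  sequence = c("MAAAGGGRYLTVAAVFWWCCHHKK", "MSSTTPPKLNPQQFEVDDEEFFHH",
               "MKKRRKLWDIINVNISSTTYYA", "MPPLLKGEIAASIATHMRPYNNQQW",
               "MHHWWCCDDEEKKLLNNPPQQRRSSTTVVYY"))
mutations <- data.frame(
  protein_id = c("P1","P2","P3","P4","P5"), position = c(3L,13L,11L,14L,5L),
  ref_aa = c("A","Q","I","A","W"), alt_aa = c("G","R","V","V","F"),
  gene_id = paste0("G", 1:5),
  label = c("G1 p.A3G","G2 p.Q13R","G3 p.I11V","G4 p.A14V","G5 p.W5F"))
surrogate <- peptidome(c("RYLTVAAVF","KLNPQQFEV","KLWDIINVNI",
  "KGEIAASIATHMRPY","WWCCHHKK","DDEEFFHH","NVNISSTT","THMRPYNN"), "I")
expr <- data.frame(gene_id = paste0("G", 1:5), tpm = 10)

res <- run_nessie(surrogate, reference, mutations, expr,
                  length_bounds = c(8L, 25L))  # mixed-class fixture
res$pass[, c("representative_wt","representative_mut","substitutions",
             "gene_id","tpm","filter_flags")]
#>   representative_wt representative_mut substitutions gene_id tpm filter_flags
#> 1         KLNPQQFEV          KLNPQRFEV          Q13R      G2  10         PASS
#> 2        KLWDIINVNI         KLWDIVNVNI          I11V      G3  10         PASS
#> 3   KGEIAASIATHMRPY    KGEIAASIVTHMRPY          A14V      G4  10         PASS
```

Of the eight input peptides, exactly three become candidates: each is a
surrogate peptide found only in the wild-type proteome, reported with its
single-residue mutant form (`KLNPQQFEV → KLNPQRFEV`, and so on).
`RYLTVAAVF` is correctly rejected — its protein's mutation lies outside the
peptide, so the identical sequence exists in the mutant proteome — as are
all four decoys. The run report counts every stage:

```r
str(res$report$counts)
#> List of 11
#>  $ peptides_in                 : int 8
#>  $ peptides_length_filtered_out: int 0
#>  $ peptides_after_length_filter: int 8
#>  $ mutations                   : int 5
#>  $ mutated_proteins            : int 5
#>  $ counterpart_peptides        : int 3
#>  $ counterpart_occurrences     : int 3
#>  $ candidate_groups            : int 3
#>  $ expression_excluded         : int 0
#>  $ no_expression_data          : int 0
#>  $ pass                        : int 3
```

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/cli/nessier.R`) with subcommands `build-proteomes`, `run`,
`insilico`, `stats`, `ivtt` and `simulate`.

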