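---
title: "Neoantigen selection with a surrogate immunopeptidome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neoantigen selection with a surrogate immunopeptidome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nessier)
```

## The problem and the approach

Somatic missense mutations in a tumor can create neoantigens: HLA-presented
peptides carrying a tumor-specific amino-acid substitution. Identifying which
of a patient's hundreds to thousands of missense mutations actually yield
presented, immunogenic peptides is the central practical obstacle to
personalized neoantigen vaccines. Binding-affinity predictors nominate
hundreds of candidates per patient, most of them false positives; direct mass
spectrometry of the tumor immunopeptidome is specific but needs fresh or
fresh-frozen tumor material that is often unavailable.

This package implements a third route. HLA-eluted peptidomes are strongly
shared across samples with matched HLA, and a tumor that presents a mutant
peptide very often presents — or a matched normal tissue presents — its
unmutated *wild-type counterpart*. So instead of the tumor's own peptidome,
the search uses a **surrogate immunopeptidome**: HLA-eluted peptides from
autologous non-tumor material (normal mucosa, PBMC-derived LCL, spleen),
which requires no tumor tissue beyond what is needed for mutation calling.

The selection rule is purely sequence-based and HLA-agnostic:

1. From the reference proteome and the missense-mutation table, build the
   **wild-type subset** (only proteins carrying at least one mutation) and
   the **mutant proteome** (the same proteins with all their substitutions
   applied).
2. A surrogate peptide is a **wild-type counterpart** iff its complete
   sequence occurs somewhere in the wild-type subset and nowhere in the
   mutant proteome. A pure substitution guarantees every qualifying
   occurrence covers at least one mutated residue (asserted at run time).
3. Each counterpart is converted to its **candidate neoantigen** by reading
   the same coordinates from the mutant protein.
4. Overlapping peptides that carry the same substitution(s) but differ in
   N-/C-terminal flanking residues are **collapsed into one candidate**.
5. Candidates whose source gene is not expressed in the tumor
   (TPM ≤ 1 by RNA-seq) are excluded.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| class length bounds | 8–12 (HLA-I), 10–25 (HLA-II) | eluted-ligand length windows; applied to the surrogate list before matching |
| `tpm_threshold` | 1.0 TPM | expression filter; the boundary itself is *excluded* (TPM must exceed the threshold) |
| `il_equivalent` | off | treat I and L as one letter during matching (they are isobaric under MS); reporting stays literal |
| `strict_expression` | off | genes absent from the TPM table are retained with a `NO_EXPRESSION_DATA` flag by default; strict mode drops them |

Filtering lengths before rather than after matching is an order-free choice:
membership of a literal sequence does not depend on the other peptides, so
the outcome is identical either way and filtering first costs less.

## Design choices where the procedure was genuinely open

- **Proteome-wide, literal membership.** A peptide occurring in an
  *unchanged* region of any mutant protein is "found in the mutant
  proteome" and therefore rejected, even if another of its occurrences
  covers a mutation elsewhere. This is the conservative reading of the
  found-in-wt-but-not-in-mt criterion and is what the brute-force oracle in
  the test suite also implements.
- **Co-occurring mutations on one protein are applied simultaneously** to a
  single mutant sequence. With one mutant record per mutation, a wild-type
  peptide spanning mutation A would still be present in the record built
  for mutation B and the exclusion rule would silently break. Phasing of
  somatic mutations is unknowable at this level; two substitutions at the
  same residue are rejected as contradictory input.
- **Collapsing key = exact covered-site set.** A peptide spanning two
  adjacent substitutions and a peptide covering only one of them represent
  different mutant sequences, so they form different candidates. The
  representative of a group is its longest member, lexicographic
  tie-break — a deterministic choice with no biological weight.
- **In silico comparison uses the minimum %rank.** The companion counting
  rule scores all 8–12-mer windows of the mutant protein containing the
  substituted residue, over the patient's alleles, and assigns the mutation
  its best predicted binder. Because %rank is smaller-is-stronger and the
  candidate rule is "%rank < 2.0 (weak) / < 0.5 (strong), TPM > 1", the
  best binder is the *minimum* %rank; taking a literal maximum would make
  the thresholds nearly unsatisfiable. The predictor itself is always
  external: this package emits the windows as FASTA and consumes a
  (peptide, allele, %rank) table.
- **Missing expression data is flagged, not dropped.** A gene-id join
  failure should be visible in the report rather than silently removing a
  candidate; strict mode restores the hard filter.

## The IVTT screening designer

Candidates surviving selection can be screened by tandem in vitro
transcription/translation. Each peptide becomes a self-contained unit —
T7 promoter, ribosome-binding site, `ATG` + FLAG (`DYKDDDDK`) codons,
peptide codons, stop codon, 3'UTR stem-loop — so a vector carrying up to 10
units translates as a pool, and any single unit can be excised with its
unique flanking restriction-enzyme pair (adjacent units share one site, so
*n* units need *n* + 1 collision-free enzymes) and translated alone. The
FLAG ends in `DDDDK`, so enterokinase cleavage releases the peptide with no
extra N-terminal residues; that chemistry is a documented rationale, not
something the package simulates. Codon choice is deterministic
most-frequent-codon from a bundled E. coli usage table (the reconstituted
IVTT kit is an E. coli system), with an optional seeded randomized mode;
element sequences are canonical published defaults and fully configurable,
since only the construct anatomy, not its exact bases, is fixed by the
design. Restriction handling is recognition-site scanning only — cut-offset
chemistry and vector backbones are out of scope.

## The synthetic-data generator

`simulate_dataset()` emulates the *structure* of the real inputs: a random
uniform-composition proteome (30 proteins of 150–400 residues by default),
6 mutated proteins with 1–2 substitutions each, 8 implanted counterpart
peptides of class-appropriate length with 2 extra length variants per site
(to exercise collapsing), 10 decoys from unmutated regions (present in both
proteomes; must be rejected), 10 decoys drawn from mutant sequences across
a site (present in the mutant proteome; must be rejected), and gene-level
TPM drawn log-normal(meanlog 1, sdlog 2) with a quarter of mutated genes
forced to TPM ≤ 1. These sizes keep accidental sequence collisions
negligible (a specific 8-mer arises by chance in a 10⁴-residue proteome
with probability ≈ 10⁻⁶) while still covering every qualifying and every
failure path; the generator *verifies* each decoy's intended failure mode by
running the membership tests itself and redraws on accidental qualification.

What the simulator does **not** emulate — and therefore what passing tests
do not show about real data: MS identification error and FDR behavior,
biased amino-acid composition and HLA binding motifs, expression-correlated
peptide sampling, and transcript-level quantification. Perfect recovery on
simulation demonstrates the correctness of the selection logic, not the
sensitivity of the laboratory pipeline around it.

`simulate_rank_table()` plants a designed best %rank per mutation
(strong / weak / non-binder) for testing the in silico counting rule.
Mutations whose enumeration windows overlap another mutation's (sites closer
than the longest window on one protein) are marked `entangled` and left
unplanted, because a shared window cannot be scored independently for both.

## Numerical and degenerate-input choices

- All residue coordinates are 1-based inclusive, matching HGVS.p-style
  annotations (`p.Q294R`).
- Matching is exact string matching over the 20 standard letters;
  overlapping occurrences are all enumerated. Non-standard letters
  (B, J, O, U, X, Z) are dropped from peptide lists with a warning (MS
  exports routinely contain them); strict mode errors instead.
- Empty outputs are legal everywhere: an empty peptidome, a mutation set
  covered by no peptide, or a fully filtered candidate list all produce
  empty tables and zero counts, with exit status 0 at the CLI.
- Candidate and report ordering is fully deterministic (protein id, first
  covered position, representative sequence); there is no randomness
  anywhere in the core pipeline.
- The TPM boundary uses `>` (a candidate at exactly the threshold is
  excluded), and thresholds are compared with strict `<` on %rank.

## Problem sizes used in validation

The test suite validates the pipeline against a brute-force membership
oracle on 100+ random instances of up to 10 proteins × 200 residues,
6 mutations and 50 peptides, and against simulator ground truth across 50+
seeds at the default sizes above; the acceptance script recomputes the same
quantities from scratch. These sizes were chosen as the smallest at which
every code path (overlap, clipping, collapsing, both decoy classes, the
expression boundary) is exercised on every run.

## Known limitations

- Only single-residue substitutions are modeled. Frameshift, stop-loss,
  splice and fusion products have no wild-type counterpart and are
  undetectable by construction; the same holds for mutations whose
  wild-type peptide is simply never presented by any surveyed tissue.
- Candidates are per-protein; a peptide shared verbatim between two
  mutated proteins would be excluded by the proteome-wide membership rule
  rather than attributed to either.
- The in silico module reproduces a counting rule over an externally
  supplied score table; it neither reimplements nor approximates the
  predictor.
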