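Package: nessier
Title: Neoantigen Selection Using a Surrogate Immunopeptidome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate tumor neoantigens by searching a surrogate
    (non-tumor) HLA-eluted immunopeptidome for wild-type counterpart peptides
    of somatic missense mutations. Builds paired wild-type/mutant proteomes
    from a reference proteome and a mutation table, finds surrogate peptides
    whose sequences occur in the wild-type but not the mutant proteome,
    substitutes the mutant residues, collapses N-/C-terminal length variants
    into single candidates, and applies a tumor gene-expression (TPM) filter.
    Also provides the companion in silico percentile-rank candidate-counting
    rule over externally supplied binding predictions, descriptive
    immunopeptidome statistics (cross-sample sharing, pairwise overlap,
    length distributions, source-gene expression profiles), a tandem in vitro
    transcription/translation (IVTT) screening-construct designer, and a
    ground-truthed synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
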