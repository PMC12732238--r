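Package: pepscreen
Title: HLA Class I Immunopeptidome Screening for Cross-Reactive TCR Ligands
Version: 0.1.0
Authors@R:
    person("pepscreen", "developers", email = "pepscreen@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing HLA class I immunopeptidome tables and
    nominating candidate ligands of an autoreactive T-cell receptor (TCR).
    Provides q-value (FDR) filtering of peptide identification tables,
    NetMHCpan-style percent-rank binder classification with best-binder
    allele assignment, construction of position-probability / log-odds
    peptide recognition motifs from stimulatory-ligand panels and
    motif-based screening of peptidomes, upset-style set analytics across
    peptidomes, ERAP1 haplotype calling from nine coding SNPs via an
    editable residue-combination key, normalization of TCR-hybridoma
    activation readouts against negative and positive controls, and a
    fully deterministic synthetic immunopeptidome generator used to
    validate every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
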