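Package: neuropep
Title: Neuropeptide Precursor Discovery from Predicted Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico pipeline for discovering neuropeptide precursor
    (preprohormone) genes in predicted proteomes. Restricts proteins to a
    putative secretome (signal peptide, no transmembrane segments, no known
    functional domains), scans the remainder for prohormone-convertase
    dibasic cleavage sites (KK, RK, KR, RR and glycine-extended GK, GR),
    extracts candidate mature peptides with C-terminal amidation,
    N-terminal pyroglutamate and proline-protection annotation, assigns
    peptides to sequence families (RFamide, GLWamide, PRXamide and others),
    filters candidates by homology evidence and by neuronal single-cell
    expression, and classifies survivors by all-versus-all local-alignment
    similarity clustering with a seeded force-directed layout. Includes a
    synthetic-proteome generator with ground-truth manifests so every stage
    is testable end to end without external data or binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
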