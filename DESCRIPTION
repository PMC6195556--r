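Package: venomics
Title: Venom-Gland Transcriptome and Venom Proteome Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale, fully tested implementation of a multi-individual
    venom-gland transcriptome and venom proteome characterization pipeline for
    snakes: k-mer based cross-sample contamination filtering, quality trimming
    and read-pair merging, greedy seed-extension de novo assembly, reference
    based toxin/nontoxin annotation, cd-hit-style identity clustering into a
    species consensus transcriptome, coverage-based chimera screening and
    presence/absence calling, EM-based TPM quantification with compositional
    (clr) transforms, dual-flavor negative-binomial consensus differential
    expression across life-history and lineage contrasts, Blomberg's K
    phylogenetic-signal testing, and internal-standard label-free proteomic
    quantification. Ships a synthetic-data generator that emulates the
    statistical structure of the real study inputs so the whole pipeline is
    exercisable end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stringi,
    stats,
    utils,
    MASS,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    picante,
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
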