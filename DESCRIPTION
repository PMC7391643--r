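Package: cyclomine
Title: Mining and Annotation of Cyclotide Precursors from Plant Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and annotating cyclotide precursor genes in
    plant transcriptome assemblies, modelled on the albumin-1 gene architecture
    of Fabaceae cyclotides ("cliotides"). Provides six-frame ORF extraction,
    PROSITE-style motif scanning, Smith-Waterman/Needleman-Wunsch homology
    search, parsing of albumin-1-type precursor architecture (ER signal with
    TEA cleavage motif, six-cysteine mature domain, linker, albumin-1a chain,
    C-terminal propeptide), loop decomposition and Moebius/Bracelet/Hybrid
    topology classification, monoisotopic mass calculation for cyclic
    disulfide-rich peptides with MALDI peak matching, rule-based annotation of
    biosynthetic enzymes (asparaginyl endopeptidases, protein disulfide
    isomerases, ER oxidoreductin-1, cyclophilins), Pearson-correlation
    complete-linkage expression clustering, cysteine-anchored alignment with
    neighbor-joining phylogenies, and a seeded synthetic-data generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'seq_io.R'
    'prosite.R'
    'align.R'
    'mass_calc.R'
    'precursor_annot.R'
    'cyclo_mine.R'
    'enzyme_annot.R'
    'expression_cluster.R'
    'phylo.R'
    'synthetic_data.R'
    'pipeline.R'
    'cyclomine-package.R'
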