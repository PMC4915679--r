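Package: orpscan
Title: Discovery and Characterization of Opsin-Related Proteins in Microbial Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening pipeline for type-1 (microbial) opsin homologs that lack
    the Schiff-base lysine required for covalent retinal binding, termed
    opsin-related proteins (ORPs). Proteomes are searched against a packaged
    opsin reference panel with a decoy-calibrated profile gate, hits are anchored
    to sensory-rhodopsin-II residue numbering to extract a fingerprint of
    retinal-binding-pocket and signal-transduction residues, and classified into
    opsin families and ORP groups A (Schiff-base arginine) and B (hydrophobic
    residue). Gene-neighborhood context (chemotaxis signal transducers, taxis
    operons, stress genes), retinal-biosynthesis gene complements (crtY, brp,
    crtE, crtB, crtI), distance-based phylogenetics with monophyly tests, and
    apo/holo calling from absorbance spectra complete the screen. A
    seed-deterministic synthetic-data generator with planted ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
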