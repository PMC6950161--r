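Package: peptidomer
Title: Venom Peptidome Characterization with Disulfide-Linked Dimer
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrated transcriptomic and proteomic
    characterization of venom peptidomes. Computes exact monoisotopic and
    average peptide masses with post-translational modifications
    (C-terminal amidation, methionine oxidation, pyroglutamate,
    carbamidomethylation), enumerates monomer, homodimer and heterodimer
    hypotheses for cysteine-bearing chains and verifies them against
    native, reduced and alkylated LC-MS mass lists via disulfide mass
    shifts, mines peptide precursors from transcriptome contigs by
    six-frame translation, de novo sequence-tag matching and
    signal/prepro/mature segmentation, quantifies transcripts as
    reads-per-million and peptides as relative peak-area abundance, and
    annotates peptides with hydrophobicity, net charge and isoelectric
    point. Includes a ground-truthed synthetic data generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
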