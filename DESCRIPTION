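Package: guidecraft
Title: CRISPR/Cas9 Guide Selection and Construction-Oligo Design for Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects CRISPR/Cas9 guide-RNA target sites in yeast genomes and
    designs all construction oligonucleotides around them. Candidate 20 bp +
    NGG protospacers are enumerated within an ORF on both strands, discarded
    when they contain a poly-T Pol III terminator or any genome-wide
    off-target (17/20 identity with an NGG or NAG PAM), then scored by AT
    content, predicted RNA secondary structure pairing and restriction-site
    presence, normalized per locus and ranked. For the selected target the
    package emits single-gRNA plasmid insert oligos, double-gRNA tailed
    primers, 120 bp deletion and point-mutagenesis repair fragments and
    multigene-integration homology tails, and simulates plasmid assembly
    outcomes and restriction-digest verification. A deterministic synthetic
    genome generator with planted targets and off-target decoys supports
    download-free testing, and a command-line pipeline runs the whole design
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    methods,
    optparse,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
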