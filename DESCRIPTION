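Package: crypticsplice
Title: Cryptic Cassette Exon Discovery and Splice-Junction PSI Quantification
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects unannotated (cryptic) cassette exons inside annotated
    introns from splice-junction evidence, quantifies splice-site usage by
    percent spliced in (PSI), annotates the resulting transcripts for
    premature termination codons and nonsense-mediated decay (NMD)
    susceptibility including truncated-protein mass, scores UG-dinucleotide
    richness of the flanking intron and overlap with CLIP peak intervals,
    and classifies neurofascin-style isoforms from junction evidence.
    Includes a seeded synthetic-locus generator emulating a TDP-43-repressed
    cryptic exon so the whole pipeline is testable without downloads, plus
    delta-delta-Cq relative quantification for companion RT-qPCR data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
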