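Package: glutencaller
Title: Typing Wheat High-Molecular-Weight Glutenin Subunits from
    Intact-Protein MALDI-TOF Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies the high-molecular-weight glutenin subunit (HMW-GS)
    composition of bread wheat at the Glu-A1, Glu-B1 and Glu-D1 loci from
    intact-protein MALDI-TOF mass spectra. Provides an embedded reference
    library of subunit alleles with measured and gene-predicted masses,
    4-vinylpyridine alkylation adduct correction, peak detection and
    external one-point calibration for profile spectra, a mass-window
    genotype caller with locus-haplotype constraints, linked-pair
    disambiguation and 1Bx7 group resolution, cohort-level summaries, and
    a synthetic-spectrum simulator for end-to-end validation without
    instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
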