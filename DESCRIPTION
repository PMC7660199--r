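Package: chainfish
Title: Simulation and Decoding of Chained-Probe Sequential FISH Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for combinatorial color-sequence barcoding of nucleic
    acids by consecutive fluorescence in situ hybridization with chained,
    self-amplifying decoding probes. Provides codebook construction and
    validation (capacity M^N), assembly of 45-nt pre-decoding and 70-nt
    two-landing-site decoding probes with orthogonal-sequence accounting, a
    seeded multi-cycle fluorescence image simulator with ground truth
    (geometric signal amplification, photobleach residuals, inter-cycle
    drift, crowding saturation, non-specific binding), and a full decoder:
    spot detection with sub-pixel localization, phase-correlation drift
    registration, colocalization linking across cycles, threshold-free
    channel calling, codebook lookup, per-cell copy numbers and QC metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    Biostrings,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
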