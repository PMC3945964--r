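Package: barcodeval
Title: Assessment of DNA Barcoding Markers for Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the performance of candidate DNA barcoding
    markers (e.g. COI, 16S rDNA, ITS2, 12S rDNA) for species
    identification against a curated reference library.  Computes
    Kimura two-parameter genetic distances with pairwise deletion, six
    intra-/inter-specific divergence parameters (average distances,
    theta, theta prime, minimum inter-specific distance, coalescent
    depth), barcoding-gap frequency distributions, and optimal
    species-boundary thresholds from cumulative false-positive and
    false-negative error curves.  Identifies query sequences by four
    decision rules (nearest neighbour, best local-alignment hit with
    bit-score and E-value statistics, liberal tree-based, and liberal
    tree-based with a distance threshold), screens unverified reference
    sequences by tree clustering, scores per-marker identification
    success rates, and compares markers and methods with Duncan's
    multiple range test.  A sequence simulator with controlled
    divergence structure supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
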