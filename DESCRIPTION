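Package: lipidsn
Title: Class-Resolved Annotation of Direct-Infusion Lipid Spectra with
    sn-Positional Assignment and Acyl-Editing Route Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for shotgun (direct-infusion) ESI-MS glycerolipid
    profiling of the kind used for diatom polar lipids. Computes elemental
    formulas, monoisotopic masses, adduct ion m/z and diagnostic fragment
    masses for glycerophospholipid and galactolipid classes; enumerates
    candidate species from an acyl-chain pool and matches observed peaks
    under scan-mode class gating (precursor-ion 184, neutral-loss 162,
    negative Q1); assigns sn-1/sn-2 positions from product-ion carboxylate
    intensities; classifies species as prokaryotic or eukaryotic assembly
    by the sn-2 acyl chain; and searches a PLA/LPCAT/PDCT/PDAT/DGAT/ELO/DES
    reaction network for shortest acyl-editing routes that incorporate
    eicosapentaenoic acid (EPA) into triacylglycerol. A seeded synthetic
    spectrum generator with known ground truth makes the whole pipeline
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
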