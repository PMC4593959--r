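Package: oiecare
Title: Resolution of Overlapping Isotopic Envelopes in Protein Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A top-down proteomics fragment-matching engine built around the
    OIE_CARE method for resolving overlapping isotopic envelopes (OIEs) in
    high-resolution tandem mass spectra of intact proteins. Theoretical
    isotopic envelopes are computed exactly from elemental compositions by
    isotope-distribution convolution (no Averagine approximation), b/y/a
    product ions with neutral losses are generated for proteoforms expanded
    from PTM annotations, and experimental centroid peaks are matched by
    isotopic m/z and envelope fingerprinting under IPACO/IPMD/IPAD
    tolerances. When several product ions claim the same experimental peak,
    the shared abundance is partitioned among them in closed form from the
    relative deviation between observed and ideal abundances. Protein
    spectrum matches are scored by sequence and peptide-bond coverage,
    matching-ion percentages and PTM localization counts, and filtered by
    decoy-based false discovery rate. A synthetic-spectrum generator with
    ground truth supports calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr,
    mzR
VignetteBuilder: knitr
Config/testthat/edition: 3
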