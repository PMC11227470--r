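Package: leafmorph
Title: Leaf Outline Morphometrics and Axial-Asymmetry Analysis
Version: 1.0.0
Authors@R:
    person("Jan", "Kowalczyk", email = "jan.kowalczyk@example.org",
           role = c("aut", "cre"))
Description: Outline-based morphometrics of scanned leaves for mechanical
    stress (thigmomorphogenesis) phenotyping. Extracts binary leaf masks
    from single-leaf scans (BT.601 luminance, Otsu thresholding,
    morphological cleaning), computes Kuhl-Giardina elliptic Fourier
    descriptors with frequency-domain normalisation, and derives pairwise
    shape distances, fluctuating-asymmetry errors, population ratio
    statistics and a normality-screened two-sample test battery. Includes a
    synthetic leaf-scan generator emulating a paired two-treatment study
    design so every stage is testable without deposited scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
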