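Package: pvdms
Title: Pyoverdine Variant Annotation and A-Domain Specificity Profiling from Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying sequence variants of pyoverdine, the
    chromophore-bearing, C-terminally macrocyclized non-ribosomal peptide
    siderophore of fluorescent Pseudomonas, from MALDI and ESI mass spectra.
    Provides a monoisotopic building-block registry and elemental-formula
    arithmetic, precursor and b/y fragment-ion prediction that treats the
    C-terminal macrolactam as an uncleavable unit, retro-Diels-Alder companion
    peak handling, peak-list matching with substitution inference and MS/MS
    localization, isotopic-envelope titration quantification with
    response-factor calibration, Beer-Lambert photometric quantification, and
    differential-conservation profiling of adenylation-domain specificity
    codes with thresholded key-residue calling. Includes seeded synthetic-data
    generators for labeled sequence sets and peak lists so the whole pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    stats,
    utils,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
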