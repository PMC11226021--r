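Package: mzexacto
Title: Consolidation of Tentative GC-MS Identifications into
    Compound-by-Sample Area Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for deconvoluted, library-searched
    GC-MS exports. Expands flat tentative-identification tables into
    field-wise matrices, resolves compound names to exact masses, fragment
    spectra and structures through an offline local store, consolidates
    component areas across samples inside mass-ordered retention-time
    windows with a top-2 m/z rescue pass, profiles compounds by functional
    groups and maximum-common-substructure Tanimoto similarity against
    user-defined chemical categories, and quantifies against internal or
    external standards. Ships a deterministic synthetic-experiment
    generator with planted ground truth so the whole workflow is testable
    without instrument data or network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
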