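Package: lipidtag
Title: Triacylglycerol MS/MS Annotation, MRM Planning and
    Internal-Standard Lipid Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for targeted glycerolipid mass spectrometry of oilseed
    lipidomes: elemental formula arithmetic and monoisotopic adduct m/z
    with electron-mass correction, a parser for lipid-class C:DB shorthand
    with combinatorial enumeration of acyl compositions, class-resolved
    MRM/precursor-ion/neutral-loss acquisition planning, annotation of
    sodiated triacylglycerol MS/MS spectra with intensity-based sn-2
    regioisomer assignment, internal-standard normalisation to
    mole-fraction distributions across seed maturation stages, and a
    synthetic-data generator emulating the statistical structure of
    instrument output so the full pipeline is testable end to end.
License: MIT + file LICENSE
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
    withr,
    optparse
Config/testthat/edition: 3
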