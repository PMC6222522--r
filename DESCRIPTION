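Package: pcdkit
Title: Combinatorial Compound Databases and Kendrick Mass Defect Analysis
    for Proanthocyanidin LC-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating proanthocyanidin (condensed tannin)
    oligomers in negative-mode LC-MS data. Generates a combinatorial
    theoretical database of flavan-3-ol polymers from the four grape-derived
    subunits, matches deisotoped feature tables against it within a ppm
    tolerance with deprotonation/formate adduct and charge-state arithmetic,
    visualises identifications with a modified Kendrick mass defect analysis
    (repeat unit C15H12O6), and predicts and annotates diagnostic MS/MS
    fragments from heterocyclic ring fission, quinone methide cleavage and
    retro-Diels-Alder pathways. Includes a synthetic feature/spectrum
    generator for validating every stage without instrument data.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
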