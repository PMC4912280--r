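Package: neckct
Title: Volumetric Neck Anthropometry from Computed Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies neck adipose tissue volume (NATV), airway volume
    (AWV), their prognostic ratio, and neck cross-sectional areas (NCSA)
    from CT volumes by Hounsfield-unit windowing and seeded connected
    component airway extraction within anatomic landmark margins.  Includes
    a synthetic neck-phantom generator with analytically known ground
    truth, interobserver agreement statistics (ICC for absolute agreement,
    Bland-Altman limits), cohort correlation and group comparisons, and
    Kaplan-Meier / Cox survival stratification by the NATV:AWV ratio.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
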