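Package: fwtract
Title: Free-Water-Corrected Deterministic Tractography for Single-Shell DTI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Bi-compartment free-water elimination for clinically feasible
    single-shell diffusion tensor imaging, deterministic streamline
    tractography over uncorrected and tissue-compartment tensor fields,
    free-water-parameterized tractograms with an adaptive correction
    threshold ("slider"), digital DWI phantoms with an edematous free-water
    gradient for validation, and the ordinal inter-rater agreement
    statistics (ordinal-weighted Gwet AC2, Stuart-Maxwell marginal
    homogeneity, Spearman correlation) used to evaluate corrected
    tractography in surgical-planning surveys.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
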