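Package: tactileEEG
Title: EEG Reactivity to Tactile Stimulation in Post-Traumatic Coma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying EEG reactivity to tactile
    stimulation in comatose patients after severe traumatic brain injury.
    Estimates power spectral density in unit-width frequency bins (2-20 Hz),
    forms stimulation-versus-rest band-power contrasts on a 19-channel 10-20
    montage, tests them at the group level (Mann-Whitney, mixed repeated
    measures ANOVA) and per subject (rank-sum tests with Bonferroni control
    across electrodes), and relates electrode-wise spectral change to brain
    morphometry covariates and coma outcome through a cluster-based
    permutation test on Spearman correlation topographies. Includes a
    synthetic-cohort generator that emulates the statistical structure of
    the study (patient versus control spectra, theta suppression coupled to
    morphometry and outcome) so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    tibble
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
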