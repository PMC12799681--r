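Package: recvar
Title: Inter-Individual and Inter-Regional Variability of PET Receptor
    Binding Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how positron emission tomography (PET) derived
    neurotransmitter receptor and transporter densities vary across
    individuals versus across brain regions. Computes coefficient of
    variation (CV) brain maps from group mean and standard deviation
    volumes or regional tables, applies low-binding and reference-region
    exclusion rules, compares inter-regional to inter-individual CV with a
    bootstrap null, scores spatial consistency of replicate group maps
    with Spearman correlations, and ships a seeded synthetic cohort
    generator so the full analysis is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
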