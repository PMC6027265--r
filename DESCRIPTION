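Package: oxyshift
Title: Kinetics, Carbon Balance and Transcriptome Analysis of Triple-Phase
    Oxygen-Shift Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for batch fermentations that pass from
    aerobiosis via microaerobiosis to anaerobiosis, as used for
    Corynebacterium glutamicum zero-growth bioprocess development.
    Segments a fermentation time series into the three oxygen phases by
    organic-acid onset and aeration stop, estimates phase-wise specific
    growth rates (semi-logarithmic regression with an R-squared
    window-maximization search), biomass and product yields, and specific
    substrate uptake rates with Gaussian error propagation; closes the
    carbon balance over substrate, biomass, organic acids and integrated
    CO2 evolution; computes TPM from gene-level counts and calls
    differential expression with an empirical m/a-value cutoff including
    phase-wise Venn partitioning, COG-class summaries and a regulator
    screen; and converts raw assay records into per-cell RNA content,
    intracellular metabolite concentrations and specific enzyme
    activities. A seeded synthetic-data generator emulates the whole
    triple-phase process with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
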