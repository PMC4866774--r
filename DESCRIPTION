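Package: mpctrace
Title: Stable-Isotope Tracing, Metabolomics Quantification and
    Differential Statistics for Mitochondrial Pyruvate Carrier Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for studying the consequences of
    mitochondrial pyruvate carrier (MPC) loss on central-carbon
    metabolism. Provides a carbon-atom-transition simulator for
    steady-state mass isotopomer distributions (MIDs) of TCA-cycle
    metabolites under 13C tracers ([U-13C]glucose, [U-13C]glutamine,
    [1-13C]glutamine) with oxidative and reductive glutamine branches;
    correction of measured isotopologue intensities for naturally
    occurring 13C; targeted LC-MS/MS quantification via internal-standard
    normalization, external calibration and protein normalization;
    accurate-mass annotation of negative-mode flow-injection QTOF peak
    lists against a compound library; differential-metabolome statistics
    (PCA, two-sample screens with Benjamini-Hochberg FDR, fold-change
    tables, phosphocreatine/creatine ratios, 2^-ddCq qPCR expression);
    extracellular-flux oxygen-consumption trace summarization; and
    seeded synthetic-data generators emulating each assay design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
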