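Package: LPFS
Title: Linear Programming Based Feature Selection for Two-Group Metabolomic
    Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Sparse biomarker discovery for two-group high-dimensional
    intensity profiles (binned 1H NMR spectra and similar omics tables).
    Implements LPFS, a linear-programming relaxation of a mixed-integer
    program that jointly minimizes the number of selected features and the
    leave-one-out nearest-centroid (L1) classification error, with the
    cross-validation folds embedded as constraints of a single optimization.
    Includes the standard preprocessing contract for binned NMR profiles
    (solvent-window exclusion, constant-sum normalization, log transform,
    Pareto scaling), filter and wrapper baselines (two-sample t statistic,
    fold change, SVM-RFE), a seeded planted-biomarker synthetic data
    generator, evaluation utilities (volcano tables, Venn overlaps,
    control-experiment filtering, recovery metrics), and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, e1071, jsonlite
Suggests: testthat (>= 3.0.0), pracma, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
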