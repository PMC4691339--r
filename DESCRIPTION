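Package: rocur
Title: Return-on-Curation Metrics and Resource Planning for Biocuration Projects
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for managing literature-curation (biocuration) projects that
    run under fixed, insufficient resources. Implements the overhead family of
    curation-efficiency metrics (the false-positive to true-positive ratio and
    its time-weighted, value-weighted and probability-adjusted refinements),
    precision/recall/F-beta conversions, and true-positive production rates;
    management of a toolbox of document-filtering strategies via Pareto
    dominance, the area covered by a strategy set, and adjustable
    precision-recall curves; value-ranked curation scheduling under a time
    budget with value floors and redundancy discounting; allocation of a global
    time budget across competing projects by minimizing the summed overheads;
    and a seeded simulator of curation projects with known ground truth for
    end-to-end validation. A command-line interface exposes every analysis on
    TSV item tables and JSON configuration files.
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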