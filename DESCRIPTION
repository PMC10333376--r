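Package: pelvimetry
Title: Landmark-Based Pelvic Floor Morphometry from Dynamic MRI Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pelvic organ prolapse from point annotations
    made on dynamic pelvic MRI. Constructs the pubococcygeal line (PCL), the
    sacrococcygeal-inferior-pubic-point (SCIPP) line, and the phase-specific
    three-dimensional pelvic inclination correction system (PICS) frame from
    five bony landmarks; computes signed organ-point coordinates at rest and
    maximum strain; grades compartment-wise prolapse against configurable
    descent thresholds; summarizes ordinal reader scores; and runs the
    method-agreement battery (Wilcoxon signed-rank, Bland-Altman limits of
    agreement, two-way random-effects intraclass correlation, Lilliefors
    normality). A synthetic-cohort generator emulates the statistical structure
    of a single-slice versus multi-slice reader study so the whole pipeline can
    be exercised and tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
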