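Package: gkscreen
Title: Two-Strain Age-Course Microarray Screening and Longitudinal
    Physiology Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the data-mining cascade used to screen Affymetrix
    probe sets for persistent differential expression between a diseased
    and a control rat strain sampled at five ages: MAS5-style
    Present/Marginal/Absent detection calls from PM/MM probe pairs via an
    exact Wilcoxon signed-rank test, per-chip 50th-percentile scaling,
    control-strain median-ratio normalization, an expression filter on
    Present-call counts, and a fold-change persistence filter requiring a
    minimum fold difference in a consistent direction at a minimum number
    of ages.  Also provides probe-set-to-gene rollup with functional
    category tallies, cross-tissue overlap counts, rank-transformed
    two-way ANOVA with Tukey post-hoc contrasts for longitudinal
    physiology variables (with detection-floor censoring), a GEO series
    matrix reader, and a synthetic-data generator that emulates the
    two-strain, five-age, five-chips-per-group design with known ground
    truth so the whole cascade is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
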