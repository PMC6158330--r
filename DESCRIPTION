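Package: fafpipe
Title: Analysis of Frequency-Altered Feedback Experiments on Vocal Pitch Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for frequency-altered feedback (FAF)
    experiments in which speakers hear their voice pitch-shifted while
    sustaining a vowel. Implements voice fundamental-frequency (F0) extraction
    and cents conversion, epoching and classification of compensatory vocal
    responses, event-related potential (ERP) processing with explicit
    moving-average artifact rejection and channel/subject exclusion rules,
    N1/P2 peak measurement, and the associated statistics: split-plot
    repeated-measures ANOVA with Greenhouse-Geisser correction and partial
    eta-squared, Bonferroni post hoc comparisons, Pearson correlations, and a
    Hardy-Weinberg equilibrium test for genotype tables. A synthetic-cohort
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
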