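Package: dorsalstream
Title: Scoring and Base-Rate Analysis for Dorsal-Stream Test Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Formula-based scoring of paediatric neuropsychological tasks
    probing dorsal-stream visual function: object recognition in suboptimal
    representations (five-subtask L94 battery with inconclusive-item
    exclusion), adaptive 2-up-1-down staircase thresholds for global motion
    and motion speed, condition-graded motion-defined form, and visual-search
    times corrected for motor response time.  Scores are classified against
    age-banded percentile norms entered at the child's developmental age, and
    multi-test abnormality counts are compared with Monte Carlo base rates
    simulated from a correlated healthy reference model.  Includes exact
    binomial tests against fixed base rates, Clopper-Pearson intervals,
    Fisher's exact test, Mann-Whitney U with tie-corrected z, a synthetic
    cohort generator with known ground truth, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
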