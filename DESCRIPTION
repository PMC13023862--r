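Package: faceiat
Title: Implicit Face-Trait Association Scoring and Single-Case Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing implicit association task (IAT) data from
    face-trait judgement experiments, with an emphasis on single-case
    neuropsychology. Implements the improved IAT D-score algorithm in both
    its reference form (block-mean + 600 ms error replacement) and the
    built-in error-penalty variant (full latency to the corrected
    response), together with the standard trial- and participant-level
    latency exclusion rules. Provides the Crawford-Garthwaite modified
    t-test for comparing one case against a normative control sample with
    percentile-rank estimates, group-level one-sample inference (t-test,
    Cohen's d, confidence intervals, the JZS default Bayes factor and its
    sequential form, Spearman correlation), scoring rules for a
    prosopagnosia screening battery (PI20, CFPT deviation scores, famous
    faces adjusted accuracy, AQ-based exclusion, two-task deficit
    classification), a trial-level session simulator for the seven-block
    IAT design, and an end-to-end scoring pipeline with plain-text IO.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
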