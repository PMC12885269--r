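Package: phqlm
Title: Interpretable Depression Severity Assessment from Interview Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts PHQ-8 depression severity from clinical interview
    transcripts using an interpretable two-stage pipeline: a fixed prompting
    protocol scores 23 domain-informed features (clinical symptoms, linguistic
    patterns, cognitive distortions) on a 0-10 scale through a pluggable
    scoring backend, and a standardized linear model maps the features to the
    PHQ-8 scale. Includes structure-coefficient, standardized-beta and
    ablation-based feature-contribution reports with percentile-bootstrap
    confidence intervals and Benjamini-Hochberg false-discovery-rate control,
    lexicon-based construct-validity checks, RBF support-vector-regression and
    stacking-ensemble baselines, a deterministic mock scoring backend, and a
    synthetic cohort generator so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
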