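Package: kdtc
Title: Knockdown Time-Course Transcriptome Classification
Version: 0.1.0
Authors@R: person("kdtc", "maintainers", email = "kdtc@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for siRNA knockdown time-course transcriptomes
    of differentiating myoblasts, comparing single and double knockdowns of the
    paralogous co-activators CBP and P300 against a control siRNA. Implements
    an adaptive fold-change significance cutoff (binned-slope departure from
    linearity of the ordered fold-magnitude curve), transfection-artifact
    exclusion, per-gene classification into factor-specific, common, opposite
    and redundant (double-knockdown-only) response categories, intersection
    with the control-cell differentiation program and with an external
    enhancer-associated gene list, hierarchical-clustering heatmap ordering,
    degree-based hub ranking, and a synthetic-data generator with planted
    ground truth for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
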