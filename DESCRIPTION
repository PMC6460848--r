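Package: rocpv
Title: Prevalence-Aware ROC Analysis with Predictive-Value Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interrogating receiver operating characteristic (ROC)
    curves against clinically meaningful, prevalence-dependent criteria.
    Constructs empirical ROC curves from case-control risk scores, draws
    equi-PPV and equi-NPV isolines in ROC space for a stated disease
    prevalence, partitions the ROC space into clinical-relevance regions,
    tests whether a ROC curve (or its bootstrap confidence band) enters the
    success region defined by rule-in and rule-out predictive-value cutoffs,
    selects decision thresholds under predictive-value constraints, and
    simulates labelled score data with controllable ROC shape, including
    equal-AUROC curves of differing clinical utility.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
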