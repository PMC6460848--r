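# rocpv — prevalence-aware ROC analysis with predictive-value criteria

Biomarker discovery and early prognostic-test development lean on the AUROC,
a rank statistic that is blind to disease prevalence. Clinicians, however,
judge a risk-stratification test by its positive and negative predictive
values (PPV, NPV), which depend strongly on prevalence — at a 5 % disease
prevalence, a test with sensitivity 0.58 and specificity 0.90 delivers a PPV
of only 0.23. `rocpv` closes this gap for test developers working with
case-control data (where prevalence cannot be estimated from the sample and
must be supplied): it expresses PPV/NPV criteria directly in ROC space and
asks whether a candidate test can meet them.

## The method

With sensitivity Sn, specificity Sp and prevalence p, Bayes' theorem gives

    PPV = Sn·p / (Sn·p + (1 − Sp)(1 − p))
    NPV = Sp·(1 − p) / ((1 − Sn)·p + Sp·(1 − p))

Fixing PPV at a cutoff PPVc and solving for the ROC coordinates shows that
all operating points with that PPV lie on a straight line through the origin
of ROC space (x = 1 − Sp, y = Sn):

    Sn = (1 − Sp) · ((1 − p)/p) · (PPVc/(1 − PPVc))        (equi-PPV line)

and analogously all points with NPV = NPVc lie on a line through (1, 1):

    Sn = 1 − Sp · ((1 − p)/p) · ((1 − NPVc)/NPVc)          (equi-NPV line)

Points above a line do better than its cutoff. Together with minimum
sensitivity/specificity targets, these isolines carve a convex **success
region** out of ROC space; a test complies with the clinical criteria
exactly when its ROC curve enters that region. The package provides:

- empirical ROC curves with exact rank/trapezoid AUROC agreement under ties
  (`roc_curve()`, `auroc_rank()`, `sensitivity_at_specificity()`);
- Bayes conversions among Sn/Sp/prevalence, predictive values, likelihood
  ratios and "1 in N" risk notation (`ppv()`, `npv()`,
  `likelihood_ratios()`, `risk_to_probability()`);
- isoline and success-region geometry (`equi_ppv_line()`, `equi_npv_line()`,
  `success_region()`) and curve compliance (`roc_meets_criteria()`),
  including the minimal operating point and AUROC implied by joint
  likelihood-ratio requirements (`lr_to_min_operating_point()`,
  `min_auroc_through_point()`);
- threshold selection under predictive-value constraints, with Youden,
  closest-corner and fixed-specificity comparators and joint
  rule-in/rule-out accounting (`select_rule_in_threshold()`,
  `joint_rule_in_rule_out()`);
- stratified bootstrap confidence bands and three-valued compliance verdicts
  (`bootstrap_roc()`, `compliance_with_ci()`);
- a synthetic-score generator producing equal-AUROC curves of differing
  clinical utility (`generator_spec()`, `equal_auc_trio()`,
  `prevalence_weighted_population()`).

A command-line front end with subcommands `roc`, `isolines`, `comply`,
`select`, `simulate` and `report` is installed at
`system.file("cli", "rocpv", package = "rocpv")`.

## Worked example

Simulate a rule-in-shaped test (half of the cases are very well
discriminated), and ask whether it meets a clinically motivated rule-in
specification — PPV ≥ 0.133 with at least half of the cases detected, at a
5 % prevalence:

```r
library(rocpv)

spec <- generator_spec(case = list(mean = c(3, 0), sd = c(0.5, 1),
                                   weight = c(0.5, 0.5)),
                       n_cases = 200, n_controls = 200)
d   <- simulate_scores(spec, seed = 42)
fit <- roc_curve(d)
summary(fit)
#> AUROC = 0.7752  (200 cases / 200 controls)
#> Sensitivity at fixed specificity:
#>    sp    sn
#>  0.80 0.650
#>  0.90 0.590
#>  0.95 0.575

crit <- predictive_criteria(0.05, ppv_c = 0.133, sn_min = 0.5)
roc_meets_criteria(fit, crit)
#> ROC compliance: COMPLIANT (p = 0.05)
#>   criterion: PPV >= 0.133
#>   criterion: Sn >= 0.5
#>   best achievable PPV = 1.000, NPV = 0.990 at this prevalence
#>   compliant curve section(s), (fpr, sn) from -> to:
#>  fpr_in sn_in fpr_out sn_out
#>    0.01   0.5  0.2247  0.655

select_rule_in_threshold(fit, crit)
#> Threshold choice (ppv-constrained rule): threshold = 0.813195
#>   Sn = 0.655, Sp = 0.790; at p = 0.05: PPV = 0.141, NPV = 0.978

compliance_with_ci(d, crit, B = 500, seed = 42)
#> Compliance with 95% bootstrap uncertainty: COMPLIANT
#>   point estimate meets: TRUE; lower band edge: TRUE; upper band edge: TRUE
#>   fraction of 500 replicate curves meeting the criteria: 1.000
```

The curve enters the success region between sensitivity 0.50 (where the
minimum-sensitivity floor is crossed at a false-positive rate of 0.01) and
0.655 (where it crosses the equi-PPV line). The selected threshold is the
most sensitive compliant operating point: 65.5 % of future cases flagged at
PPV 0.141, comfortably above the 0.133 target, and the verdict survives
bootstrap uncertainty — even the lower edge of the 95 % confidence band
enters the region.

An AUROC of 0.78 alone could not have told you any of this: an
equal-variance binormal test with the same AUROC has markedly lower
sensitivity in the high-specificity corner where rule-in compliance is
decided (see `equal_auc_trio()`).

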