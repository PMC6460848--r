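---
title: "Predictive-value criteria in ROC space: model, geometry and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive-value criteria in ROC space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(rocpv)
```

## The problem this package addresses

Early-stage prognostic tests — say, a first-trimester biomarker panel for
pre-eclampsia risk in first-time pregnancies — are usually developed on
case-control samples and summarised by the AUROC. Both choices are
economical, and both hide prevalence: the case fraction of a case-control
sample is a design artefact, and the AUROC is a pure ranking statistic.
Clinical deployment, by contrast, hinges on prevalence-dependent predictive
values. A rule-in test escalates its positives to intensified care, so it
needs a minimum PPV (and enough sensitivity to be worth running); a
rule-out test de-escalates its negatives, so it needs a minimum NPV (and
enough specificity). At a prevalence of a few percent, respectable-looking
sensitivity/specificity pairs can have dismal PPVs, and candidate tests
selected on AUROC alone routinely fail their clinical requirements.

`rocpv` makes the clinical requirement visible inside the developer's
coordinate system. Everything rests on two elementary identities (Bayes'
theorem applied to the 2×2 table), with sensitivity $S_n$, specificity
$S_p$ and prevalence $p$:

$$\mathrm{PPV} = \frac{S_n\,p}{S_n\,p + (1-S_p)(1-p)}, \qquad
  \mathrm{NPV} = \frac{S_p\,(1-p)}{(1-S_n)\,p + S_p\,(1-p)}.$$

Fixing PPV at a cutoff $c$ and solving for the ROC coordinates
$(x, y) = (1-S_p,\, S_n)$ gives a *straight line through the origin*,

$$y = x \cdot \frac{1-p}{p}\cdot\frac{c}{1-c},$$

the equi-PPV line; every point strictly above it has PPV $> c$. Dually the
equi-NPV locus for cutoff $c'$ is a line through $(1,1)$ with slope
$\frac{1-p}{p}\cdot\frac{1-c'}{c'}$, and points above it have NPV $> c'$.
In inverse form the same algebra is affine in the prior odds:
$1/\mathrm{PPV} = 1 + \frac{(1-p)/p}{\mathrm{LR}^{+}}$ and
$1/\mathrm{NPV} = 1 + \frac{p}{1-p}\,\mathrm{LR}^{-}$, with the likelihood
ratios $\mathrm{LR}^{+} = S_n/(1-S_p)$, $\mathrm{LR}^{-} = (1-S_n)/S_p$;
the package verifies these two routes against each other to machine
precision.

```{r isolines, fig.alt = "ROC space with equi-PPV and equi-NPV lines and success region"}
crit <- predictive_criteria(0.05, ppv_c = 0.133, npv_c = 0.988,
                            sn_min = 0.5, sp_min = 0.5)
region <- success_region(crit)
plot(region, add = FALSE)
lines(equi_ppv_line(0.133, 0.05), col = "firebrick", lwd = 2)
lines(equi_npv_line(0.988, 0.05), col = "navy", lwd = 2)
region
```

The intersection of the half-planes (above both isolines, above the
sensitivity floor, left of the specificity floor) is the **success region**;
a test complies when its ROC curve enters it. All inequalities are closed —
an operating point exactly on a cutoff counts — matching the "≥" phrasing
in which such criteria are stated clinically.

Two geometric facts discovered while implementing this deserve note. First,
the success region can never be strictly empty: the perfect-test corner
$(0, 1)$ satisfies every constraint of this family. What extreme criteria do
is collapse the region to a sliver without interior at that corner; the
`empty` flag on `success_region()` marks this degenerate case, which is the
operational reading of "criteria only an essentially perfect test could
meet". Second, the corners $(0,0)$ and $(1,1)$ lie on *every* equi-PPV
(resp. equi-NPV) line, yet PPV is undefined at $(0,0)$ (no test positives)
and NPV at $(1,1)$ (no negatives). Since every ROC curve starts and ends at
these corners, treating them as compliant would make any curve "meet" any
PPV criterion. Compliance therefore discounts feasible sets that degenerate
to exactly such a corner; a chance-level test correctly fails any
PPV cutoff above prevalence.

## The empirical ROC estimator

`roc_curve()` places one operating point per distinct observed score, with
"score ≥ threshold" defining test-positivity (higher score = higher risk; a
convention that must be fixed for reproducible confusion matrices). Tied
scores produce diagonal segments, and with that convention the trapezoidal
area under the empirical curve equals the tie-corrected Mann–Whitney
statistic computed from midranks *exactly*, not approximately — the suite
asserts agreement to $10^{-12}$ and cross-checks against an independent
pair-counting oracle and the pROC package. Between empirical points the
curve is interpolated linearly: thresholds between observed scores are
realisable by randomisation, interpolation is assumption-free (no binormal
smoothing), and it is the unique choice consistent with trapezoidal area.
Reading the curve at a specificity (`sensitivity_at_specificity()`) returns
the *maximal* sensitivity at vertical steps, i.e. the best operating point
attainable at that specificity.

Compliance is likewise decided on the interpolated curve (crossings found
analytically as segment–line intersections); `interpolate = FALSE` restricts
eligibility to empirical vertices for users who consider only observed
thresholds actionable. The verdict is invariant to refining the curve with
collinear points, which the suite checks.

## Threshold selection

Under a rule-in constraint several thresholds may comply. The package
returns the compliant threshold maximising sensitivity (ties broken towards
higher specificity): once the PPV floor is met, detecting more of the future
cases is strictly better. The rule-out selector mirrors this with
specificity and NPV. This preference is a documented package choice — the
constraint set itself does not rank its members — and the classical
prevalence-blind rules (Youden index, closest-to-corner, fixed specificity)
are provided for comparison; on symmetric equal-variance data Youden and
closest-corner coincide to within one threshold step. Infeasibility is a
*result* (with the closest achievable point attached), not an error, since
"no threshold can meet this specification" is precisely the information a
test developer needs.

When independent rule-in and rule-out tests are deployed together,
`joint_rule_in_rule_out()` accounts for the four joint outcomes, including
the conflict group (flagged high-risk and cleared low-risk simultaneously)
and the unclassified group that stays in one-fits-all care. Because the
case-control sample's case mix is artificial, fractions are reweighted to
the stated prevalence; raw sample fractions are reported alongside.

## Bootstrap uncertainty

`bootstrap_roc()` resamples cases and controls separately (the design fixes
the two group sizes; pooled resampling would add prevalence noise the
design excludes) and forms pointwise percentile intervals of sensitivity on
a fixed specificity grid (defaults: B = 2000, level 0.95, 101 grid points;
percentile rather than BCa as the simplest defensible band, configurable in
principle by post-processing the stored replicate matrix). Seeds are
explicit arguments everywhere and the global RNG stream is never touched,
so identical inputs give bit-identical bands.

`compliance_with_ci()` grades the verdict: **compliant** when even the lower
band edge enters the success region, **potentially compliant** when only the
point estimate or upper edge does, **non-compliant** otherwise. Because "the
confidence band crosses the zone" admits more than one operational reading,
the fraction of individual replicate curves meeting the criteria is always
reported alongside the edge-based verdict; the replicate fraction is
computed on full replicate curves and is therefore independent of the band's
grid density.

At the suite's study scale (500 simulated equal-variance datasets of
100 cases/100 controls, shift 1.19, B = 400) the measured pointwise coverage
of the 95 % band at specificities 0.8 and 0.9 was 0.948–0.956, inside the
liberal 0.90–0.99 bracket that acknowledges percentile-bootstrap bias at
small n.

## What the synthetic generator emulates

Scores are modelled as univariate normal mixtures: standard-normal controls
and, by default, location-shifted cases. This is the simplest family that
realises the phenomenon the package exists to expose — *skewed risk-score
distributions give skewed ROC curves of equal AUROC but unequal clinical
utility*:

- **symmetric**: cases at $N(\delta, 1)$ with
  $\delta = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$ (closed-form binormal AUROC
  $\Phi(\delta/\sqrt2)$);
- **rule-in shaped**: a case mixture with a well-discriminated component at
  $N(3, 0.5^2)$ — a fraction of future cases carries a strong signal, the
  ROC rises steeply at low false-positive rates;
- **rule-out shaped**: the mirror image, a control mixture with a component
  at $N(-3, 0.5^2)$.

The far component's location (3 standard deviations) and tightness (sd 0.5)
were fixed once as a plausibly strong subgroup signal; the mixture weight is
then solved by bisection on the closed-form mixture AUROC (tolerance
$10^{-4}$), so all three members share one target AUROC to within 0.002.
`analytic_auroc()` is the generator's own oracle: the empirical AUROC of a
sample converges to it as n grows, which the suite checks.

```{r trio}
trio <- equal_auc_trio(0.75, n_cases = 4000, n_controls = 4000, seed = 1)
sapply(trio, function(m) round(auc(roc_curve(m$data)), 3))
```

At a 5 % prevalence with the rule-in criteria {PPV ≥ 0.133, Sn ≥ 0.50} and
rule-out criteria {NPV ≥ 0.988, Sp ≥ 0.50}, the rule-in-shaped member meets
the former, the rule-out-shaped member the latter, and each fails the
opposite specification — equal AUROC, different clinical value. One caveat
is worth stating precisely: the *symmetric* member at AUROC 0.75 is a
knife-edge case for the rule-in criteria above — its best PPV subject to
Sn ≥ 0.5 is 0.1340, a margin of 0.001 over the cutoff — so its analytic
compliance status is essentially "on the line" and finite samples fall on
either side. The two mixture members, by contrast, clear or fail their
criteria with wide margins.

`prevalence_weighted_population()` draws cohort-design samples (labels
Bernoulli(p), scores from the matching class) on which predictive values
are observable as plain frequencies; the suite uses it to confirm the Bayes
conversions empirically at prevalences 0.03, 0.05 and 0.07 (n = $10^5$,
agreement within 3 Monte-Carlo standard errors).

What the generator does *not* emulate: real risk scores are bounded,
heteroscedastic, often multimodal for reasons unrelated to outcome, and
measured with batch effects; case-control sampling can distort the patient
spectrum. Passing tests demonstrate the geometry, the estimators and their
consistency — not that any particular biomarker will behave like a normal
mixture.

## Numerical choices and degenerate inputs

- Prevalence is an explicit user input everywhere, never estimated from the
  sample; it must lie strictly inside (0, 1) (degenerate prevalences are
  rejected at validation).
- A PPV cutoff at or below prevalence (or NPV cutoff at or below
  1 − prevalence) is met by the useless chance test; the isoline
  constructors warn rather than fail.
- Required specificities from the rearranged Bayes identity
  (`specificity_for_ppv()`) may be negative; they are reported unclamped,
  because "no specificity can achieve this PPV at this sensitivity and
  prevalence" is the substantive finding.
- All-identical scores are a legitimate non-discriminative test: the curve
  is the diagonal chord with AUROC 0.5, not an error.
- Geometric predicates use closed inequalities with a $10^{-12}$ slack;
  polygon clipping is plain Sutherland–Hodgman against the unit square
  (convexity is guaranteed, so no general polygon library is needed).
- Ties in threshold selection break deterministically (documented per rule),
  so reports are reproducible byte for byte.
- Human-readable output rounds to 3 decimals (round-half-to-even);
  machine-readable output keeps full precision with a separate rounded
  `display` block.

## Study scales used by the test suite

Problem sizes were chosen as the smallest that make each property
statistically unambiguous: $10^4$ per group for the chance-AUROC and trio
checks (AUROC standard error ≈ 0.004), $10^5$ for cohort-frequency Bayes
checks, 200 × 200 grids for isoline sign agreement, 1000 random tied
datasets for the rank/trapezoid identity, and 500 simulated datasets for
band coverage.

## Known limitations

- No covariate adjustment, partial AUC, or smoothed/parametric ROC
  estimation; the empirical curve is the estimand.
- No confidence intervals for single 2×2-table predictive values.
- Percentile bands are pointwise, not simultaneous; "band edge enters the
  region" is therefore a liberal reading of joint compliance.
- Model calibration is orthogonal to everything here: monotone
  recalibration leaves rankings, hence ROC curves and compliance verdicts,
  unchanged — which is exactly why predictive-value criteria can be imposed
  before calibration — but calibrated absolute risks serve a different
  purpose and are out of scope.
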