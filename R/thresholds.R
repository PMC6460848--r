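#' Decision-threshold selection rules
#'
#' Select a score threshold from the empirical operating points of a ROC
#' curve. Two prevalence-aware rules implement rule-in and rule-out test
#' construction: among thresholds meeting the predictive-value constraint,
#' `select_rule_in_threshold()` maximises sensitivity (more cases detected at
#' equal compliance is strictly better; ties broken by higher specificity)
#' and `select_rule_out_threshold()` symmetrically maximises specificity.
#' Three classical prevalence-blind comparators are provided: the Youden
#' index, the point closest to the top-left corner (0, 1), and thresholding
#' at a fixed specificity. Failure to satisfy the constraints is reported as
#' a no-solution result (with the closest achievable operating point), not an
#' error.
#'
#' @param curve a [roc_curve()] (or a `labeled_scores` object / data.frame,
#'   from which a curve is fitted).
#' @param criteria a [predictive_criteria()]; needs `ppv_c` for rule-in,
#'   `npv_c` for rule-out.
#' @return An object of class `"threshold_choice"`: `threshold`, `sn`, `sp`,
#'   achieved `ppv` and `npv` at the stated prevalence, the `rule` used and a
#'   `feasible` flag.
#' @examples
#' fit <- roc_curve(c(1, 4, 3, 5), c(0, 0, 1, 1))
#' youden_threshold(fit)
#' @name threshold_selection
NULL

candidate_points <- function(curve, p = NULL) {
  pts <- curve$points
  out <- data.frame(threshold = pts$threshold, sn = pts$sn, sp = pts$sp)
  if (!is.null(p)) {
    den_p <- out$sn * p + (1 - out$sp) * (1 - p)
    den_n <- (1 - out$sn) * p + out$sp * (1 - p)
    out$ppv <- ifelse(den_p > 0, out$sn * p / den_p, NA_real_)
    out$npv <- ifelse(den_n > 0, out$sp * (1 - p) / den_n, NA_real_)
  }
  out
}

as_curve <- function(x) {
  if (inherits(x, "roc_curve")) x else roc_curve(as_labeled_scores(x))
}

safe_pv <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den

new_threshold_choice <- function(row, rule, p, feasible = TRUE, note = NULL) {
  structure(list(threshold = row$threshold, sn = row$sn, sp = row$sp,
                 ppv = if (!is.null(p))
                   safe_pv(row$sn * p, row$sn * p + (1 - row$sp) * (1 - p))
                 else NA_real_,
                 npv = if (!is.null(p))
                   safe_pv(row$sp * (1 - p),
                           (1 - row$sn) * p + row$sp * (1 - p))
                 else NA_real_,
                 p = p, rule = rule, feasible = feasible, note = note),
            class = "threshold_choice")
}

#' @rdname threshold_selection
#' @export
select_rule_in_threshold <- function(curve, criteria) {
  curve <- as_curve(curve)
  stopifnot(inherits(criteria, "predictive_criteria"))
  if (is.null(criteria$ppv_c))
    stop("rule-in selection requires a `ppv_c` in the criteria", call. = FALSE)
  p <- criteria$p
  cand <- candidate_points(curve, p)
  sn_min <- if (is.null(criteria$sn_min)) 0 else criteria$sn_min
  ok <- !is.na(cand$ppv) & cand$ppv >= criteria$ppv_c & cand$sn >= sn_min
  if (any(ok)) {
    sub <- cand[ok, ]
    sub <- sub[order(-sub$sn, -sub$sp), ]
    new_threshold_choice(sub[1L, ], "ppv-constrained", p)
  } else {
    # closest achievable: the candidate with the highest PPV among those
    # meeting sn_min, else the highest PPV overall
    pool <- cand[!is.na(cand$ppv) & cand$sn >= sn_min, ]
    if (nrow(pool) == 0L) pool <- cand[!is.na(cand$ppv), ]
    best <- pool[order(-pool$ppv, -pool$sn), ][1L, ]
    new_threshold_choice(best, "ppv-constrained", p, feasible = FALSE,
                         note = "no threshold satisfies the criteria; closest achievable point shown")
  }
}

#' @rdname threshold_selection
#' @export
select_rule_out_threshold <- function(curve, criteria) {
  curve <- as_curve(curve)
  stopifnot(inherits(criteria, "predictive_criteria"))
  if (is.null(criteria$npv_c))
    stop("rule-out selection requires an `npv_c` in the criteria", call. = FALSE)
  p <- criteria$p
  cand <- candidate_points(curve, p)
  sp_min <- if (is.null(criteria$sp_min)) 0 else criteria$sp_min
  ok <- !is.na(cand$npv) & cand$npv >= criteria$npv_c & cand$sp >= sp_min
  if (any(ok)) {
    sub <- cand[ok, ]
    sub <- sub[order(-sub$sp, -sub$sn), ]
    new_threshold_choice(sub[1L, ], "npv-constrained", p)
  } else {
    pool <- cand[!is.na(cand$npv) & cand$sp >= sp_min, ]
    if (nrow(pool) == 0L) pool <- cand[!is.na(cand$npv), ]
    best <- pool[order(-pool$npv, -pool$sp), ][1L, ]
    new_threshold_choice(best, "npv-constrained", p, feasible = FALSE,
                         note = "no threshold satisfies the criteria; closest achievable point shown")
  }
}

#' @rdname threshold_selection
#' @param prevalence optional prevalence at which to report achieved
#'   predictive values for the classical rules.
#' @export
youden_threshold <- function(curve, prevalence = NULL) {
  curve <- as_curve(curve)
  cand <- candidate_points(curve)
  j <- cand$sn + cand$sp - 1
  # tie-break: smallest threshold among maximisers
  best <- cand[j >= max(j) - 1e-12, ]
  best <- best[order(best$threshold), ][1L, ]
  new_threshold_choice(best, "youden", prevalence)
}

#' @rdname threshold_selection
#' @export
closest_corner_threshold <- function(curve, prevalence = NULL) {
  curve <- as_curve(curve)
  cand <- candidate_points(curve)
  d <- sqrt((1 - cand$sp)^2 + (1 - cand$sn)^2)
  best <- cand[d <= min(d) + 1e-12, ]
  best <- best[order(best$threshold), ][1L, ]
  new_threshold_choice(best, "closest-corner", prevalence)
}

#' @rdname threshold_selection
#' @param sp_target the specificity to lock (fixed false-positive-rate rule).
#' @export
fixed_specificity_threshold <- function(curve, sp_target, prevalence = NULL) {
  curve <- as_curve(curve)
  check_prob(sp_target, "sp_target")
  cand <- candidate_points(curve)
  ok <- cand$sp >= sp_target
  best <- cand[ok, ]
  best <- best[order(-best$sn, best$sp), ][1L, ]  # most sensitive point still meeting sp
  new_threshold_choice(best, "fixed-specificity", prevalence)
}

#' @rdname threshold_selection
#' @param rule one of `"rule-in"`, `"rule-out"`, `"youden"`, `"corner"`,
#'   `"fixed-sp"`.
#' @param sp_target specificity for `rule = "fixed-sp"`.
#' @export
select_threshold <- function(curve, rule = c("rule-in", "rule-out", "youden",
                                             "corner", "fixed-sp"),
                             criteria = NULL, sp_target = NULL) {
  rule <- match.arg(rule)
  switch(rule,
         "rule-in" = select_rule_in_threshold(curve, criteria),
         "rule-out" = select_rule_out_threshold(curve, criteria),
         "youden" = youden_threshold(curve, criteria$p),
         "corner" = closest_corner_threshold(curve, criteria$p),
         "fixed-sp" = fixed_specificity_threshold(curve, sp_target, criteria$p))
}

#' @export
print.threshold_choice <- function(x, ...) {
  cat(sprintf("Threshold choice (%s rule): threshold = %s\n",
              x$rule, format(x$threshold)))
  cat(sprintf("  Sn = %.3f, Sp = %.3f", x$sn, x$sp))
  if (!is.na(x$ppv))
    cat(sprintf("; at p = %s: PPV = %.3f, NPV = %.3f",
                format(x$p), report_round(x$ppv), report_round(x$npv)))
  cat("\n")
  if (!x$feasible) cat("  NOTE:", x$note, "\n")
  invisible(x)
}

#' Joint classification by paired rule-in and rule-out tests
#'
#' When an independent rule-in test (positives escalated to high-risk care)
#' and rule-out test (negatives de-escalated to low-risk care) are deployed
#' together on the same subjects, four joint categories arise. A subject
#' positive on the rule-in test but negative on the rule-out test receives
#' conflicting information ("conflict" group); one negative on the rule-in
#' test and positive on the rule-out test is flagged by neither and stays in
#' one-fits-all care ("unclassified"). Because case-control samples do not
#' reflect the population case mix, fractions are reweighted to the stated
#' prevalence (the raw sample fractions are also reported).
#'
#' @param scores_in,scores_out risk scores of the two tests for the same
#'   subjects, in the same order.
#' @param labels common 0/1 outcome labels.
#' @param threshold_in,threshold_out decision thresholds (score >= threshold
#'   is positive).
#' @param prevalence population prevalence used for reweighting.
#' @return An object of class `"joint_classification"` with
#'   `population_fractions` and `sample_fractions` over the categories
#'   `high_risk` (rule-in +, rule-out +), `low_risk` (rule-in -, rule-out -),
#'   `conflict` (rule-in +, rule-out -) and `unclassified` (rule-in -,
#'   rule-out +); each set sums to 1.
#' @export
joint_rule_in_rule_out <- function(scores_in, scores_out, labels,
                                   threshold_in, threshold_out, prevalence) {
  check_prevalence(prevalence)
  if (length(scores_in) != length(scores_out) ||
      length(scores_in) != length(labels))
    stop("the two tests must score the same subjects: lengths differ", call. = FALSE)
  labels <- as.integer(labels)
  pos_in <- scores_in >= threshold_in    # flagged high risk
  pos_out <- scores_out >= threshold_out # NOT cleared (rule-out negative clears)
  cat4 <- function(keep) {
    c(high_risk = mean(pos_in[keep] & pos_out[keep]),
      low_risk = mean(!pos_in[keep] & !pos_out[keep]),
      conflict = mean(pos_in[keep] & !pos_out[keep]),
      unclassified = mean(!pos_in[keep] & pos_out[keep]))
  }
  by_case <- cat4(labels == 1L)
  by_ctrl <- cat4(labels == 0L)
  pop <- prevalence * by_case + (1 - prevalence) * by_ctrl
  n <- length(labels)
  samp <- (sum(labels) * by_case + sum(labels == 0L) * by_ctrl) / n
  structure(list(population_fractions = pop, sample_fractions = samp,
                 by_case = by_case, by_control = by_ctrl,
                 prevalence = prevalence),
            class = "joint_classification")
}

#' @export
print.joint_classification <- function(x, ...) {
  cat(sprintf("Joint rule-in/rule-out classification (prevalence-weighted, p = %s):\n",
              format(x$prevalence)))
  print(round(x$population_fractions, 4))
  cat("Unweighted sample fractions:\n")
  print(round(x$sample_fractions, 4))
  invisible(x)
}
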