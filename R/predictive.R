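#' Positive predictive value from sensitivity, specificity and prevalence
#'
#' Bayes' theorem for the probability of disease given a positive test:
#' \deqn{PPV = \frac{S_n p}{S_n p + (1 - S_p)(1 - p)}}
#' Prevalence is the pre-test probability of the condition in the intended-use
#' population; under a case-control design it cannot be estimated from the
#' sample and must be supplied.
#'
#' @param sn sensitivity in `[0, 1]`.
#' @param sp specificity in `[0, 1]`.
#' @param p prevalence, strictly inside `(0, 1)`.
#' @return PPV in `[0, 1]`. Vectorised over all arguments.
#' @examples
#' ppv(0.58, 0.90, 0.05)
#' @export
ppv <- function(sn, sp, p) {
  check_prob(sn, "sn"); check_prob(sp, "sp"); check_prevalence(p)
  den <- sn * p + (1 - sp) * (1 - p)
  if (any(den == 0))
    stop("PPV undefined: no test-positives possible (sn = 0, sp = 1)", call. = FALSE)
  sn * p / den
}

#' Negative predictive value from sensitivity, specificity and prevalence
#'
#' \deqn{NPV = \frac{S_p (1 - p)}{(1 - S_n) p + S_p (1 - p)}}
#'
#' @inheritParams ppv
#' @return NPV in `[0, 1]`. Vectorised.
#' @examples
#' npv(0.58, 0.90, 0.05)
#' @export
npv <- function(sn, sp, p) {
  check_prob(sn, "sn"); check_prob(sp, "sp"); check_prevalence(p)
  den <- (1 - sn) * p + sp * (1 - p)
  if (any(den == 0))
    stop("NPV undefined: no test-negatives possible (sn = 1, sp = 0)", call. = FALSE)
  sp * (1 - p) / den
}

#' Likelihood ratios of an operating point
#'
#' `lr_pos = sn / (1 - sp)` (reported as `Inf` when `sp == 1`) and
#' `lr_neg = (1 - sn) / sp`. These prevalence-free ratios link pre-test to
#' post-test odds.
#'
#' @inheritParams ppv
#' @return List with `lr_pos` and `lr_neg`, classed `"likelihood_ratios"`.
#' @examples
#' likelihood_ratios(0.8163, 0.9184)
#' @export
likelihood_ratios <- function(sn, sp) {
  check_prob(sn, "sn"); check_prob(sp, "sp")
  if (sp == 0)
    stop("negative likelihood ratio undefined at sp = 0", call. = FALSE)
  lr_pos <- if (sp == 1) Inf else sn / (1 - sp)
  structure(list(lr_pos = lr_pos, lr_neg = (1 - sn) / sp),
            class = "likelihood_ratios")
}

#' @export
print.likelihood_ratios <- function(x, ...) {
  cat(sprintf("LR+ = %s, LR- = %s\n",
              format(x$lr_pos, digits = 4), format(x$lr_neg, digits = 4)))
  invisible(x)
}

#' Inverse predictive values as linear functions of prior odds
#'
#' The multiplicative inverse of PPV is affine in the inverse prior odds at a
#' fixed positive likelihood ratio, `1/PPV = 1 + ((1 - p)/p) / LR+`, and the
#' inverse of NPV is affine in the prior odds at a fixed negative likelihood
#' ratio, `1/NPV = 1 + (p/(1 - p)) LR-`. These identities are algebraically
#' equivalent to the Bayes forms in [ppv()] and [npv()].
#'
#' @param lr_pos positive likelihood ratio, `> 0`.
#' @param lr_neg negative likelihood ratio, `>= 0`.
#' @param p prevalence in `(0, 1)`.
#' @return The inverse predictive value (a number `>= 1`).
#' @export
inverse_ppv_linear <- function(lr_pos, p) {
  stopifnot(all(lr_pos > 0))
  check_prevalence(p)
  1 + ((1 - p) / p) / lr_pos
}

#' @rdname inverse_ppv_linear
#' @export
inverse_npv_linear <- function(lr_neg, p) {
  stopifnot(all(lr_neg >= 0))
  check_prevalence(p)
  1 + (p / (1 - p)) * lr_neg
}

#' "1 in N" risk notation
#'
#' Clinical risk is often quoted as "1 in N". `risk_to_probability()` converts
#' it to the probability `1/N` (a post-test probability of disease, i.e. a
#' PPV when applied to test positives); `risk_to_npv()` converts a residual
#' risk among test negatives to the NPV `1 - 1/N`; `probability_to_risk()`
#' is the inverse of the first.
#'
#' @param risk a number `N > 1`, or a string like `"1 in 7.5"`
#'   (case-insensitive).
#' @return A probability in `(0, 1)` (or `N` for `probability_to_risk()`).
#' @examples
#' risk_to_probability("1 in 7.5")  # 0.1333...
#' risk_to_npv(77)                  # 0.987...
#' @export
risk_to_probability <- function(risk) {
  n <- parse_risk(risk)
  1 / n
}

#' @rdname risk_to_probability
#' @export
risk_to_npv <- function(risk) {
  n <- parse_risk(risk)
  1 - 1 / n
}

#' @rdname risk_to_probability
#' @param probability a probability in `(0, 1)`.
#' @export
probability_to_risk <- function(probability) {
  stopifnot(all(probability > 0), all(probability < 1))
  1 / probability
}

parse_risk <- function(risk) {
  if (is.character(risk)) {
    m <- regmatches(risk, regexec("^\\s*1\\s+in\\s+([0-9.]+)\\s*$", risk,
                                  ignore.case = TRUE))
    n <- suppressWarnings(as.numeric(vapply(m, function(g) {
      if (length(g) == 2L) g[2L] else NA_character_
    }, character(1))))
    if (anyNA(n))
      stop("risk must be numeric or of the form \"1 in N\"", call. = FALSE)
  } else {
    n <- as.numeric(risk)
  }
  if (any(is.na(n)) || any(n <= 1))
    stop("invalid risk: N must be > 1 in \"1 in N\"", call. = FALSE)
  n
}

check_prob <- function(x, name) {
  if (any(x < 0 | x > 1))
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  invisible(x)
}

check_prevalence <- function(p) {
  if (any(p <= 0 | p >= 1))
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  invisible(p)
}

# round-half-to-even at the reporting layer; full precision kept internally
report_round <- function(x, digits = 3L) round(x, digits)
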