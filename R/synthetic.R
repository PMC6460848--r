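#' Specification of a synthetic score generator
#'
#' Describes the score distributions of controls and cases as univariate
#' normal mixtures. The default emulates the canonical biomarker setting:
#' standard-normal controls and location-shifted cases. Skewed ROC shapes —
#' the kind that favour rule-in or rule-out use — are obtained by giving one
#' class a two-component mixture with a far-shifted, tight, well-discriminated
#' component.
#'
#' @param case,control each a list with numeric vectors `mean`, `sd` and
#'   `weight` (weights sum to 1) describing a normal mixture; scalars are
#'   single components.
#' @param n_cases,n_controls sample sizes, `>= 1`.
#' @return An object of class `"generator_spec"`.
#' @examples
#' spec <- generator_spec(case = list(mean = 1.19), n_cases = 100, n_controls = 100)
#' analytic_auroc(spec)
#' @export
generator_spec <- function(case = list(mean = 1, sd = 1, weight = 1),
                           control = list(mean = 0, sd = 1, weight = 1),
                           n_cases = 100L, n_controls = 100L) {
  norm_mix <- function(m) {
    m <- list(mean = as.numeric(m$mean),
              sd = if (is.null(m$sd)) rep(1, length(m$mean)) else as.numeric(m$sd),
              weight = if (is.null(m$weight)) rep(1 / length(m$mean), length(m$mean))
                       else as.numeric(m$weight))
    k <- length(m$mean)
    if (length(m$sd) == 1L) m$sd <- rep(m$sd, k)
    if (length(m$weight) == 1L && k == 1L) m$weight <- 1
    stopifnot(length(m$sd) == k, length(m$weight) == k,
              all(m$sd > 0), all(m$weight >= 0))
    if (abs(sum(m$weight) - 1) > 1e-9)
      stop("mixture weights must sum to 1", call. = FALSE)
    m
  }
  stopifnot(n_cases >= 1L, n_controls >= 1L)
  structure(list(case = norm_mix(case), control = norm_mix(control),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls)),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  fmt <- function(m) paste(sprintf("%.3g*N(%.3g, %.3g^2)", m$weight, m$mean, m$sd),
                           collapse = " + ")
  cat("Synthetic score generator\n")
  cat("  controls:", fmt(x$control), sprintf(" (n = %d)\n", x$n_controls))
  cat("  cases   :", fmt(x$case), sprintf(" (n = %d)\n", x$n_cases))
  cat(sprintf("  analytic AUROC = %.4f\n", analytic_auroc(x)))
  invisible(x)
}

r_mixture <- function(n, mix) {
  comp <- sample.int(length(mix$weight), n, replace = TRUE, prob = mix$weight)
  stats::rnorm(n, mean = mix$mean[comp], sd = mix$sd[comp])
}

# run `expr` under a local RNG stream seeded with `seed`; the caller's global
# RNG state is untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw labelled scores from a generator specification
#'
#' Reproducible given `seed`; the global RNG state is left untouched. As the
#' sample sizes grow, the empirical AUROC of the sample converges to
#' [analytic_auroc()] of the specification.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed (required; no hidden global random state).
#' @return A `labeled_scores` object.
#' @export
simulate_scores <- function(spec, seed) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(seed, {
    cases <- r_mixture(spec$n_cases, spec$case)
    controls <- r_mixture(spec$n_controls, spec$control)
    labeled_scores(c(cases, controls),
                   c(rep(1L, spec$n_cases), rep(0L, spec$n_controls)))
  })
}

#' Closed-form AUROC of a generator specification
#'
#' For normal mixtures the probability that a random case outscores a random
#' control decomposes over component pairs:
#' `sum_ij w_i v_j Phi((mu_i - nu_j) / sqrt(s_i^2 + t_j^2))`.
#'
#' @param spec a [generator_spec()].
#' @return AUROC in `[0, 1]`.
#' @export
analytic_auroc <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  ca <- spec$case; co <- spec$control
  total <- 0
  for (i in seq_along(ca$mean)) {
    for (j in seq_along(co$mean)) {
      total <- total + ca$weight[i] * co$weight[j] *
        stats::pnorm((ca$mean[i] - co$mean[j]) /
                     sqrt(ca$sd[i]^2 + co$sd[j]^2))
    }
  }
  total
}

# bisection on mixture weight f so that analytic AUROC hits the target
solve_mixture_weight <- function(target_auc, make_spec, tol = 1e-4) {
  f_lo <- 0; f_hi <- 1
  a_lo <- analytic_auroc(make_spec(f_lo))
  a_hi <- analytic_auroc(make_spec(f_hi))
  if (target_auc < min(a_lo, a_hi) || target_auc > max(a_lo, a_hi))
    stop(sprintf("target AUROC %.3f infeasible for this mixture geometry (achievable range %.3f-%.3f)",
                 target_auc, min(a_lo, a_hi), max(a_lo, a_hi)), call. = FALSE)
  increasing <- a_hi > a_lo
  for (it in 1:100) {
    f <- (f_lo + f_hi) / 2
    a <- analytic_auroc(make_spec(f))
    if (abs(a - target_auc) < tol) break
    if ((a < target_auc) == increasing) f_lo <- f else f_hi <- f
  }
  f
}

#' Three equal-AUROC score models of differing clinical utility
#'
#' Constructs three generator specifications sharing one analytic AUROC yet
#' differing in ROC shape, and samples from each:
#' \describe{
#'   \item{symmetric}{equal-variance binormal, case shift
#'     `sqrt(2) * qnorm(target_auc)` — the textbook ROC shape.}
#'   \item{rule_in}{a fraction of cases is very well discriminated (case
#'     mixture with a component at N(3, 0.5^2)); the ROC rises steeply at
#'     low false-positive rates, favouring high-PPV rule-in use.}
#'   \item{rule_out}{mirror image: a fraction of controls is very well
#'     discriminated (component at N(-3, 0.5^2)); the ROC approaches
#'     sensitivity 1 early in specificity terms, favouring high-NPV rule-out
#'     use.}
#' }
#' Mixture weights are solved by bisection on the closed-form AUROC
#' (tolerance 1e-4). Equal AUROC does not imply equal clinical utility: at a
#' low prevalence the three members differ markedly in the predictive-value
#' criteria they can meet.
#'
#' @param target_auc common AUROC, in `(0.5, 1)`.
#' @param n_cases,n_controls per-group sample sizes.
#' @param seed integer seed; the three samples use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return A list with elements `symmetric`, `rule_in`, `rule_out`, each a
#'   list of `spec` (the `generator_spec`) and `data` (`labeled_scores`).
#' @export
equal_auc_trio <- function(target_auc, n_cases = 1000L, n_controls = 1000L,
                           seed = 1L) {
  stopifnot(target_auc > 0.5, target_auc < 1)
  sym <- generator_spec(case = list(mean = sqrt(2) * stats::qnorm(target_auc)),
                        n_cases = n_cases, n_controls = n_controls)
  mk_in <- function(f) generator_spec(
    case = list(mean = c(3, 0), sd = c(0.5, 1), weight = c(f, 1 - f)),
    n_cases = n_cases, n_controls = n_controls)
  mk_out <- function(f) generator_spec(
    control = list(mean = c(-3, 0), sd = c(0.5, 1), weight = c(f, 1 - f)),
    case = list(mean = 0),
    n_cases = n_cases, n_controls = n_controls)
  f_in <- solve_mixture_weight(target_auc, mk_in)
  f_out <- solve_mixture_weight(target_auc, mk_out)
  specs <- list(symmetric = sym, rule_in = mk_in(f_in), rule_out = mk_out(f_out))
  out <- vector("list", 3L)
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    out[[i]] <- list(spec = specs[[i]],
                     data = simulate_scores(specs[[i]], seed + i - 1L))
  }
  out
}

#' Cohort-design sample at a stated prevalence
#'
#' Draws `n` subjects whose label is 1 with probability `p` and whose score
#' comes from the matching class distribution of `spec` — the sampling design
#' under which predictive values are directly observable as frequencies.
#' Used to verify the Bayes-theorem conversions empirically.
#'
#' @param spec a [generator_spec()] (its `n_cases`/`n_controls` are ignored).
#' @param p prevalence in `(0, 1)`.
#' @param n total cohort size.
#' @param seed integer seed.
#' @return A `labeled_scores` object of length `n`.
#' @export
prevalence_weighted_population <- function(spec, p, n, seed) {
  stopifnot(inherits(spec, "generator_spec"))
  check_prevalence(p)
  with_seed(seed, {
    label <- stats::rbinom(n, 1L, p)
    score <- numeric(n)
    score[label == 1L] <- r_mixture(sum(label == 1L), spec$case)
    score[label == 0L] <- r_mixture(sum(label == 0L), spec$control)
    labeled_scores(score, label)
  })
}
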