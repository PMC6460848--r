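#' Stratified bootstrap confidence band for a ROC curve
#'
#' Resamples cases and controls separately with replacement (the case-control
#' design fixes the group sizes, so pooled resampling would inject prevalence
#' noise the design excludes), re-fits the empirical ROC of each replicate,
#' reads its sensitivity at a fixed specificity grid, and forms pointwise
#' percentile intervals at the stated confidence level. Fully reproducible
#' given `seed`; the global RNG state is untouched.
#'
#' @param data a `labeled_scores` object (or data.frame with
#'   `score`/`label`).
#' @param B number of bootstrap replicates, `>= 100` (default 2000).
#' @param level confidence level in `(0, 1)` (default 0.95).
#' @param sp_grid specificity grid (default 101 equally spaced points).
#' @param seed integer seed (required).
#' @return An object of class `"roc_band"`: data.frame `band` with columns
#'   `sp`, `sn_lo`, `sn_hat`, `sn_hi`, plus `B`, `level`, `seed` and the
#'   matrix of replicate sensitivities.
#' @examples
#' d <- simulate_scores(generator_spec(case = list(mean = 1.19),
#'                                     n_cases = 50, n_controls = 50), seed = 7)
#' b <- bootstrap_roc(d, B = 200, seed = 7)
#' @export
bootstrap_roc <- function(data, B = 2000L, level = 0.95,
                          sp_grid = seq(0, 1, length.out = 101L), seed) {
  data <- as_labeled_scores(data)
  stopifnot(B >= 100L, level > 0, level < 1)
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  cases <- data$score[data$label == 1L]
  controls <- data$score[data$label == 0L]
  if (length(cases) < 5L || length(controls) < 5L)
    stop("need at least 5 subjects in each class to bootstrap", call. = FALSE)
  if (length(cases) < 20L || length(controls) < 20L)
    warning("fewer than 20 subjects in a class: percentile band may be unreliable",
            call. = FALSE)
  sn_hat <- sens_at_sp_scores(cases, controls, sp_grid)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      sens_at_sp_scores(sample(cases, replace = TRUE),
                        sample(controls, replace = TRUE),
                        sp_grid)
    }, numeric(length(sp_grid)))
  })
  reps <- matrix(reps, nrow = length(sp_grid))
  alpha <- (1 - level) / 2
  qs <- apply(reps, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  band <- data.frame(sp = sp_grid,
                     sn_lo = pmin(qs[1L, ], sn_hat),
                     sn_hat = sn_hat,
                     sn_hi = pmax(qs[2L, ], sn_hat))
  structure(list(band = band, B = B, level = level, seed = seed,
                 replicates = reps, data = data),
            class = "roc_band")
}

#' @export
print.roc_band <- function(x, ...) {
  cat(sprintf("Bootstrap ROC band: B = %d stratified replicates, %.0f%% pointwise percentile interval (seed %d)\n",
              x$B, 100 * x$level, x$seed))
  show <- x$band[x$band$sp %in% c(0.5, 0.8, 0.9, 0.95), ]
  if (nrow(show)) print(format(show, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Plot a bootstrap ROC band
#'
#' @param x a `roc_band`.
#' @param ... graphical parameters passed to [graphics::lines()] for the
#'   point estimate.
#' @export
plot.roc_band <- function(x, ...) {
  b <- x$band[order(1 - x$band$sp), ]
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), asp = 1,
                 xlab = "1 - specificity (FPR)", ylab = "Sensitivity")
  graphics::abline(0, 1, col = "grey70", lty = 3)
  graphics::polygon(c(1 - b$sp, rev(1 - b$sp)), c(b$sn_lo, rev(b$sn_hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(1 - b$sp, b$sn_hat, ...)
  invisible(x)
}

#' Compliance verdict with bootstrap uncertainty
#'
#' Combines [roc_meets_criteria()] with the stratified bootstrap: the verdict
#' is `"compliant"` when even the lower edge of the pointwise confidence band
#' enters the success region, `"potentially compliant"` when only the point
#' estimate or the upper edge does, and `"non-compliant"` otherwise. The
#' fraction of individual bootstrap replicate curves meeting the criteria is
#' reported alongside (replicate compliance is computed on full replicate
#' curves, not on the gridded band).
#'
#' @inheritParams bootstrap_roc
#' @param criteria a [predictive_criteria()].
#' @return An object of class `"compliance_ci"`: `verdict`,
#'   `point_estimate_meets`, `lower_meets`, `upper_meets`,
#'   `replicate_fraction`, and the underlying `roc_band`.
#' @export
compliance_with_ci <- function(data, criteria, B = 2000L, level = 0.95,
                               sp_grid = seq(0, 1, length.out = 101L), seed) {
  data <- as_labeled_scores(data)
  stopifnot(inherits(criteria, "predictive_criteria"))
  band <- bootstrap_roc(data, B = B, level = level, sp_grid = sp_grid,
                        seed = seed)
  cons <- criteria_constraints(criteria)
  curve <- roc_curve(data)
  point_meets <- curve_region_intervals(curve$points$fpr, curve$points$sn,
                                        cons)$meets
  edge_meets <- function(sn_col) {
    o <- order(1 - band$band$sp)
    curve_region_intervals((1 - band$band$sp)[o], band$band[[sn_col]][o],
                           cons)$meets
  }
  lower_meets <- edge_meets("sn_lo")
  upper_meets <- edge_meets("sn_hi")
  cases <- data$score[data$label == 1L]
  controls <- data$score[data$label == 0L]
  rep_meets <- with_seed(band$seed, {
    vapply(seq_len(B), function(b) {
      ca <- sample(cases, replace = TRUE)
      co <- sample(controls, replace = TRUE)
      g <- roc_coords(ca, co)
      curve_region_intervals(g$fpr, g$sn, cons)$meets
    }, logical(1))
  })
  verdict <- if (lower_meets) "compliant"
             else if (point_meets || upper_meets) "potentially compliant"
             else "non-compliant"
  structure(list(verdict = verdict, point_estimate_meets = point_meets,
                 lower_meets = lower_meets, upper_meets = upper_meets,
                 replicate_fraction = mean(rep_meets),
                 criteria = criteria, band = band),
            class = "compliance_ci")
}

#' @export
print.compliance_ci <- function(x, ...) {
  cat(sprintf("Compliance with %.0f%% bootstrap uncertainty: %s\n",
              100 * x$band$level, toupper(x$verdict)))
  cat(sprintf("  point estimate meets: %s; lower band edge: %s; upper band edge: %s\n",
              x$point_estimate_meets, x$lower_meets, x$upper_meets))
  cat(sprintf("  fraction of %d replicate curves meeting the criteria: %.3f\n",
              x$band$B, x$replicate_fraction))
  invisible(x)
}
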