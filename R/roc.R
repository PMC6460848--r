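#' Labelled risk scores
#'
#' Validate and package per-subject continuous risk scores with binary
#' outcome labels, the unit of data for all ROC analyses in this package.
#' Scores are oriented so that higher values mean higher predicted risk;
#' labels use 1 for subjects that develop the condition (cases) and 0 for
#' those that do not (controls).
#'
#' @param score numeric vector of risk scores (dimensionless).
#' @param label vector of 0/1 outcome indicators, same length as `score`.
#' @return A `data.frame` with columns `score` and `label`, classed
#'   `"labeled_scores"`.
#' @examples
#' d <- labeled_scores(c(1, 4, 3, 5), c(0, 0, 1, 1))
#' @export
labeled_scores <- function(score, label) {
  score <- as.numeric(score)
  label <- as.integer(label)
  if (length(score) != length(label))
    stop("`score` and `label` must have equal length", call. = FALSE)
  if (length(score) < 2L)
    stop("need at least two subjects", call. = FALSE)
  if (anyNA(score) || anyNA(label))
    stop("missing values in `score` or `label`; filter them first", call. = FALSE)
  if (!all(label %in% c(0L, 1L)))
    stop("`label` must contain only 0 and 1", call. = FALSE)
  if (sum(label) == 0L || sum(label) == length(label))
    stop("need at least one case (label 1) and one control (label 0)", call. = FALSE)
  structure(data.frame(score = score, label = label),
            class = c("labeled_scores", "data.frame"))
}

#' Confusion matrix at a decision threshold
#'
#' A subject is test-positive iff its score is greater than or equal to the
#' threshold (weak inequality; higher score means higher risk).
#'
#' @param data a `labeled_scores` object (or data.frame with `score`/`label`).
#' @param threshold decision threshold on the score scale; may be +/-Inf.
#' @return List with integer counts `tp`, `fp`, `tn`, `fn`, classed
#'   `"confusion_matrix"`.
#' @examples
#' confusion_at_threshold(labeled_scores(c(1, 4, 3, 5), c(0, 0, 1, 1)), 3)
#' @export
confusion_at_threshold <- function(data, threshold) {
  data <- as_labeled_scores(data)
  pos <- data$score >= threshold
  case <- data$label == 1L
  structure(list(tp = sum(pos & case), fp = sum(pos & !case),
                 tn = sum(!pos & !case), fn = sum(!pos & case),
                 threshold = threshold),
            class = "confusion_matrix")
}

as_labeled_scores <- function(data) {
  if (inherits(data, "labeled_scores")) return(data)
  if (is.data.frame(data) && all(c("score", "label") %in% names(data)))
    return(labeled_scores(data$score, data$label))
  stop("expected a `labeled_scores` object or a data.frame with columns score, label",
       call. = FALSE)
}

#' Sensitivity (true positive rate) of a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @return `tp / (tp + fn)`.
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn == 0)
    stop("sensitivity undefined: no cases present", call. = FALSE)
  cm$tp / (cm$tp + cm$fn)
}

#' Specificity (true negative rate) of a confusion matrix
#'
#' @param cm a `confusion_matrix`.
#' @return `tn / (tn + fp)`.
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0)
    stop("specificity undefined: no controls present", call. = FALSE)
  cm$tn / (cm$tn + cm$fp)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix at threshold", format(x$threshold), "\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              truth = c("case", "control")))
  print(m)
  invisible(x)
}

#' Empirical ROC curve
#'
#' Fit the empirical receiver operating characteristic curve of a continuous
#' risk score against a binary outcome. One operating point is placed at each
#' distinct observed score (a subject is positive iff score >= threshold), so
#' tied scores produce diagonal segments; a `+Inf` threshold supplies the
#' (sensitivity 0, specificity 1) corner and the minimum score supplies the
#' (1, 0) corner. The area under the curve is computed by the trapezoidal
#' rule and equals the tie-corrected Mann-Whitney rank statistic exactly.
#'
#' @param x risk scores (numeric), a `labeled_scores` object, or a formula
#'   `label ~ score`.
#' @param ... passed between methods.
#' @return An object of class `"roc_curve"`: a list with `points` (data.frame
#'   of `threshold`, `sn`, `sp`, `fpr`, ordered by decreasing threshold),
#'   `auc`, `n_cases`, `n_controls` and the original data.
#' @examples
#' fit <- roc_curve(c(1, 4, 3, 5), c(0, 0, 1, 1))
#' auc(fit)
#' @export
roc_curve <- function(x, ...) UseMethod("roc_curve")

#' @rdname roc_curve
#' @param label 0/1 outcome labels (default method).
#' @export
roc_curve.default <- function(x, label, ...) {
  roc_curve(labeled_scores(x, label))
}

#' @rdname roc_curve
#' @param data a data.frame in which the formula terms are evaluated.
#' @export
roc_curve.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data = data)
  roc_curve(labeled_scores(mf[[2L]], mf[[1L]]))
}

#' @rdname roc_curve
#' @export
roc_curve.labeled_scores <- function(x, ...) {
  cases <- x$score[x$label == 1L]
  controls <- x$score[x$label == 0L]
  g <- roc_coords(cases, controls)
  pts <- data.frame(threshold = g$thr, sn = g$sn, sp = 1 - g$fpr, fpr = g$fpr)
  structure(list(points = pts,
                 auc = auroc_trapezoid(g$fpr, g$sn),
                 n_cases = length(cases), n_controls = length(controls),
                 data = x),
            class = "roc_curve")
}

#' Trapezoidal area under a piecewise-linear ROC curve
#'
#' @param fpr,sn coordinates of the curve vertices in ROC space
#'   (x = 1 - specificity, y = sensitivity), ordered along the curve.
#' @return Area in `[0, 1]`.
#' @examples
#' auroc_trapezoid(c(0, 1), c(0, 1))  # chance diagonal: 0.5
#' @export
auroc_trapezoid <- function(fpr, sn) {
  stopifnot(length(fpr) == length(sn), length(fpr) >= 2L)
  sum(diff(fpr) * (utils::head(sn, -1L) + utils::tail(sn, -1L)) / 2)
}

#' Rank (Mann-Whitney) AUROC
#'
#' The probability that a randomly chosen case scores higher than a randomly
#' chosen control, with tied pairs counted one half. Computed from midranks,
#' so it agrees exactly with the trapezoidal area under the empirical ROC
#' curve of [roc_curve()].
#'
#' @param data a `labeled_scores` object or data.frame with `score`, `label`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc_rank <- function(data) {
  data <- as_labeled_scores(data)
  m <- sum(data$label == 1L)
  n <- sum(data$label == 0L)
  r <- rank(data$score)          # midranks handle ties
  (sum(r[data$label == 1L]) - m * (m + 1) / 2) / (m * n)
}

# ROC vertices from raw class scores: one point per distinct score plus the
# +Inf corner, by cumulative counts over the descending distinct values
# (O(n log n); no per-threshold scan).
roc_coords <- function(cases, controls) {
  thr_vals <- sort(unique(c(cases, controls)), decreasing = TRUE)
  k <- length(thr_vals)
  n_case_at <- tabulate(match(cases, thr_vals), nbins = k)
  n_ctrl_at <- tabulate(match(controls, thr_vals), nbins = k)
  list(thr = c(Inf, thr_vals),
       sn = c(0, cumsum(n_case_at)) / length(cases),
       fpr = c(0, cumsum(n_ctrl_at)) / length(controls))
}

# Sensitivity at specificity on the interpolated curve, fast path used by the
# bootstrap: takes raw class scores and a grid of specificities.
sens_at_sp_scores <- function(cases, controls, sp_target) {
  g <- roc_coords(cases, controls)
  interp_sn_at_fpr(g$fpr, g$sn, 1 - sp_target)
}

# Linear interpolation of sensitivity at given FPR values; vertical jumps
# (duplicate fpr) collapse to their maximal sensitivity, so the value at a
# specificity is the best sensitivity attainable there.
interp_sn_at_fpr <- function(fpr, sn, x_out) {
  stats::approx(fpr, sn, xout = x_out, ties = max, rule = 2)$y
}

#' Sensitivity of a ROC curve at a given specificity
#'
#' Reads the curve at specificity `sp_target`, linearly interpolating between
#' adjacent empirical operating points (thresholds between observed scores are
#' realisable by randomisation). At a vertical step the maximal sensitivity is
#' returned.
#'
#' @param curve a `roc_curve`.
#' @param sp_target specificity (or vector of specificities) in `[0, 1]`.
#' @return Sensitivity value(s) in `[0, 1]`.
#' @export
sensitivity_at_specificity <- function(curve, sp_target) {
  stopifnot(inherits(curve, "roc_curve"), all(sp_target >= 0 & sp_target <= 1))
  interp_sn_at_fpr(curve$points$fpr, curve$points$sn, 1 - sp_target)
}

#' Area under a fitted ROC curve
#'
#' @param object a `roc_curve`.
#' @param ... unused.
#' @return The AUROC.
#' @export
auc <- function(object, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.roc_curve <- function(object, ...) object$auc

#' @export
print.roc_curve <- function(x, ...) {
  cat("Empirical ROC curve:", x$n_cases, "cases,", x$n_controls, "controls\n")
  cat(sprintf("AUROC = %.4f (%d operating points)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' @export
summary.roc_curve <- function(object, ...) {
  sp_grid <- c(0.8, 0.9, 0.95)
  sn <- sensitivity_at_specificity(object, sp_grid)
  out <- list(auc = object$auc, n_cases = object$n_cases,
              n_controls = object$n_controls,
              at_specificity = data.frame(sp = sp_grid, sn = sn))
  class(out) <- "summary.roc_curve"
  out
}

#' @export
print.summary.roc_curve <- function(x, ...) {
  cat(sprintf("AUROC = %.4f  (%d cases / %d controls)\n",
              x$auc, x$n_cases, x$n_controls))
  cat("Sensitivity at fixed specificity:\n")
  print(format(x$at_specificity, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Plot an empirical ROC curve
#'
#' @param x a `roc_curve`.
#' @param add logical; add to an existing plot.
#' @param ... further graphical parameters passed to [graphics::lines()].
#' @export
plot.roc_curve <- function(x, add = FALSE, ...) {
  if (!add) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), asp = 1,
                   xlab = "1 - specificity (FPR)", ylab = "Sensitivity")
    graphics::abline(0, 1, col = "grey70", lty = 3)
  }
  graphics::lines(x$points$fpr, x$points$sn, ...)
  invisible(x)
}

#' Read labelled scores from a delimited text file
#'
#' Comma- or tab-separated, auto-detected from the extension (`.csv` vs
#' `.tsv`/`.txt`), with a header row containing at least `score` and `label`.
#' Extra columns are ignored; rows with a missing score or label are dropped
#' with a message reporting the count.
#'
#' @param path file path.
#' @return A `labeled_scores` object.
#' @export
read_scores <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("score", "label") %in% names(df)))
    stop("input must have columns `score` and `label`: ", path, call. = FALSE)
  keep <- stats::complete.cases(df[, c("score", "label")])
  if (any(!keep))
    message(sum(!keep), " row(s) with missing score or label dropped")
  labeled_scores(df$score[keep], df$label[keep])
}

#' Write a ROC curve's operating points as CSV
#'
#' Columns `threshold`, `sn`, `sp`, `fpr`, one row per operating point.
#'
#' @param curve a `roc_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(curve, path) {
  stopifnot(inherits(curve, "roc_curve"))
  utils::write.csv(curve$points, path, row.names = FALSE)
  invisible(path)
}
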