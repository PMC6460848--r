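#' Clinical predictive-value criteria
#'
#' Bundle the prevalence of the condition in the intended-use population with
#' the predictive-value cutoffs that define clinical relevance: a PPV cutoff
#' (rule-in), an NPV cutoff (rule-out), and optional minimum sensitivity /
#' specificity. At least one of `ppv_c`, `npv_c` must be given.
#'
#' @param prevalence pre-test probability of the condition, in `(0, 1)`.
#' @param ppv_c PPV cutoff in `(0, 1)`, or `NULL`.
#' @param npv_c NPV cutoff in `(0, 1)`, or `NULL`.
#' @param sn_min minimum sensitivity in `[0, 1]`, or `NULL`.
#' @param sp_min minimum specificity in `[0, 1]`, or `NULL`.
#' @return An object of class `"predictive_criteria"`.
#' @examples
#' predictive_criteria(0.05, ppv_c = 0.133, sn_min = 0.5)
#' @export
predictive_criteria <- function(prevalence, ppv_c = NULL, npv_c = NULL,
                                sn_min = NULL, sp_min = NULL) {
  check_prevalence(prevalence)
  if (is.null(ppv_c) && is.null(npv_c))
    stop("at least one of `ppv_c` and `npv_c` must be given", call. = FALSE)
  for (v in list(ppv_c = ppv_c, npv_c = npv_c)) {
    if (!is.null(v) && (v <= 0 || v >= 1))
      stop("predictive-value cutoffs must lie in (0, 1)", call. = FALSE)
  }
  for (v in list(sn_min = sn_min, sp_min = sp_min)) {
    if (!is.null(v) && (v < 0 || v > 1))
      stop("sn_min and sp_min must lie in [0, 1]", call. = FALSE)
  }
  structure(list(p = prevalence, ppv_c = ppv_c, npv_c = npv_c,
                 sn_min = sn_min, sp_min = sp_min),
            class = "predictive_criteria")
}

#' @export
print.predictive_criteria <- function(x, ...) {
  cat("Predictive criteria at prevalence p =", format(x$p), "\n")
  if (!is.null(x$ppv_c)) cat("  rule-in : PPV >=", format(x$ppv_c),
                             if (!is.null(x$sn_min)) paste(", Sn >=", format(x$sn_min)), "\n")
  if (!is.null(x$npv_c)) cat("  rule-out: NPV >=", format(x$npv_c),
                             if (!is.null(x$sp_min)) paste(", Sp >=", format(x$sp_min)), "\n")
  invisible(x)
}

#' Specificity required for a target PPV at a given sensitivity
#'
#' Rearranges Bayes' theorem: `Sp = 1 - Sn (p/(1-p)) ((1-ppv_c)/ppv_c)`.
#' The result may be negative, signalling that no specificity can achieve
#' that PPV at this sensitivity and prevalence; the value is returned
#' unclamped so infeasibility is visible.
#'
#' @param sn sensitivity in `(0, 1]`.
#' @param ppv_c target PPV in `(0, 1)`.
#' @param p prevalence in `(0, 1)`.
#' @return Required specificity (may be `< 0` when infeasible). Vectorised.
#' @examples
#' specificity_for_ppv(0.5, 0.5, 0.05)  # 0.9737
#' @export
specificity_for_ppv <- function(sn, ppv_c, p) {
  check_prob(sn, "sn"); check_prevalence(p)
  stopifnot(all(ppv_c > 0), all(ppv_c < 1))
  1 - sn * (p / (1 - p)) * ((1 - ppv_c) / ppv_c)
}

# slope (in x = 1-sp, y = sn coordinates) of the equi-PPV line through (0,0)
equi_ppv_slope <- function(ppv_c, p) ((1 - p) / p) * (ppv_c / (1 - ppv_c))
# slope of the equi-NPV line through (1,1)
equi_npv_slope <- function(npv_c, p) ((1 - p) / p) * ((1 - npv_c) / npv_c)

#' Equi-PPV and equi-NPV isolines in ROC space
#'
#' The locus of operating points achieving a fixed PPV at prevalence `p` is a
#' straight line through the origin of ROC space,
#' `Sn = (1 - Sp) ((1-p)/p) (ppv_c/(1-ppv_c))`; points above it have higher
#' PPV. The equi-NPV locus is a line through (1 - Sp = 1, Sn = 1) with slope
#' `((1-p)/p) ((1-npv_c)/npv_c)`; points above it have higher NPV. Both are
#' returned clipped to the unit square.
#'
#' @param ppv_c,npv_c the predictive-value cutoff in `(0, 1)`.
#' @param p prevalence in `(0, 1)`.
#' @return An object of class `"isoline"`: kind, slope, intercept (in
#'   `y = intercept + slope * x` form with `x = 1 - Sp`), the clipped segment
#'   endpoints, and the defining `p` and cutoff.
#' @examples
#' equi_ppv_line(0.5, 0.05)    # slope 19
#' equi_npv_line(0.988, 0.05)  # slope 0.2308
#' @export
equi_ppv_line <- function(ppv_c, p) {
  check_prevalence(p)
  stopifnot(ppv_c > 0, ppv_c < 1)
  if (ppv_c <= p)
    warning("ppv_c <= prevalence: the equi-PPV line lies on/below the chance diagonal; ",
            "the criterion is met even by a useless test", call. = FALSE)
  new_isoline("equi-PPV", slope = equi_ppv_slope(ppv_c, p), intercept = 0,
              p = p, cutoff = ppv_c)
}

#' @rdname equi_ppv_line
#' @export
equi_npv_line <- function(npv_c, p) {
  check_prevalence(p)
  stopifnot(npv_c > 0, npv_c < 1)
  if (npv_c <= 1 - p)
    warning("npv_c <= 1 - prevalence: the equi-NPV line lies on/below the chance diagonal; ",
            "the criterion is met even by a useless test", call. = FALSE)
  m <- equi_npv_slope(npv_c, p)
  new_isoline("equi-NPV", slope = m, intercept = 1 - m, p = p, cutoff = npv_c)
}

new_isoline <- function(kind, slope, intercept, p, cutoff) {
  seg <- clip_line_unit_square(slope, intercept)
  structure(list(kind = kind, slope = slope, intercept = intercept,
                 segment = seg, p = p, cutoff = cutoff),
            class = "isoline")
}

# clip y = intercept + slope*x to the unit square; returns a 2x2 matrix of
# (x, y) endpoints, or NULL if the line misses the square
clip_line_unit_square <- function(slope, intercept) {
  cand <- list(c(0, intercept),
               c(1, intercept + slope))
  if (slope != 0) {
    cand <- c(cand, list(c((0 - intercept) / slope, 0),
                         c((1 - intercept) / slope, 1)))
  }
  pts <- do.call(rbind, cand)
  eps <- 1e-12
  keep <- pts[, 1] >= -eps & pts[, 1] <= 1 + eps &
          pts[, 2] >= -eps & pts[, 2] <= 1 + eps
  pts <- unique(round(pts[keep, , drop = FALSE], 12))
  if (nrow(pts) < 2L) return(NULL)
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  rbind(pts[1L, ], pts[nrow(pts), ])
}

#' @export
print.isoline <- function(x, ...) {
  cat(sprintf("%s line at p = %s, cutoff = %s\n", x$kind,
              format(x$p), format(x$cutoff)))
  cat(sprintf("  Sn = %s + %s * (1 - Sp)\n",
              format(x$intercept, digits = 6), format(x$slope, digits = 6)))
  if (!is.null(x$segment))
    cat(sprintf("  clipped segment: (%.4f, %.4f) -- (%.4f, %.4f)\n",
                x$segment[1, 1], x$segment[1, 2],
                x$segment[2, 1], x$segment[2, 2]))
  invisible(x)
}

#' Overlay an isoline on a ROC plot
#'
#' @param x an `isoline`.
#' @param ... graphical parameters for [graphics::lines()].
#' @export
lines.isoline <- function(x, ...) {
  if (!is.null(x$segment))
    graphics::lines(x$segment[, 1], x$segment[, 2], ...)
  invisible(x)
}

# ---- half-plane constraints -------------------------------------------------
# Each constraint is a*x + b*y >= c in ROC coordinates (x = 1 - Sp, y = Sn).

criteria_constraints <- function(criteria) {
  cons <- list()
  if (!is.null(criteria$ppv_c)) {
    s <- equi_ppv_slope(criteria$ppv_c, criteria$p)
    cons <- c(cons, list(list(a = -s, b = 1, c = 0, type = "ppv",
                              label = sprintf("PPV >= %s", format(criteria$ppv_c)))))
  }
  if (!is.null(criteria$npv_c)) {
    m <- equi_npv_slope(criteria$npv_c, criteria$p)
    cons <- c(cons, list(list(a = -m, b = 1, c = 1 - m, type = "npv",
                              label = sprintf("NPV >= %s", format(criteria$npv_c)))))
  }
  if (!is.null(criteria$sn_min))
    cons <- c(cons, list(list(a = 0, b = 1, c = criteria$sn_min, type = "sn",
                              label = sprintf("Sn >= %s", format(criteria$sn_min)))))
  if (!is.null(criteria$sp_min))
    cons <- c(cons, list(list(a = -1, b = 0, c = -(1 - criteria$sp_min), type = "sp",
                              label = sprintf("Sp >= %s", format(criteria$sp_min)))))
  cons
}

# Sutherland-Hodgman clipping of a convex polygon by a*x + b*y >= c
clip_polygon_halfplane <- function(poly, a, b, c) {
  if (is.null(poly) || nrow(poly) == 0L) return(poly)
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  val <- a * poly[, 1] + b * poly[, 2] - c
  eps <- 1e-12
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- val[i]; vj <- val[j]
    if (vi >= -eps) out <- rbind(out, poly[i, ])
    if ((vi > eps && vj < -eps) || (vi < -eps && vj > eps)) {
      t <- vi / (vi - vj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  if (nrow(out) == 0L) return(out)
  unique(round(out, 12))
}

#' Success region in ROC space
#'
#' Intersects the half-planes implied by the criteria (on/above the equi-PPV
#' line, on/above the equi-NPV line, `Sn >= sn_min`, `Sp >= sp_min`, each
#' included only when present) with the unit square. All inequalities are
#' closed: an operating point on a boundary counts as compliant. The region
#' is convex and always contains the perfect-test corner (Sn 1, Sp 1), so it
#' cannot vanish entirely; under extreme criteria it collapses towards that
#' corner (the `empty` flag marks a region degenerate to fewer than three
#' vertices, i.e. without interior) — clinically, criteria that only an
#' essentially perfect test could meet.
#'
#' @param criteria a [predictive_criteria()] object.
#' @return An object of class `"success_region"` with the constraint list and
#'   the polygon `vertices` (matrix of `x = 1 - Sp`, `y = Sn`; zero rows if
#'   empty).
#' @examples
#' success_region(predictive_criteria(0.05, ppv_c = 0.5, sn_min = 0.5))
#' @export
success_region <- function(criteria) {
  stopifnot(inherits(criteria, "predictive_criteria"))
  cons <- criteria_constraints(criteria)
  poly <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  for (cn in cons) poly <- clip_polygon_halfplane(poly, cn$a, cn$b, cn$c)
  if (!is.null(poly) && nrow(poly) >= 3L) {
    ctr <- colMeans(poly)
    poly <- poly[order(atan2(poly[, 2] - ctr[2], poly[, 1] - ctr[1])), , drop = FALSE]
  }
  structure(list(criteria = criteria, constraints = cons,
                 vertices = poly, empty = is.null(poly) || nrow(poly) < 3L),
            class = "success_region")
}

#' @export
print.success_region <- function(x, ...) {
  cat("Success region:",
      paste(vapply(x$constraints, `[[`, "", "label"), collapse = " & "),
      sprintf("at p = %s\n", format(x$criteria$p)))
  if (x$empty) {
    cat("  empty: no operating point can satisfy all criteria simultaneously\n")
  } else {
    cat("  polygon vertices (x = 1 - Sp, y = Sn):\n")
    v <- round(x$vertices, 4)
    colnames(v) <- c("fpr", "sn")
    print(v)
  }
  invisible(x)
}

#' Shade a success region on a ROC plot
#'
#' @param x a `success_region`.
#' @param add logical; add to an existing plot (default) or open a new one.
#' @param col fill colour.
#' @param border border colour.
#' @param ... further parameters for [graphics::polygon()].
#' @export
plot.success_region <- function(x, add = TRUE,
                                col = grDevices::adjustcolor("darkgreen", 0.25),
                                border = "darkgreen", ...) {
  if (!add) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), asp = 1,
                   xlab = "1 - specificity (FPR)", ylab = "Sensitivity")
    graphics::abline(0, 1, col = "grey70", lty = 3)
  }
  if (!x$empty)
    graphics::polygon(x$vertices[, 1], x$vertices[, 2],
                      col = col, border = border, ...)
  invisible(x)
}

# feasible t-interval(s) of one curve segment under all constraints;
# returns c(lo, hi) or NULL
segment_feasible_interval <- function(p0, p1, cons) {
  lo <- 0; hi <- 1
  for (cn in cons) {
    g0 <- cn$a * p0[1] + cn$b * p0[2] - cn$c
    g1 <- cn$a * p1[1] + cn$b * p1[2] - cn$c
    eps <- 1e-12
    if (abs(g1 - g0) < eps) {
      if (g0 < -eps) return(NULL)
    } else {
      t_cross <- g0 / (g0 - g1)
      if (g1 > g0) lo <- max(lo, t_cross) else hi <- min(hi, t_cross)
    }
    if (lo > hi + eps) return(NULL)
  }
  c(max(0, min(1, lo)), max(0, min(1, hi)))
}

#' Test a ROC curve against predictive-value criteria
#'
#' Decides whether the (interpolated piecewise-linear) ROC curve enters the
#' success region defined by the criteria: the test complies when at least
#' one point of the curve satisfies all constraints simultaneously
#' (closed inequalities). Crossing points with the constraint boundaries are
#' found analytically as segment-line intersections. When both a PPV and an
#' NPV cutoff are given, each criterion is additionally evaluated alone,
#' supporting a split rule-in / rule-out strategy.
#'
#' @param curve a [roc_curve()].
#' @param criteria a [predictive_criteria()].
#' @param interpolate logical; if `FALSE`, only empirical operating points
#'   (curve vertices) are eligible, not interpolated ones.
#' @return An object of class `"compliance_report"`: `meets` plus the
#'   compliant sensitivity/specificity interval, the curve's maximal PPV and
#'   NPV at the stated prevalence, and per-criterion verdicts.
#' @examples
#' fit <- roc_curve(c(1, 4, 3, 5), c(0, 0, 1, 1))
#' roc_meets_criteria(fit, predictive_criteria(0.05, ppv_c = 0.133, sn_min = 0.5))
#' @export
roc_meets_criteria <- function(curve, criteria, interpolate = TRUE) {
  stopifnot(inherits(curve, "roc_curve"),
            inherits(criteria, "predictive_criteria"))
  region <- success_region(criteria)
  res <- curve_region_intervals(curve$points$fpr, curve$points$sn,
                                region$constraints, interpolate)
  p <- criteria$p
  verts_ok <- curve$points$sn > 0 | curve$points$fpr > 0
  best_ppv <- max(ppv(curve$points$sn[verts_ok],
                      curve$points$sp[verts_ok], p))
  best_npv <- max(npv(curve$points$sn[curve$points$sn < 1 | curve$points$sp > 0],
                      curve$points$sp[curve$points$sn < 1 | curve$points$sp > 0], p))
  each <- list()
  if (!is.null(criteria$ppv_c) && !is.null(criteria$npv_c)) {
    crit_in <- predictive_criteria(p, ppv_c = criteria$ppv_c,
                                   sn_min = criteria$sn_min)
    crit_out <- predictive_criteria(p, npv_c = criteria$npv_c,
                                    sp_min = criteria$sp_min)
    each$rule_in <- curve_region_intervals(curve$points$fpr, curve$points$sn,
                                           criteria_constraints(crit_in),
                                           interpolate)$meets
    each$rule_out <- curve_region_intervals(curve$points$fpr, curve$points$sn,
                                            criteria_constraints(crit_out),
                                            interpolate)$meets
  }
  structure(list(meets = res$meets, criteria = criteria, region = region,
                 intervals = res$intervals, crossings = res$crossings,
                 best_ppv = best_ppv, best_npv = best_npv,
                 each_criterion = each, interpolate = interpolate),
            class = "compliance_report")
}

# shared engine: feasible sub-segments of a polyline under half-plane
# constraints. Returns meets flag, compliant (fpr, sn) intervals and the
# entry/exit crossing points. The corners (0,0) and (1,1) lie on every
# equi-PPV resp. equi-NPV line but have no test positives resp. negatives,
# so a PPV (NPV) criterion cannot be certified there: feasible sets that
# degenerate to such a corner do not count as compliance.
curve_region_intervals <- function(fpr, sn, cons, interpolate = TRUE) {
  has_ppv <- any(vapply(cons, function(cn) identical(cn$type, "ppv"), logical(1)))
  has_npv <- any(vapply(cons, function(cn) identical(cn$type, "npv"), logical(1)))
  eps <- 1e-12
  excluded <- function(pt) {
    (has_ppv && abs(pt[1]) < eps && abs(pt[2]) < eps) ||
    (has_npv && abs(pt[1] - 1) < eps && abs(pt[2] - 1) < eps)
  }
  if (!interpolate) {
    ok <- rep(TRUE, length(fpr))
    for (cn in cons)
      ok <- ok & (cn$a * fpr + cn$b * sn - cn$c >= -eps)
    ok <- ok & !vapply(seq_along(fpr),
                       function(i) excluded(c(fpr[i], sn[i])), logical(1))
    pts <- cbind(fpr = fpr[ok], sn = sn[ok])
    return(list(meets = any(ok),
                intervals = if (any(ok)) pts else NULL,
                crossings = NULL))
  }
  intervals <- list()
  for (i in seq_len(length(fpr) - 1L)) {
    p0 <- c(fpr[i], sn[i]); p1 <- c(fpr[i + 1L], sn[i + 1L])
    tt <- segment_feasible_interval(p0, p1, cons)
    if (!is.null(tt)) {
      a <- p0 + tt[1] * (p1 - p0)
      b <- p0 + tt[2] * (p1 - p0)
      if (sum(abs(b - a)) < eps && excluded(a)) next
      intervals[[length(intervals) + 1L]] <- rbind(a, b)
    }
  }
  if (length(intervals) == 0L)
    return(list(meets = FALSE, intervals = NULL, crossings = NULL))
  # merge contiguous sub-segments into maximal compliant runs, so the report
  # shows one entry/exit pair per excursion into the region
  merged <- list(intervals[[1L]])
  for (m in intervals[-1L]) {
    last <- merged[[length(merged)]]
    if (sum(abs(last[2L, ] - m[1L, ])) < 1e-9)
      merged[[length(merged)]][2L, ] <- m[2L, ]
    else merged[[length(merged) + 1L]] <- m
  }
  ends <- do.call(rbind, lapply(merged, function(m)
    c(m[1, 1], m[1, 2], m[2, 1], m[2, 2])))
  crossings <- data.frame(fpr_in = ends[, 1], sn_in = ends[, 2],
                          fpr_out = ends[, 3], sn_out = ends[, 4])
  list(meets = TRUE, intervals = merged, crossings = crossings)
}

#' @export
print.compliance_report <- function(x, ...) {
  verdict <- if (x$meets) "COMPLIANT" else "NON-COMPLIANT"
  cat(sprintf("ROC compliance: %s (p = %s)\n", verdict, format(x$criteria$p)))
  for (cn in x$region$constraints) cat("  criterion:", cn$label, "\n")
  cat(sprintf("  best achievable PPV = %.3f, NPV = %.3f at this prevalence\n",
              report_round(x$best_ppv), report_round(x$best_npv)))
  if (x$meets && !is.null(x$crossings)) {
    cat("  compliant curve section(s), (fpr, sn) from -> to:\n")
    print(round(x$crossings, 4), row.names = FALSE)
  }
  if (length(x$each_criterion)) {
    cat(sprintf("  rule-in alone: %s; rule-out alone: %s\n",
                ifelse(x$each_criterion$rule_in, "compliant", "non-compliant"),
                ifelse(x$each_criterion$rule_out, "compliant", "non-compliant")))
  }
  invisible(x)
}

#' Least demanding operating point for joint likelihood-ratio bounds
#'
#' Solves `Sn = lr_pos_min (1 - Sp)` together with `Sn = 1 - lr_neg_max Sp`
#' for the unique operating point at which a test attains both a positive
#' likelihood ratio of `lr_pos_min` and a negative likelihood ratio of
#' `lr_neg_max` simultaneously. A published pre-eclampsia screening
#' requirement of LR+ > 10 and LR- < 0.2 corresponds to Sn 0.82, Sp 0.92.
#'
#' @param lr_pos_min required positive likelihood ratio, `> 1`.
#' @param lr_neg_max allowed negative likelihood ratio, in `(0, 1)`.
#' @return List with `sn`, `sp` (classed `"operating_point"`).
#' @examples
#' lr_to_min_operating_point(10, 0.2)
#' @export
lr_to_min_operating_point <- function(lr_pos_min, lr_neg_max) {
  stopifnot(lr_pos_min > 1, lr_neg_max > 0, lr_neg_max < 1)
  sp <- (lr_pos_min - 1) / (lr_pos_min - lr_neg_max)
  sn <- lr_pos_min * (1 - sp)
  if (sp < 0 || sp > 1 || sn < 0 || sn > 1)
    stop("infeasible likelihood-ratio criteria: no operating point in the unit square",
         call. = FALSE)
  structure(list(sn = sn, sp = sp), class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Operating point: Sn = %.4f, Sp = %.4f\n", x$sn, x$sp))
  invisible(x)
}

#' Minimum AUROC of a concave ROC curve through an operating point
#'
#' The least area any concave ROC curve passing through `(sn, sp)` can have
#' is attained by the two-segment curve (0,0) -> (1-sp, sn) -> (1,1), whose
#' trapezoidal area is `(sn + sp) / 2`.
#'
#' @param pt a list with `sn` and `sp` (e.g. from
#'   [lr_to_min_operating_point()]), on or above the chance diagonal.
#' @return The minimal AUROC.
#' @examples
#' min_auroc_through_point(lr_to_min_operating_point(10, 0.2))  # 0.8673
#' @export
min_auroc_through_point <- function(pt) {
  sn <- pt$sn; sp <- pt$sp
  check_prob(sn, "sn"); check_prob(sp, "sp")
  if (sn < 1 - sp)
    stop("operating point lies below the chance diagonal", call. = FALSE)
  (sn + sp) / 2
}
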