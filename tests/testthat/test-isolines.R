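test_that("specificity_for_ppv rearranges Bayes' theorem and flags infeasibility", {
  expect_equal(specificity_for_ppv(0.5, 0.5, 0.05),
               1 - 0.5 * (0.05 / 0.95), tolerance = 1e-12)
  expect_equal(round(specificity_for_ppv(0.5, 0.5, 0.05), 4), 0.9737)
  expect_equal(specificity_for_ppv(1e-9, 0.5, 0.05), 1, tolerance = 1e-8)
  expect_equal(specificity_for_ppv(1, 0.5, 0.5), 0)
  # demanding PPV at high prevalence-to-cutoff ratio can be infeasible:
  # the required specificity goes negative and is not clamped
  expect_lt(specificity_for_ppv(1, 0.1, 0.6), 0)
})

test_that("equi-PPV line passes through the origin with the Bayes slope", {
  l <- equi_ppv_line(0.5, 0.05)
  expect_equal(l$slope, 19)
  expect_equal(l$intercept, 0)
  expect_equal(l$segment[1, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(l$segment[2, ], c(1 / 19, 1), ignore_attr = TRUE,
               tolerance = 1e-9)

  expect_warning(ld <- equi_ppv_line(0.5, 0.5), "useless test")
  expect_equal(ld$slope, 1)  # the chance diagonal

  l2 <- equi_ppv_line(0.133, 0.05)
  expect_equal(l2$slope, (0.95 / 0.05) * (0.133 / 0.867), tolerance = 1e-12)
  expect_equal(l2$slope, 2.915, tolerance = 1e-3)
})

test_that("equi-NPV line passes through (1, 1) with the Bayes slope", {
  expect_warning(ld <- equi_npv_line(0.95, 0.05), "useless test")
  expect_equal(ld$slope, 1)
  expect_equal(ld$intercept, 0)

  l <- equi_npv_line(0.988, 0.05)
  expect_equal(l$slope, (0.95 / 0.05) * (0.012 / 0.988), tolerance = 1e-12)
  expect_equal(l$slope, 0.2308, tolerance = 1e-3)
  expect_equal(l$intercept + l$slope, 1, tolerance = 1e-12)  # through (1,1)
  expect_equal(l$intercept, 0.769, tolerance = 1e-3)         # Sn at Sp = 1

  l_hi <- equi_npv_line(1 - 1e-9, 0.05)
  expect_equal(l_hi$intercept, 1, tolerance = 1e-6)  # limit: horizontal Sn = 1
})

test_that("points above an isoline exceed the cutoff, points below fall short", {
  # dense-grid sign agreement between the line geometry and Bayes' theorem
  sn_grid <- seq(0.01, 0.99, length.out = 60)
  sp_grid <- seq(0.01, 0.99, length.out = 60)
  g <- expand.grid(sn = sn_grid, sp = sp_grid)
  for (p in c(0.05, 0.2)) {
    for (cutoff in c(0.133, 0.5)) {
      l <- suppressWarnings(equi_ppv_line(cutoff, p))
      side <- g$sn - l$slope * (1 - g$sp)
      diff_ppv <- ppv(g$sn, g$sp, p) - cutoff
      expect_true(all(sign(side[abs(side) > 1e-9]) ==
                      sign(diff_ppv[abs(side) > 1e-9])))
      # and points exactly on the line hit the cutoff to machine precision
      sp_on <- specificity_for_ppv(sn_grid, cutoff, p)
      ok <- sp_on >= 0 & sp_on <= 1
      expect_equal(ppv(sn_grid[ok], sp_on[ok], p), rep(cutoff, sum(ok)),
                   tolerance = 1e-12)
    }
    for (cutoff in c(0.9, 0.988)) {
      l <- suppressWarnings(equi_npv_line(cutoff, p))
      side <- g$sn - (l$intercept + l$slope * (1 - g$sp))
      diff_npv <- npv(g$sn, g$sp, p) - cutoff
      expect_true(all(sign(side[abs(side) > 1e-9]) ==
                      sign(diff_npv[abs(side) > 1e-9])))
    }
  }
})

test_that("equi-PPV slope falls as prevalence rises", {
  slopes <- vapply(c(0.05, 0.10, 0.20),
                   function(p) equi_ppv_line(0.5, p)$slope, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("success region is the clipped intersection of the criteria half-planes", {
  r <- success_region(predictive_criteria(0.05, ppv_c = 0.5, sn_min = 0.5))
  expect_false(r$empty)
  # vertex where the equi-PPV line meets Sn = 0.5
  expect_true(any(abs(r$vertices[, 1] - 0.5 / 19) < 1e-9 &
                  abs(r$vertices[, 2] - 0.5) < 1e-9))
  # every vertex satisfies every constraint (closed inequalities)
  for (cn in r$constraints) {
    expect_true(all(cn$a * r$vertices[, 1] + cn$b * r$vertices[, 2]
                    >= cn$c - 1e-9))
  }

  # cutoff equal to prevalence: region is the whole upper triangle
  r2 <- suppressWarnings(success_region(predictive_criteria(0.3, ppv_c = 0.3)))
  expect_false(r2$empty)
  expect_equal(sort(round(r2$vertices[, 1] + r2$vertices[, 2], 9)),
               c(0, 1, 2))  # vertices (0,0), (0,1), (1,1)

  # the paper-style joint rule-in + rule-out wedge near the top-left corner
  r3 <- success_region(predictive_criteria(0.05, ppv_c = 0.133, npv_c = 0.988))
  expect_false(r3$empty)
  expect_true(all(r3$vertices[, 2] >= 0.7))   # wedge sits high ...
  expect_true(all(r3$vertices[, 1] <= 0.35))  # ... and left

  # extreme criteria collapse the region to a sliver at the perfect corner
  # (the corner (0, 1) satisfies every criterion, so the region never
  # vanishes entirely)
  r4 <- success_region(predictive_criteria(0.01, ppv_c = 0.9, sn_min = 0.9,
                                           sp_min = 0.5))
  expect_false(r4$empty)
  expect_true(all(r4$vertices[, 1] <= 1 / equi_ppv_line(0.9, 0.01)$slope + 1e-9))
  expect_true(all(r4$vertices[, 2] >= 0.9))
  # criteria only the perfect test meets: degenerate single-vertex region
  r5 <- success_region(predictive_criteria(0.05, ppv_c = 0.5, sn_min = 1,
                                           sp_min = 1))
  expect_true(r5$empty)
})

test_that("region convexity: midpoints of vertices satisfy all constraints", {
  set.seed(51)
  for (i in 1:20) {
    crit <- predictive_criteria(runif(1, 0.02, 0.3),
                                ppv_c = runif(1, 0.1, 0.9),
                                npv_c = runif(1, 0.7, 0.999),
                                sn_min = runif(1, 0, 0.8))
    r <- suppressWarnings(success_region(crit))
    if (r$empty) next
    v <- r$vertices
    mid <- (v[sample(nrow(v), 1), ] + v[sample(nrow(v), 1), ]) / 2
    for (cn in r$constraints)
      expect_true(cn$a * mid[1] + cn$b * mid[2] >= cn$c - 1e-9)
  }
})

test_that("ROC compliance is decided on the interpolated curve", {
  perfect <- roc_curve(labeled_scores(c(1, 2, 10, 11), c(0, 0, 1, 1)))
  crit <- predictive_criteria(0.05, ppv_c = 0.9, npv_c = 0.99)
  expect_true(roc_meets_criteria(perfect, crit)$meets)

  diag_curve <- roc_curve(labeled_scores(c(2, 2, 2, 2), c(0, 1, 0, 1)))
  expect_false(roc_meets_criteria(diag_curve,
                                  predictive_criteria(0.05, ppv_c = 0.3))$meets)

  # steep-early curve vs the rule-in criteria: compliant via its (0.02, 0.55)
  # vertex, where direct Bayes evaluation gives PPV ~ 0.591
  steep <- structure(list(points = data.frame(
    threshold = c(Inf, 2, 1), sn = c(0, 0.55, 1),
    sp = c(1, 0.98, 0), fpr = c(0, 0.02, 1))), class = "roc_curve")
  rep1 <- roc_meets_criteria(steep,
                             predictive_criteria(0.05, ppv_c = 0.133,
                                                 sn_min = 0.5))
  expect_true(rep1$meets)
  expect_equal(ppv(0.55, 0.98, 0.05), 0.5914, tolerance = 1e-3)
  expect_gte(rep1$best_ppv, 0.591)

  # a curve compliant only through an interpolated point: vertex-only mode
  # must then disagree. At p = 0.2, ppv_c = 0.5 the equi-PPV slope is 4; the
  # segment (0, 0.2) -> (0.3, 0.95) crosses the region but neither endpoint
  # satisfies both PPV >= 0.5 and Sn >= 0.3.
  v_curve <- structure(list(points = data.frame(
    threshold = c(Inf, 3, 2, 1), sn = c(0, 0.2, 0.95, 1),
    sp = c(1, 1, 0.7, 0), fpr = c(0, 0, 0.3, 1))), class = "roc_curve")
  crit2 <- predictive_criteria(0.2, ppv_c = 0.5, sn_min = 0.3)
  rep_interp <- roc_meets_criteria(v_curve, crit2, interpolate = TRUE)
  rep_vertex <- roc_meets_criteria(v_curve, crit2, interpolate = FALSE)
  expect_true(rep_interp$meets)
  expect_false(rep_vertex$meets)
})

test_that("compliance is invariant to refining the curve with collinear points", {
  set.seed(61)
  for (i in 1:10) {
    d <- random_tied_data(40)
    fit <- roc_curve(d)
    crit <- predictive_criteria(0.1, ppv_c = runif(1, 0.15, 0.6),
                                sn_min = runif(1, 0, 0.6))
    base <- roc_meets_criteria(fit, crit)$meets
    # insert midpoints of every segment (collinear refinement)
    pts <- fit$points
    n <- nrow(pts)
    mid <- data.frame(threshold = NA,
                      sn = (pts$sn[-n] + pts$sn[-1]) / 2,
                      sp = (pts$sp[-n] + pts$sp[-1]) / 2,
                      fpr = (pts$fpr[-n] + pts$fpr[-1]) / 2)
    refined <- rbind(pts, mid)
    refined <- refined[order(refined$fpr, refined$sn), ]
    fit2 <- structure(list(points = refined), class = "roc_curve")
    expect_identical(roc_meets_criteria(fit2, crit)$meets, base)
  }
})

test_that("joint likelihood-ratio bounds solve to the published operating point", {
  pt <- lr_to_min_operating_point(10, 0.2)
  expect_equal(round(pt$sn, 2), 0.82)
  expect_equal(round(pt$sp, 2), 0.92)
  # the point indeed attains both ratios
  lr <- likelihood_ratios(pt$sn, pt$sp)
  expect_equal(lr$lr_pos, 10, tolerance = 1e-12)
  expect_equal(lr$lr_neg, 0.2, tolerance = 1e-12)

  pt2 <- lr_to_min_operating_point(2, 0.5)
  expect_equal(pt2$sp, 2 / 3, tolerance = 1e-12)
  expect_equal(pt2$sn, 2 / 3, tolerance = 1e-12)

  pt3 <- lr_to_min_operating_point(1 + 1e-6, 1 - 1e-6)
  expect_equal(pt3$sn, 1 - pt3$sp, tolerance = 1e-3)  # approaches the diagonal
})

test_that("minimal AUROC through a point is (sn + sp)/2 and a true lower bound", {
  pt <- lr_to_min_operating_point(10, 0.2)
  expect_equal(round(min_auroc_through_point(pt), 2), 0.87)
  expect_equal(min_auroc_through_point(list(sn = 1, sp = 1)), 1)
  expect_equal(min_auroc_through_point(list(sn = 0.5, sp = 0.5)), 0.5)
  expect_error(min_auroc_through_point(list(sn = 0.2, sp = 0.5)),
               "below the chance diagonal")

  # the two-segment envelope itself has exactly this area
  expect_equal(auroc_trapezoid(c(0, 1 - pt$sp, 1), c(0, pt$sn, 1)),
               min_auroc_through_point(pt), tolerance = 1e-12)

  # no concave curve through the point does better than the bound
  set.seed(71)
  for (i in 1:50) {
    x0 <- runif(1, 0.05, 0.6)
    y0 <- runif(1, x0 + 0.05, 1)
    cur <- random_concave_curve_through(x0, y0)
    expect_gte(auroc_trapezoid(cur$fpr, cur$sn) + 1e-12,
               min_auroc_through_point(list(sn = y0, sp = 1 - x0)))
  }
})
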