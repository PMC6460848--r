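test_that("confusion matrices count the sample correctly at any threshold", {
  d <- tiny_data()
  cm <- confusion_at_threshold(d, 3)
  expect_equal(list(cm$tp, cm$fp, cm$tn, cm$fn), list(2L, 1L, 1L, 0L))
  # everything positive / everything negative at the infinite thresholds
  lo <- confusion_at_threshold(d, -Inf)
  expect_equal(c(lo$tp, lo$fp, lo$tn, lo$fn), c(2L, 2L, 0L, 0L))
  hi <- confusion_at_threshold(d, Inf)
  expect_equal(c(hi$tp, hi$fp, hi$tn, hi$fn), c(0L, 0L, 2L, 2L))
  # counts always partition the sample
  for (t in c(-1, 1, 2.5, 4, 6)) {
    cm <- confusion_at_threshold(d, t)
    expect_identical(cm$tp + cm$fp + cm$tn + cm$fn, 4L)
    expect_identical(cm$tp + cm$fn, 2L)  # cases
    expect_identical(cm$tn + cm$fp, 2L)  # controls
  }
})

test_that("sensitivity and specificity are the class-conditional rates", {
  expect_equal(sensitivity(list(tp = 2, fn = 0)), 1)
  expect_equal(sensitivity(list(tp = 1, fn = 1)), 0.5)
  expect_equal(sensitivity(list(tp = 58, fn = 42)), 0.58)
  expect_equal(specificity(list(tn = 9, fp = 1, tp = 0, fn = 0)), 0.9)
  expect_equal(specificity(list(tn = 0, fp = 5)), 0)
  expect_equal(specificity(list(tn = 3, fp = 3)), 0.5)
  expect_error(sensitivity(list(tp = 0, fn = 0)), "no cases")
  expect_error(specificity(list(tn = 0, fp = 0)), "no controls")
})

test_that("labelled-score validation rejects malformed input", {
  expect_error(labeled_scores(1:3, c(0, 1)), "equal length")
  expect_error(labeled_scores(c(1, 2), c(0, 0)), "at least one case")
  expect_error(labeled_scores(c(1, 2), c(2, 0)), "only 0 and 1")
  expect_error(labeled_scores(c(1, NA), c(0, 1)), "missing")
})

test_that("empirical ROC curve has the required endpoints, ordering and AUROC", {
  fit <- roc_curve(tiny_data())
  pts <- fit$points
  expect_equal(c(pts$sn[1], pts$sp[1]), c(0, 1))
  expect_equal(c(pts$sn[nrow(pts)], pts$sp[nrow(pts)]), c(1, 0))
  expect_true(all(diff(pts$sn) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$threshold) <= 0))
  expect_equal(fit$auc, 0.75)
  expect_equal(fit$auc, pair_count_auroc(tiny_data()))

  # perfect separation reaches the top-left corner
  perfect <- labeled_scores(c(1, 2, 10, 11), c(0, 0, 1, 1))
  pfit <- roc_curve(perfect)
  expect_equal(auc(pfit), 1)
  expect_true(any(pfit$points$fpr == 0 & pfit$points$sn == 1))

  # all-identical scores give the diagonal chord, AUROC 0.5
  flat <- roc_curve(labeled_scores(c(2, 2, 2, 2), c(0, 1, 0, 1)))
  expect_equal(flat$auc, 0.5)
  expect_equal(nrow(flat$points), 2L)
})

test_that("formula and default interfaces agree with the labelled-scores method", {
  df <- data.frame(score = c(1, 4, 3, 5), label = c(0, 0, 1, 1))
  f1 <- roc_curve(label ~ score, data = df)
  f2 <- roc_curve(df$score, df$label)
  f3 <- roc_curve(tiny_data())
  expect_equal(f1$points, f3$points)
  expect_equal(f2$points, f3$points)
})

test_that("trapezoid and rank AUROC agree exactly, including ties", {
  expect_equal(auroc_trapezoid(c(0, 1), c(0, 1)), 0.5)
  expect_equal(auroc_trapezoid(c(0, 0, 1), c(0, 1, 1)), 1)
  expect_equal(auroc_trapezoid(c(0, 0.0816, 1), c(0, 0.8163, 1)), 0.8673,
               tolerance = 1e-4)

  expect_equal(auroc_rank(tiny_data()), 0.75)
  expect_equal(auroc_rank(labeled_scores(c(2, 2, 2, 2), c(1, 1, 0, 0))), 0.5)
  expect_equal(auroc_rank(labeled_scores(c(10, 11, 1, 2), c(1, 1, 0, 0))), 1)

  # the module's central oracle equivalence, on many tied datasets
  set.seed(11)
  for (i in 1:200) {
    d <- random_tied_data(sample(4:40, 1L), max_score = sample(3:12, 1L))
    a_rank <- auroc_rank(d)
    a_trap <- roc_curve(d)$auc
    expect_equal(a_rank, a_trap, tolerance = 1e-12)
    expect_equal(a_rank, pair_count_auroc(d), tolerance = 1e-12)
  }
})

test_that("AUROC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:20) {
    d <- random_tied_data(60, max_score = 8L)
    ref <- as.numeric(pROC::auc(pROC::roc(d$label, d$score, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_curve(d)$auc, ref, tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under monotone transforms and flips with labels", {
  set.seed(31)
  for (i in 1:50) {
    d <- random_tied_data(30)
    a <- auroc_rank(d)
    expect_equal(auroc_rank(labeled_scores(exp(d$score / 3), d$label)), a)
    expect_equal(auroc_rank(labeled_scores(d$score^3, d$label)), a)
    expect_equal(auroc_rank(labeled_scores(d$score, 1L - d$label)), 1 - a)
  }
})

test_that("sensitivity at specificity interpolates linearly on the curve", {
  perfect <- roc_curve(labeled_scores(c(1, 2, 10, 11), c(0, 0, 1, 1)))
  expect_equal(sensitivity_at_specificity(perfect, 0.9), 1)

  diag_curve <- roc_curve(labeled_scores(c(2, 2, 2, 2), c(0, 1, 0, 1)))
  expect_equal(sensitivity_at_specificity(diag_curve, 0.9), 0.1)

  # hand-interpolated value on the curve (0,0)-(0.05,0.6)-(1,1)
  fake <- structure(list(points = data.frame(threshold = c(Inf, 1, 0),
                                             sn = c(0, 0.6, 1),
                                             sp = c(1, 0.95, 0),
                                             fpr = c(0, 0.05, 1))),
                    class = "roc_curve")
  expect_equal(sensitivity_at_specificity(fake, 0.9),
               0.6 + (0.1 - 0.05) / (1 - 0.05) * 0.4, tolerance = 1e-12)

  # endpoint conventions: best sensitivity at sp = 1; everything at sp = 0
  fit <- roc_curve(tiny_data())
  expect_equal(sensitivity_at_specificity(fit, 1), 0.5)
  expect_equal(sensitivity_at_specificity(fit, 0), 1)
})

test_that("score CSV/TSV round-trips through read_scores and write_roc", {
  d <- tiny_data()
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(d), csv, row.names = FALSE)
  expect_equal(as.data.frame(read_scores(csv)), as.data.frame(d))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(d), tsv, sep = "\t", row.names = FALSE)
  expect_equal(as.data.frame(read_scores(tsv)), as.data.frame(d))

  # rows with missing values are dropped with a message
  df <- rbind(as.data.frame(d), data.frame(score = NA, label = 1))
  utils::write.csv(df, csv, row.names = FALSE)
  expect_message(d2 <- read_scores(csv), "1 row")
  expect_equal(nrow(d2), 4L)

  out <- withr::local_tempfile(fileext = ".csv")
  write_roc(roc_curve(d), out)
  back <- utils::read.csv(out)
  expect_equal(back$sn, roc_curve(d)$points$sn)
})
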