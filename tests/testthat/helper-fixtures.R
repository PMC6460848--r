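# Shared fixtures and independent oracles used across test files.

# four-subject textbook example: cases score {3, 5}, controls {1, 4}
tiny_data <- function() labeled_scores(c(1, 4, 3, 5), c(0, 0, 1, 1))

# brute-force pair-counting AUROC: fraction of (case, control) pairs with the
# case ranked higher, ties counted one half. Independent of the package's
# rank/trapezoid implementations.
pair_count_auroc <- function(data) {
  cases <- data$score[data$label == 1]
  controls <- data$score[data$label == 0]
  total <- 0
  for (ca in cases) {
    total <- total + sum(ca > controls) + 0.5 * sum(ca == controls)
  }
  total / (length(cases) * length(controls))
}

# random labelled scores with ties (integer-valued scores)
random_tied_data <- function(n, max_score = 10L) {
  repeat {
    label <- rbinom(n, 1L, 0.5)
    if (sum(label) > 0 && sum(label) < n) break
  }
  labeled_scores(sample.int(max_score, n, replace = TRUE), label)
}

# upper concave hull (Andrew's monotone chain, upper chain only) of a point
# set; endpoints in x are always retained
upper_hull <- function(x, y) {
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  h <- list()
  for (i in seq_along(x)) {
    while (length(h) >= 2L) {
      a <- h[[length(h) - 1L]]; b <- h[[length(h)]]
      cr <- (b[1] - a[1]) * (y[i] - a[2]) - (b[2] - a[2]) * (x[i] - a[1])
      if (cr >= 0) h[[length(h)]] <- NULL else break
    }
    h[[length(h) + 1L]] <- c(x[i], y[i])
  }
  do.call(rbind, h)
}

# a random concave-on-each-side piecewise-linear ROC curve that passes
# exactly through (x0, y0): upper concave hulls of random points on either
# side of the operating point. Returns list(fpr, sn).
random_concave_curve_through <- function(x0, y0, k = 6L) {
  left <- upper_hull(c(0, x0, runif(k, 0, x0)),
                     c(0, y0, runif(k, 0, y0)))
  right <- upper_hull(c(x0, 1, runif(k, x0, 1)),
                      c(y0, 1, runif(k, y0, 1)))
  pts <- rbind(left, right[-1L, , drop = FALSE])
  list(fpr = pts[, 1], sn = pts[, 2])
}

expect_json_number <- function(x) {
  expect_true(is.numeric(x) && length(x) == 1L && is.finite(x))
}
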