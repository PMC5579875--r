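gauss_classes <- function(n_per = 15, gap = 8, p = 4, seed = 2) {
  set.seed(seed)
  y <- rep(1:3, each = n_per)
  x <- matrix(rnorm(3 * n_per * p), ncol = p)
  x[, 1] <- x[, 1] + gap * y
  list(x = x, y = y)
}

test_that("the exponent grid contains the conventional reported optima", {
  vals <- 2^svm_exponent_grid()
  for (v in c(256, 3.0314, 9.1896, 48.5029, 84.4485, 147.0334)) {
    expect_lt(min(abs(vals - v)), 1e-3)
  }
  expect_length(vals, 21)
})

test_that("well-separated classes reach 100% calibration accuracy", {
  g <- gauss_classes()
  m <- train_svm_grid(g$x, g$y, cost_exponents = seq(-2, 8, 2),
                      gamma_exponents = seq(-8, 0, 2), folds = 3)
  expect_equal(evaluate(m, g$x, g$y)$accuracy, 100)
})

test_that("the SVM grid search is deterministic under a fixed seed", {
  g <- gauss_classes(gap = 1.5)
  m1 <- train_svm_grid(g$x, g$y, cost_exponents = seq(0, 4, 2),
                       gamma_exponents = seq(-6, -2, 2), folds = 4, seed = 9)
  m2 <- train_svm_grid(g$x, g$y, cost_exponents = seq(0, 4, 2),
                       gamma_exponents = seq(-6, -2, 2), folds = 4, seed = 9)
  expect_identical(c(m1$cost, m1$gamma), c(m2$cost, m2$gamma))
  expect_identical(predict(m1, g$x), predict(m2, g$x))
})

test_that("the RF grid clamps and deduplicates the feature counts", {
  g <- gauss_classes(p = 15)
  m <- train_rf_grid(g$x, g$y, num_trees = c(50, 100),
                     mtry = seq(10, 100, 10), reps = 2, seed = 3)
  expect_true(m$mtry %in% c(10, 15))
})

test_that("a perfectly separating band gives the tie-break winner", {
  set.seed(4)
  y <- rep(1:3, each = 20)
  x <- matrix(rnorm(60 * 5, 0, 0.01), ncol = 5)
  x[, 3] <- y  # single band separates perfectly
  m <- train_rf_grid(x, y, num_trees = seq(50, 200, 50), mtry = c(2, 4),
                     reps = 3, seed = 5)
  expect_equal(m$oob_error, 0)
  expect_equal(m$num_trees, 50)   # fewest trees among the zero-error combos
  expect_equal(m$mtry, 2)
})

test_that("evaluation reproduces published totals from raw confusion counts", {
  ref <- reference_confusions()
  expect_equal(overall_accuracy(ref$intact.svm.calibration$confusion), 96.40)
  expect_equal(overall_accuracy(ref$sliced.svm.calibration$confusion), 85.29)
  expect_equal(overall_accuracy(diag(c(13, 13, 13))), 100.00)
})

test_that("evaluate builds the 3x3 confusion with true grades as rows", {
  g <- gauss_classes()
  m <- train_rf_grid(g$x, g$y, num_trees = 50, mtry = 3, reps = 1)
  ev <- evaluate(m, g$x, g$y)
  expect_equal(dim(ev$confusion), c(3, 3))
  expect_equal(unname(rowSums(ev$confusion)), rep(15, 3))
  expect_equal(ev$accuracy,
               round_half_up(100 * sum(diag(ev$confusion)) / 45, 2))
})

test_that("labels outside the trained classes are rejected", {
  g <- gauss_classes()
  m <- train_rf_grid(g$x[g$y != 3, ], g$y[g$y != 3], num_trees = 50,
                     mtry = 3, reps = 1)
  expect_error(evaluate(m, g$x, g$y), "not trained")
  expect_error(evaluate(m, g$x, g$y + 2), "lie in")
})

test_that("half-up rounding follows the reporting convention", {
  expect_equal(round_half_up(0.96396 * 100, 2), 96.40)
  expect_equal(round_half_up(0.73504 * 100, 2), 73.50)
  expect_equal(round_half_up(0.125, 2), 0.13)    # exact half rounds up
  expect_equal(round(0.125, 2), 0.12)            # unlike banker's rounding
})
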