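# Grid-tuned graders: RBF support vector machine and random forest. Both
# return a classed "grade_model" so that downstream evaluation and the
# pipeline treat them uniformly.

#' Exponent grid used for the SVM search
#'
#' Both the penalty coefficient C and the kernel width gamma are searched
#' over `2^e` with `e` running from -8 to 8 in steps of 0.8 (21 values
#' each), which contains the conventional reported optima such as 256,
#' 3.0314, 9.1896, 48.5029, 84.4485 and 147.0334.
#'
#' @return numeric vector of exponents.
#' @export
svm_exponent_grid <- function() seq(-8, 8, by = 0.8)

# deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  f <- integer(length(y))
  with_seed(seed, {
    for (lev in unique(y)) {
      idx <- which(y == lev)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  f
}

#' Grid-search a radial-basis SVM grader
#'
#' Features are standardized to calibration-set mean and SD internally (an
#' RBF kernel on raw reflectance scales is degenerate). Every (C, gamma)
#' combination on the exponent grid is scored by stratified k-fold
#' cross-validated accuracy; ties prefer smaller C, then smaller gamma. The
#' winner is refit on the full calibration set.
#'
#' @param x calibration spectra (samples x bands) or a [spectrum_table()].
#' @param grade integer grade labels (taken from the table when given).
#' @param cost_exponents,gamma_exponents base-2 exponent grids.
#' @param folds number of cross-validation folds.
#' @param seed seed for the fold assignment.
#' @return object of class `grade_model` (family `"svm"`).
#' @export
train_svm_grid <- function(x, grade = NULL,
                           cost_exponents = svm_exponent_grid(),
                           gamma_exponents = svm_exponent_grid(),
                           folds = 5, seed = 1) {
  if (inherits(x, "spectrum_table")) {
    grade <- x$grade
    x <- x$spectra
  }
  x <- as.matrix(x)
  stop_if_not(length(cost_exponents) > 0 && length(gamma_exponents) > 0,
              "empty parameter grid")
  stop_if_not(length(unique(grade)) >= 2, "need at least 2 classes")
  y <- factor(grade)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  fold <- stratified_folds(y, folds, derive_seed(seed, 11))

  best <- list(acc = -1)
  for (ce in sort(cost_exponents)) {
    for (ge in sort(gamma_exponents)) {
      correct <- 0L
      for (k in seq_len(folds)) {
        tr <- fold != k
        fit <- e1071::svm(z[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = 2^ce, gamma = 2^ge, scale = FALSE)
        pr <- predict(fit, z[!tr, , drop = FALSE])
        correct <- correct + sum(pr == y[!tr])
      }
      acc <- correct / length(y)
      if (acc > best$acc) {       # strict: earlier (smaller C, gamma) wins ties
        best <- list(acc = acc, ce = ce, ge = ge)
      }
    }
  }
  fit <- e1071::svm(z, y, kernel = "radial", cost = 2^best$ce,
                    gamma = 2^best$ge, scale = FALSE)
  structure(list(family = "svm", cost = 2^best$ce, gamma = 2^best$ge,
                 cost_exponent = best$ce, gamma_exponent = best$ge,
                 cv_accuracy = best$acc, fit = fit, center = ctr,
                 scale = scl, levels = levels(y)),
            class = "grade_model")
}

#' Grid-search a random-forest grader
#'
#' Searches trees-in-forest times features-per-split; feature counts
#' exceeding the band count are clamped to it and deduplicated. Each
#' combination is scored by the mean out-of-bag error over `reps` seeded
#' forests (never-out-of-bag samples count as errors); ties prefer fewer
#' trees, then fewer features. The winner is refit (seeded) on the full
#' calibration set.
#'
#' @param x calibration spectra or a [spectrum_table()].
#' @param grade integer grade labels (taken from the table when given).
#' @param num_trees trees grid.
#' @param mtry features-per-split grid.
#' @param reps seeded repetitions per combination.
#' @param seed master seed.
#' @return object of class `grade_model` (family `"rf"`).
#' @export
train_rf_grid <- function(x, grade = NULL,
                          num_trees = seq(50, 500, by = 50),
                          mtry = seq(10, 100, by = 10),
                          reps = 10, seed = 1) {
  if (inherits(x, "spectrum_table")) {
    grade <- x$grade
    x <- x$spectra
  }
  x <- as.matrix(x)
  stop_if_not(length(unique(grade)) >= 2, "need at least 2 classes")
  y <- factor(grade)
  p <- ncol(x)
  mtry_grid <- sort(unique(pmin(mtry, p)))
  df <- as.data.frame(x)
  names(df) <- paste0("b", seq_len(p))

  best <- list(err = Inf)
  for (nt in sort(num_trees)) {
    for (mt in mtry_grid) {
      errs <- numeric(reps)
      for (i in seq_len(reps)) {
        fit <- ranger::ranger(x = df, y = y, num.trees = nt, mtry = mt,
                              num.threads = 1,
                              seed = derive_seed(seed, nt * 131 + mt * 7 + i))
        pr <- fit$predictions
        errs[i] <- mean(is.na(pr) | pr != y)
      }
      err <- mean(errs)
      if (err < best$err) {       # strict: fewer trees, then fewer features
        best <- list(err = err, nt = nt, mt = mt)
      }
    }
  }
  fit <- ranger::ranger(x = df, y = y, num.trees = best$nt, mtry = best$mt,
                        num.threads = 1, importance = "impurity",
                        seed = derive_seed(seed, 999983))
  structure(list(family = "rf", num_trees = best$nt, mtry = best$mt,
                 oob_error = best$err, fit = fit, feature_names = names(df),
                 levels = levels(y)),
            class = "grade_model")
}

#' @export
print.grade_model <- function(x, ...) {
  if (x$family == "svm") {
    cat(sprintf("<grade_model svm> C = %.4f, gamma = %.4f (CV accuracy %.2f%%)\n",
                x$cost, x$gamma, 100 * x$cv_accuracy))
  } else {
    cat(sprintf("<grade_model rf> %d trees, %d features/split (OOB error %.4f)\n",
                x$num_trees, x$mtry, x$oob_error))
  }
  invisible(x)
}

#' @export
summary.grade_model <- function(object, ...) {
  print(object)
  if (object$family == "svm") {
    cat(sprintf("  exponents: C = 2^%.1f, gamma = 2^%.1f; %d support vectors\n",
                object$cost_exponent, object$gamma_exponent,
                object$fit$tot.nSV))
  } else {
    imp <- sort(object$fit$variable.importance, decreasing = TRUE)
    cat("  top importance:",
        paste(names(head(imp, 5)), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
predict.grade_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_table")) newdata <- newdata$spectra
  newdata <- as.matrix(newdata)
  if (object$family == "svm") {
    z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
    pr <- predict(object$fit, z)
  } else {
    df <- as.data.frame(newdata)
    names(df) <- object$feature_names
    pr <- predict(object$fit, data = df, num.threads = 1)$predictions
  }
  as.integer(as.character(pr))
}

#' Overall accuracy of a confusion matrix
#'
#' The percentage of correctly classified samples,
#' `100 * trace / total`, rounded half-up to two decimals.
#'
#' @param cm square confusion matrix (rows = true, columns = predicted).
#' @return accuracy percentage.
#' @export
overall_accuracy <- function(cm) {
  round_half_up(100 * sum(diag(as.matrix(cm))) / sum(cm), 2)
}

#' Evaluate a grader on a labelled set
#'
#' Builds the 3 x 3 confusion matrix (rows = true grade 1..3, columns =
#' predicted) and the overall accuracy percentage.
#'
#' @param model a fitted `grade_model`.
#' @param x spectra matrix or [spectrum_table()].
#' @param grade true grade labels in 1..3 (taken from the table when given).
#' @return object of class `model_eval` with `confusion` and `accuracy`.
#' @export
evaluate <- function(model, x, grade = NULL) {
  if (inherits(x, "spectrum_table")) {
    grade <- x$grade
    x <- x$spectra
  }
  stop_if_not(all(grade %in% 1:3), "grade labels must lie in {1,2,3}")
  stop_if_not(all(as.character(unique(grade)) %in% model$levels),
              "labels contain a class the model was not trained on")
  pred <- predict(model, x)
  cm <- table(true = factor(grade, levels = 1:3),
              predicted = factor(pred, levels = 1:3))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(true = 1:3, predicted = 1:3))
  structure(list(confusion = cm, accuracy = overall_accuracy(cm),
                 n = length(grade)),
            class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("<model_eval> accuracy %.2f%% on %d samples\n",
              x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}
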