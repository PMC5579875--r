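# Optimal-wavelength selection: second-derivative peak picking and
# random-forest recursive elimination with an out-of-bag error curve.

# all local extrema (turning points) of a vector, no separation constraint
all_extrema <- function(y) {
  s <- sign(diff(y))
  which(s[-1] * s[-length(s)] < 0) + 1L
}

#' Configuration of the recursive random-forest wavelength elimination
#'
#' @param models_per_round forests trained per elimination round (the mean
#'   importance over these is what ranks the bands).
#' @param eliminate_per_round bands dropped each round; must divide
#'   `n_bands - stop_at`.
#' @param stop_at surviving band count at which elimination stops.
#' @param num_trees trees per forest.
#' @param mtry candidate features per split; `NULL` for the square-root
#'   default. Values exceeding the current band count are clamped (with a
#'   warning).
#' @param importance per-band importance metric: `"impurity"` (mean
#'   decrease in Gini impurity, the cheap deterministic default) or
#'   `"permutation"`.
#' @param seed seed for the per-forest random streams.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(models_per_round = 100, eliminate_per_round = 20,
                             stop_at = 20, num_trees = 50, mtry = NULL,
                             importance = c("impurity", "permutation"),
                             seed = 1) {
  importance <- match.arg(importance)
  stop_if_not(models_per_round >= 1, "models_per_round must be >= 1")
  stop_if_not(eliminate_per_round >= 1, "eliminate_per_round must be >= 1")
  stop_if_not(stop_at >= 1, "stop_at must be >= 1")
  structure(list(models_per_round = models_per_round,
                 eliminate_per_round = eliminate_per_round,
                 stop_at = stop_at, num_trees = num_trees, mtry = mtry,
                 importance = importance, seed = seed),
            class = "selection_config")
}

new_wavelength_subset <- function(indices, wavelength, method, trace) {
  stop_if_not(!anyDuplicated(indices), "band indices must be unique")
  structure(list(indices = indices, wavelength_nm = wavelength[indices],
                 method = method, trace = trace),
            class = "wavelength_subset")
}

#' @export
print.wavelength_subset <- function(x, ...) {
  cat(sprintf("<wavelength_subset method=%s> %d band(s): %s nm\n",
              x$method, length(x$indices),
              paste(round(x$wavelength_nm), collapse = ", ")))
  invisible(x)
}

#' Select wavelengths from second-derivative spectra
#'
#' Candidate bands are the local extrema of the pooled mean
#' second-derivative spectrum; candidates are ranked by the between-grade
#' range (max minus min of the grade means) of the second derivative at the
#' band, and the top `k` are kept greedily subject to a minimum band
#' separation. When the grade means are indistinguishable everywhere the
#' ranking falls back to extremum magnitude (with a warning).
#'
#' @param d2 second-derivative matrix (samples x bands), see
#'   [second_derivative()].
#' @param wavelength band wavelengths (nm).
#' @param grade integer grade labels per row.
#' @param k number of wavelengths to select.
#' @param min_separation minimum band-index separation between selections.
#' @return a `wavelength_subset` (method `"d2"`), indices sorted by
#'   wavelength; the trace records candidates and their grade ranges.
#' @export
select_by_d2 <- function(d2, wavelength, grade, k = 14, min_separation = 5) {
  stop_if_not(length(unique(grade)) >= 2, "need at least 2 grades")
  stop_if_not(k >= 1, "k must be >= 1")
  pooled <- colMeans(d2)
  cand <- all_extrema(pooled)
  if (!length(cand)) {
    warning("no local extrema found; selecting by grade range alone")
    cand <- seq_along(pooled)
  }
  gm <- sapply(sort(unique(grade)), function(g) {
    colMeans(d2[grade == g, , drop = FALSE])
  })
  rng <- apply(gm, 1, max) - apply(gm, 1, min)
  score <- rng[cand]
  if (max(score) < .Machine$double.eps^0.5 * max(abs(pooled), 1)) {
    warning("grade means indistinguishable; ranking extrema by magnitude")
    score <- abs(pooled[cand])
  }
  ord <- cand[order(score, decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_separation)) {
      kept <- c(kept, i)
    }
    if (length(kept) == k) break
  }
  if (length(kept) < k) {
    warning(sprintf("only %d candidate bands available (%d requested)",
                    length(kept), k))
  }
  new_wavelength_subset(sort(kept), wavelength, "d2",
                        list(candidates = cand, grade_range = rng))
}

# one importance pass: mean impurity importance over R seeded forests
rf_importance_pass <- function(df, y, config, mtry, round_id) {
  imp <- matrix(0, config$models_per_round, ncol(df))
  for (i in seq_len(config$models_per_round)) {
    fit <- ranger::ranger(
      x = df, y = y, num.trees = config$num_trees, mtry = mtry,
      importance = config$importance %||% "impurity", num.threads = 1,
      seed = derive_seed(config$seed, round_id * 1009 + i))
    imp[i, ] <- fit$variable.importance
  }
  colMeans(imp)
}

# mean OOB error over R seeded forests; never-out-of-bag samples count as
# errors
rf_oob_error <- function(df, y, config, mtry, round_id) {
  errs <- numeric(config$models_per_round)
  for (i in seq_len(config$models_per_round)) {
    fit <- ranger::ranger(
      x = df, y = y, num.trees = config$num_trees, mtry = mtry,
      num.threads = 1,
      seed = derive_seed(config$seed, round_id * 1009 + i))
    p <- fit$predictions
    errs[i] <- mean(is.na(p) | p != y)
  }
  mean(errs)
}

#' Recursive random-forest wavelength elimination
#'
#' Repeatedly trains `models_per_round` forests, averages the per-band
#' impurity importance, and eliminates the `eliminate_per_round` bands of
#' lowest mean importance until `stop_at` bands remain (from 200 bands with
#' the defaults: nine rounds). Survivors are ranked by their final-round
#' mean importance; forests are then trained on the top-k bands for
#' k = 1..`stop_at` and the k minimizing the mean out-of-bag error (smallest
#' k on ties) defines the selected subset.
#'
#' @param x a [spectrum_table()] (typically restricted to the calibration
#'   set) or numeric matrix.
#' @param config a [selection_config()].
#' @param grade grade labels (taken from the table when `x` is one).
#' @param wavelength band wavelengths (ditto).
#' @return a `wavelength_subset` (method `"rf"`), indices sorted by
#'   wavelength; the trace records every round's surviving bands and mean
#'   importances, the final ranking and the OOB error curve.
#' @export
select_by_rf <- function(x, config = selection_config(), grade = NULL,
                         wavelength = NULL) {
  if (inherits(x, "spectrum_table")) {
    grade <- x$grade
    wavelength <- x$wavelength
    m <- x$spectra
  } else {
    m <- as.matrix(x)
    stop_if_not(!is.null(grade), "supply `grade` for matrix input")
    if (is.null(wavelength)) wavelength <- seq_len(ncol(m))
  }
  p <- ncol(m)
  stop_if_not(p > config$stop_at,
              "need more than stop_at = %d bands", config$stop_at)
  stop_if_not(length(unique(grade)) >= 2, "need at least 2 classes")
  stop_if_not((p - config$stop_at) %% config$eliminate_per_round == 0,
              "eliminate_per_round (%d) must divide n_bands - stop_at (%d)",
              config$eliminate_per_round, p - config$stop_at)
  y <- factor(grade)
  colnames(m) <- paste0("b", seq_len(p))
  clamped <- FALSE
  pick_mtry <- function(n_feat) {
    if (is.null(config$mtry)) return(max(1L, floor(sqrt(n_feat))))
    if (config$mtry > n_feat) {
      if (!clamped) {
        warning(sprintf("features-per-node %d clamped to %d available bands",
                        config$mtry, n_feat))
        clamped <<- TRUE
      }
      return(n_feat)
    }
    config$mtry
  }

  surviving <- seq_len(p)
  rounds <- list()
  r <- 0L
  last_imp <- NULL
  while (length(surviving) > config$stop_at) {
    r <- r + 1L
    df <- as.data.frame(m[, surviving, drop = FALSE])
    imp <- rf_importance_pass(df, y, config, pick_mtry(length(surviving)), r)
    rounds[[r]] <- list(bands = surviving, mean_importance = imp)
    drop_n <- min(config$eliminate_per_round,
                  length(surviving) - config$stop_at)
    ord <- order(imp, surviving)   # lowest importance first, index tie-break
    last_imp <- imp
    surviving <- sort(surviving[-ord[seq_len(drop_n)]])
  }
  # rank survivors by their importance in the last elimination round
  if (is.null(last_imp)) {        # p == stop_at never happens (checked), but
    df <- as.data.frame(m[, surviving, drop = FALSE])
    last_imp <- rf_importance_pass(df, y, config,
                                   pick_mtry(length(surviving)), r + 1L)
    rank_imp <- last_imp
  } else {
    rank_imp <- last_imp[match(surviving, rounds[[r]]$bands)]
  }
  ranked <- surviving[order(rank_imp, decreasing = TRUE)]

  oob <- numeric(config$stop_at)
  for (k in seq_len(config$stop_at)) {
    dfk <- as.data.frame(m[, ranked[seq_len(k)], drop = FALSE])
    oob[k] <- rf_oob_error(dfk, y, config, pick_mtry(k), 1000L + k)
  }
  k_star <- which.min(oob)        # first minimum = smallest k
  sel <- ranked[seq_len(k_star)]
  new_wavelength_subset(sort(sel), wavelength, "rf",
                        list(rounds = rounds, ranked = ranked,
                             ranked_nm = wavelength[ranked],
                             oob_curve = oob, k_star = k_star))
}
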