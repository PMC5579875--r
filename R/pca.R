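#' Principal component scores of mean spectra
#'
#' Mean-centered (not autoscaled) PCA via singular value decomposition.
#' Component signs follow the convention that the largest-magnitude loading
#' of each component is positive.
#'
#' @param x a [spectrum_table()] or numeric matrix (samples x bands).
#' @param n_components number of leading components,
#'   `<= min(n_samples - 1, n_bands)`.
#' @return object of class `pca_result`: `scores`
#'   (samples x components), `explained_variance` (fractions of total
#'   variance, non-increasing, summing to at most 1) and `loadings`.
#' @export
pca_scores <- function(x, n_components = 3) {
  m <- if (inherits(x, "spectrum_table")) x$spectra else as.matrix(x)
  limit <- min(nrow(m) - 1, ncol(m))
  stop_if_not(n_components >= 1 && n_components <= limit,
              "n_components must lie in [1, %d]", limit)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(scores = scores,
                 explained_variance = ev[seq_len(n_components)] / sum(ev),
                 loadings = load),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; explained variance: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}
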