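#' Construct a uniformly spaced wavelength axis
#'
#' Builds the axis of a line-scan NIR camera such that exactly `n_in_range`
#' bands fall inside the closed interval `[lo, hi]`, with `lo` and `hi`
#' themselves the first and last in-range bands. The remaining
#' `n_bands - n_in_range` bands continue the uniform spacing outside the
#' interval, split as evenly as possible (one extra band above when the
#' leftover count is odd).
#'
#' The default instrument covers 874-1734 nm with 256 bands of which the 200
#' bands between 975.01 and 1645.82 nm are retained for analysis.
#'
#' @param n_bands total number of bands.
#' @param lo,hi first and last retained wavelength (nm), `lo < hi`.
#' @param n_in_range number of bands inside `[lo, hi]` (>= 2).
#' @return numeric vector of length `n_bands`, strictly increasing.
#' @examples
#' ax <- make_wavelength_axis(256, 975.01, 1645.82, 200)
#' sum(ax >= 975.01 & ax <= 1645.82)  # 200
#' @export
make_wavelength_axis <- function(n_bands = 256, lo = 975.01, hi = 1645.82,
                                 n_in_range = 200) {
  stop_if_not(lo < hi, "`lo` (%g) must be below `hi` (%g)", lo, hi)
  stop_if_not(n_in_range >= 2, "`n_in_range` must be at least 2")
  stop_if_not(n_in_range <= n_bands,
              "`n_in_range` (%d) exceeds `n_bands` (%d)", n_in_range, n_bands)
  delta <- (hi - lo) / (n_in_range - 1)
  inner <- seq(lo, hi, length.out = n_in_range)  # endpoints exact
  extra <- n_bands - n_in_range
  n_below <- extra %/% 2L
  n_above <- extra - n_below
  below <- if (n_below > 0) lo - delta * (n_below:1) else numeric(0)
  above <- if (n_above > 0) hi + delta * (1:n_above) else numeric(0)
  axis <- c(below, inner, above)
  stop_if_not(all(diff(axis) > 0), "internal error: axis not increasing")
  axis
}
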