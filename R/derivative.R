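#' Savitzky-Golay second-derivative spectra
#'
#' Fits a local polynomial of order `polyorder` in a sliding window of
#' `window` bands and evaluates its second derivative, per sample row, in
#' reflectance per nm^2. Window edges use the boundary rows of the
#' projection matrix, i.e. a polynomial fit anchored at the ends, so the
#' derivative is exact for polynomials up to `polyorder` everywhere.
#' Requires a uniformly spaced wavelength axis.
#'
#' @param x a [spectrum_table()] or numeric matrix (samples x bands).
#' @param window odd filter length, `window > polyorder`.
#' @param polyorder polynomial order, `>= 2`.
#' @param wavelength axis in nm (taken from the table when `x` is one).
#' @return matrix of second derivatives, same shape as the spectra.
#' @export
second_derivative <- function(x, window = 11, polyorder = 3,
                              wavelength = NULL) {
  if (inherits(x, "spectrum_table")) {
    wavelength <- x$wavelength
    m <- x$spectra
  } else {
    m <- as.matrix(x)
    stop_if_not(!is.null(wavelength), "supply `wavelength` for matrix input")
  }
  stop_if_not(window %% 2 == 1, "`window` must be odd")
  stop_if_not(polyorder >= 2, "`polyorder` must be at least 2")
  stop_if_not(window > polyorder, "`window` must exceed `polyorder`")
  stop_if_not(ncol(m) >= window, "spectra shorter than the filter window")
  dl <- diff(wavelength)
  stop_if_not(diff(range(dl)) < 1e-6 * mean(dl),
              "wavelength axis must be uniformly spaced")
  filt <- signal::sgolay(p = polyorder, n = window, m = 2, ts = mean(dl))
  out <- t(apply(m, 1, function(row) signal::sgolayfilt(row, filt)))
  dimnames(out) <- NULL
  out
}
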