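#' White/dark reflectance calibration
#'
#' Converts raw digital numbers to relative reflectance against a white
#' (high-reflectance Teflon) and a dark (shuttered) reference frame:
#' `R = (raw - dark) / (white - dark)`, elementwise. The transformation is
#' invariant under any common affine rescaling of the three frames, so the
#' sensor's gain and offset drop out.
#'
#' @param raw a raw-kind [spectral_cube()].
#' @param white,dark reference frames, [spectral_cube()]s (or plain arrays)
#'   of the same dimensions as `raw`; `white > dark` everywhere.
#' @param column_average average the references over image lines before
#'   correcting (per-column correction), for instruments whose references
#'   are single line scans.
#' @param clip clamp the result into \[0, 1\]. Off by default: specular
#'   out-of-range pixels carry information and later ROI averaging is robust
#'   to them.
#' @return a reflectance-kind [spectral_cube()].
#' @export
correct_reflectance <- function(raw, white, dark, column_average = FALSE,
                                clip = FALSE) {
  w <- if (inherits(white, "spectral_cube")) white$data else white
  d <- if (inherits(dark, "spectral_cube")) dark$data else dark
  stop_if_not(identical(dim(raw$data), dim(w)) &&
                identical(dim(raw$data), dim(d)),
              "raw, white and dark frames must share dimensions")
  if (column_average) {
    # collapse the line (row) axis of each reference, then re-broadcast
    wm <- apply(w, c(2, 3), mean)
    dm <- apply(d, c(2, 3), mean)
    nr <- dim(raw$data)[1]
    w <- aperm(array(wm, dim = c(dim(wm), nr)), c(3, 1, 2))
    d <- aperm(array(dm, dim = c(dim(dm), nr)), c(3, 1, 2))
  }
  denom <- w - d
  bad <- which(denom <= 0)
  if (length(bad)) {
    pos <- arrayInd(head(bad, 5), dim(denom))
    stop(sprintf(
      "white <= dark at %d position(s), e.g. [row,col,band]: %s",
      length(bad),
      paste(apply(pos, 1, paste, collapse = ","), collapse = "; ")),
      call. = FALSE)
  }
  refl <- (raw$data - d) / denom
  if (clip) refl <- pmin(pmax(refl, 0), 1)
  spectral_cube(refl, raw$wavelength, kind = "reflectance")
}

#' Retain the bands inside a wavelength interval
#'
#' Keeps exactly the bands with `lo <= wavelength <= hi` (closed interval).
#' Idempotent for a fixed interval. The default analysis interval
#' 975.01-1645.82 nm trims the noisy ends of the 874-1734 nm instrument
#' range, leaving 200 bands on the default axis.
#'
#' @param x a [spectral_cube()] or [spectrum_table()].
#' @param lo,hi interval endpoints in nm, `lo < hi`.
#' @return object of the same class with the reduced band set.
#' @export
subset_bands <- function(x, lo = 975.01, hi = 1645.82) {
  UseMethod("subset_bands")
}

band_window <- function(wavelength, lo, hi) {
  stop_if_not(lo < hi, "`lo` must be below `hi`")
  keep <- which(wavelength >= lo & wavelength <= hi)
  stop_if_not(length(keep) > 0, "no bands inside [%g, %g] nm", lo, hi)
  keep
}

#' @export
subset_bands.spectral_cube <- function(x, lo = 975.01, hi = 1645.82) {
  keep <- band_window(x$wavelength, lo, hi)
  spectral_cube(x$data[, , keep, drop = FALSE], x$wavelength[keep],
                kind = x$kind)
}

#' @export
subset_bands.spectrum_table <- function(x, lo = 975.01, hi = 1645.82) {
  keep <- band_window(x$wavelength, lo, hi)
  spectrum_table(x$spectra[, keep, drop = FALSE], x$wavelength[keep],
                 grade = x$grade, form = x$form, id = x$id)
}
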