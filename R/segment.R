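#' Segment the sample region of interest
#'
#' Thresholds a single high-contrast band (default: the band nearest
#' 1100 nm, where sausage tissue reflects strongly against the dark
#' background) with Otsu's method and keeps the largest connected
#' component.
#'
#' @param cube a reflectance-kind [spectral_cube()].
#' @param band_nm wavelength (nm) of the band used for thresholding.
#' @return object of class `sample_mask`: list with `mask` (logical matrix)
#'   and `n_pixels`.
#' @export
segment_sample <- function(cube, band_nm = 1100) {
  stop_if_not(cube$kind == "reflectance",
              "segmentation expects a reflectance cube")
  b <- which.min(abs(cube$wavelength - band_nm))
  plane <- cube$data[, , b]
  clamped <- pmin(pmax(plane, 0), 1)
  thr <- EBImage::otsu(EBImage::Image(clamped))
  fg <- clamped > thr
  stop_if_not(any(fg), "no foreground pixels found (empty sample?)")
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg)))
  counts <- tabulate(labels[labels > 0])
  keep <- which.max(counts)
  mask <- labels == keep
  structure(list(mask = mask, n_pixels = sum(mask)), class = "sample_mask")
}

#' @export
print.sample_mask <- function(x, ...) {
  cat(sprintf("<sample_mask> %d foreground pixels in a %d x %d frame\n",
              x$n_pixels, nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices (or `sample_mask` objects) of equal size.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  if (inherits(a, "sample_mask")) a <- a$mask
  if (inherits(b, "sample_mask")) b <- b$mask
  sum(a & b) / sum(a | b)
}
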