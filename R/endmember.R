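#' Define a pure-component (endmember) reflectance spectrum
#'
#' An endmember is modelled as a flat baseline reflectance minus a sum of
#' Gaussian absorption bands:
#' \deqn{R(\lambda) = b - \sum_j d_j \exp\{-(\lambda - c_j)^2 / (2 w_j^2)\}}
#' The closed form makes every downstream property (band minima, mixture
#' means, grade separations) checkable analytically.
#'
#' @param name one of `"lean"`, `"fat"`, `"binder"`, `"background"`.
#' @param baseline baseline reflectance in (0, 1).
#' @param bands data.frame with columns `center` (nm), `width` (nm) and
#'   `depth` (reflectance units, in \[0, 1\]); may have zero rows.
#' @return an object of class `endmember`.
#' @export
endmember <- function(name, baseline, bands = data.frame(center = numeric(0),
                                                         width = numeric(0),
                                                         depth = numeric(0))) {
  name <- match.arg(name, c("lean", "fat", "binder", "background"))
  stop_if_not(baseline > 0 && baseline < 1, "baseline must lie in (0,1)")
  bands <- as.data.frame(bands)
  stop_if_not(all(c("center", "width", "depth") %in% names(bands)),
              "`bands` needs columns center, width, depth")
  if (nrow(bands)) {
    stop_if_not(all(bands$center >= 874 & bands$center <= 1734),
                "absorption centers must lie within 874-1734 nm")
    stop_if_not(all(bands$width > 0), "band widths must be positive")
    stop_if_not(all(bands$depth >= 0 & bands$depth <= 1),
                "band depths must lie in [0,1]")
  }
  em <- structure(list(name = name, baseline = baseline, bands = bands),
                  class = "endmember")
  # reflectance must stay inside [0.01, 0.99] across the instrument range
  r <- endmember_reflectance(em, seq(874, 1734, by = 1))
  stop_if_not(all(r >= 0.01 & r <= 0.99),
              "endmember '%s' leaves [0.01, 0.99] (range %.3f-%.3f)",
              name, min(r), max(r))
  em
}

#' @export
print.endmember <- function(x, ...) {
  cat(sprintf("<endmember '%s'> baseline %.2f, %d absorption band(s)\n",
              x$name, x$baseline, nrow(x$bands)))
  invisible(x)
}

#' Evaluate an endmember spectrum on a wavelength axis
#'
#' @param em an [endmember()].
#' @param axis numeric wavelength axis (nm).
#' @return reflectance values in (0, 1), one per axis element.
#' @export
endmember_reflectance <- function(em, axis) {
  stop_if_not(length(axis) > 0, "wavelength axis is empty")
  r <- rep(em$baseline, length(axis))
  b <- em$bands
  if (nrow(b)) {
    for (j in seq_len(nrow(b))) {
      r <- r - b$depth[j] * exp(-(axis - b$center[j])^2 / (2 * b$width[j]^2))
    }
  }
  r
}

#' Default sausage endmember set
#'
#' Lean meat carries protein/water features (N-H second overtones near 995 nm
#' and the 1056-1099 nm cluster, amide combination bands around 1254-1348 nm,
#' the 1450 nm water band); fat carries C-H features (1160, 1210 nm second
#' overtones, 1395 nm, a C-H band near 1725 nm) with little water. Each tissue
#' also shows a weak echo of the other's bands (residual intramuscular fat,
#' residual protein). The starch/soy binder is dominated by water and a broad
#' 1540 nm feature; the conveyor background is a dark matte surface.
#'
#' @return named list of four [endmember()] objects.
#' @export
default_endmembers <- function() {
  list(
    lean = endmember("lean", 0.75, data.frame(
      center = c(995, 1070, 1160, 1210, 1300, 1395, 1450, 1725),
      width  = c(18,   28,   22,   20,   45,   30,   35,   25),
      depth  = c(0.075, 0.120, 0.005, 0.010, 0.150, 0.007, 0.250, 0.006))),
    fat = endmember("fat", 0.78, data.frame(
      center = c(995, 1070, 1160, 1210, 1300, 1395, 1450, 1725),
      width  = c(18,   28,   22,   20,   45,   30,   35,   25),
      depth  = c(0.004, 0.007, 0.085, 0.190, 0.008, 0.135, 0.100, 0.115))),
    binder = endmember("binder", 0.68, data.frame(
      center = c(1200, 1450, 1540),
      width  = c(30,   42,   40),
      depth  = c(0.05, 0.18, 0.08))),
    background = endmember("background", 0.06)
  )
}
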