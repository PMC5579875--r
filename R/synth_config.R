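#' Configuration for the synthetic sausage-image generator
#'
#' Describes the simulated study: three quality grades differing in their
#' mean lean-meat fraction (strictly decreasing from top to second grade),
#' imaged whole ("intact", an elongated ellipse) and as cut discs ("sliced").
#' Per-sample lean fractions are Beta-distributed around the grade mean with
#' concentration `fraction_kappa`; sliced samples use the concentration
#' divided by `slice_variance_multiplier` (> 1), reproducing the larger
#' spectral spread of cut surfaces. Each sample additionally receives a
#' multiplicative scatter gain and a smooth random baseline undulation, the
#' standard nuisance structure of diffuse-reflectance NIR measurements;
#' both standard deviations are scaled by `sqrt(slice_variance_multiplier)`
#' for sliced samples.
#'
#' @param n_intact_per_grade intact sausages simulated per grade.
#' @param slices_per_sausage slices cut from each intact sausage.
#' @param lean_fraction_means named grade means of the lean fraction of the
#'   meat portion, strictly decreasing top > first > second.
#' @param fraction_kappa Beta concentration of per-sample lean fractions.
#' @param slice_variance_multiplier variance inflation for sliced samples (>1).
#' @param pixel_kappa Beta concentration of per-pixel fractions around the
#'   sample fraction (marbling graininess).
#' @param binder_fraction fixed binder volume fraction per pixel.
#' @param scatter_gain_sd SD of the per-sample multiplicative scatter gain.
#' @param baseline_wiggle_sd SD of each smooth baseline-undulation coefficient
#'   (6 Gaussian bumps of 150 nm width spanning the retained range).
#' @param noise_sd sensor noise SD in digital numbers (DN).
#' @param n_bands,range_lo,range_hi,n_in_range wavelength axis specification,
#'   see [make_wavelength_axis()].
#' @param rows,cols image frame size in pixels.
#' @param endmembers named list with elements `lean`, `fat`, `binder`,
#'   `background`, each an [endmember()].
#' @param seed master seed for dataset simulation.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_intact_per_grade = 50,
                             slices_per_sausage = 3,
                             lean_fraction_means = c(top = 0.75, first = 0.60,
                                                     second = 0.45),
                             fraction_kappa = 300,
                             slice_variance_multiplier = 4,
                             pixel_kappa = 100,
                             binder_fraction = 0.12,
                             scatter_gain_sd = 0.015,
                             baseline_wiggle_sd = 0.007,
                             noise_sd = 6,
                             n_bands = 256,
                             range_lo = 975.01,
                             range_hi = 1645.82,
                             n_in_range = 200,
                             rows = 40, cols = 26,
                             endmembers = default_endmembers(),
                             seed = 17) {
  stop_if_not(length(lean_fraction_means) == 3 &&
                all(diff(lean_fraction_means) < 0),
              "lean-fraction means must be strictly decreasing top > first > second")
  stop_if_not(all(lean_fraction_means > 0 & lean_fraction_means < 1),
              "lean fractions must lie in (0,1)")
  stop_if_not(slice_variance_multiplier > 1,
              "slice_variance_multiplier must exceed 1")
  stop_if_not(binder_fraction >= 0 && binder_fraction < 1,
              "binder_fraction must lie in [0,1)")
  stop_if_not(fraction_kappa > 0 && pixel_kappa > 0,
              "concentration parameters must be positive")
  stop_if_not(noise_sd >= 0, "noise_sd must be non-negative")
  stop_if_not(all(c("lean", "fat", "binder", "background") %in%
                    names(endmembers)),
              "endmembers must contain lean, fat, binder and background")
  axis <- make_wavelength_axis(n_bands, range_lo, range_hi, n_in_range)
  structure(list(
    n_intact_per_grade = n_intact_per_grade,
    slices_per_sausage = slices_per_sausage,
    lean_fraction_means = lean_fraction_means,
    fraction_kappa = fraction_kappa,
    slice_variance_multiplier = slice_variance_multiplier,
    pixel_kappa = pixel_kappa,
    binder_fraction = binder_fraction,
    scatter_gain_sd = scatter_gain_sd,
    baseline_wiggle_sd = baseline_wiggle_sd,
    noise_sd = noise_sd,
    rows = rows, cols = cols,
    wavelength = axis,
    range_lo = range_lo, range_hi = range_hi,
    endmembers = endmembers,
    seed = seed
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  %d intact sausages/grade, %d slices each; frames %dx%d px, %d bands\n",
              x$n_intact_per_grade, x$slices_per_sausage, x$rows, x$cols,
              length(x$wavelength)))
  cat(sprintf("  lean fractions %.2f/%.2f/%.2f (kappa %g, slice multiplier %g), seed %d\n",
              x$lean_fraction_means[1], x$lean_fraction_means[2],
              x$lean_fraction_means[3], x$fraction_kappa,
              x$slice_variance_multiplier, x$seed))
  invisible(x)
}
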