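# Synthetic cube generation: linear endmember mixing inside a rasterized
# sample geometry, wrapped in the sensor model raw = dark + R*(white-dark) + e.

# Smooth baseline-undulation basis: 6 Gaussian bumps spanning the retained
# spectral range. Deterministic given the axis.
wiggle_basis <- function(axis, lo, hi) {
  centers <- seq(lo + 0.04 * (hi - lo), hi - 0.04 * (hi - lo), length.out = 6)
  width <- 0.22 * (hi - lo)
  sapply(centers, function(cc) exp(-(axis - cc)^2 / (2 * width^2)))
}

# Relative illumination profile of the lamp across the axis.
illumination_profile <- function(axis) {
  0.55 + 0.45 * exp(-(axis - 1300)^2 / (2 * 250^2))
}

# White and dark reference frames (rows x cols x bands). The white frame
# carries the lamp spectrum and a fixed +-3% per-pixel sensitivity pattern;
# the dark frame is the sensor pedestal. Consumes RNG draws.
make_reference_frames <- function(config) {
  rows <- config$rows; cols <- config$cols
  nb <- length(config$wavelength)
  pedestal <- 100 + matrix(runif(rows * cols, -2, 2), rows, cols)
  pattern <- 1 + matrix(runif(rows * cols, -0.03, 0.03), rows, cols)
  illum <- illumination_profile(config$wavelength)
  dark <- array(pedestal, dim = c(rows, cols, nb))
  white <- dark + outer(pattern * 2900, illum)
  dim(white) <- c(rows, cols, nb)
  list(
    white = spectral_cube(white, config$wavelength, kind = "raw"),
    dark = spectral_cube(dark, config$wavelength, kind = "raw")
  )
}

# Rasterized sample geometry: elongated ellipse (intact) or disc (sliced).
sample_geometry <- function(rows, cols, form) {
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  r <- row(matrix(0, rows, cols)); c <- col(matrix(0, rows, cols))
  if (form == "intact") {
    a <- 0.40 * rows; b <- 0.35 * cols
    ((r - cr) / a)^2 + ((c - cc) / b)^2 <= 1
  } else {
    rad <- 0.38 * min(rows, cols)
    (r - cr)^2 + (c - cc)^2 <= rad^2
  }
}

# Core simulation against supplied reference frames; consumes RNG draws.
simulate_sample_core <- function(config, grade, form, refs) {
  axis <- config$wavelength
  nb <- length(axis)
  rows <- config$rows; cols <- config$cols
  mask <- sample_geometry(rows, cols, form)
  npix <- sum(mask)

  mult <- if (form == "sliced") config$slice_variance_multiplier else 1
  kappa <- config$fraction_kappa / mult
  sd_scale <- sqrt(mult)

  m <- config$lean_fraction_means[[grade]]
  p_sample <- rbeta(1, m * kappa, (1 - m) * kappa)
  gain <- rnorm(1, 1, config$scatter_gain_sd * sd_scale)
  wig_coef <- rnorm(6, 0, config$baseline_wiggle_sd * sd_scale)

  em <- config$endmembers
  L <- endmember_reflectance(em$lean, axis)
  F_ <- endmember_reflectance(em$fat, axis)
  B <- endmember_reflectance(em$binder, axis)
  bg <- endmember_reflectance(em$background, axis)

  p_px <- rbeta(npix, p_sample * config$pixel_kappa,
                (1 - p_sample) * config$pixel_kappa)
  bf <- config$binder_fraction
  mix <- bf * matrix(B, npix, nb, byrow = TRUE) +
    (1 - bf) * (outer(p_px, L) + outer(1 - p_px, F_))
  wig <- as.numeric(wiggle_basis(axis, config$range_lo, config$range_hi) %*%
                      wig_coef)
  refl_px <- pmin(pmax(gain * mix + matrix(wig, npix, nb, byrow = TRUE),
                       0.005), 0.995)

  refl <- array(rep(bg, each = rows * cols), dim = c(rows, cols, nb))
  idx <- which(mask)
  for (b in seq_len(nb)) {
    plane <- refl[, , b]
    plane[idx] <- refl_px[, b]
    refl[, , b] <- plane
  }

  w <- refs$white$data; d <- refs$dark$data
  raw <- d + refl * (w - d)
  if (config$noise_sd > 0) {
    raw <- raw + array(rnorm(length(raw), 0, config$noise_sd), dim = dim(raw))
  }

  frac_lean <- matrix(0, rows, cols); frac_lean[idx] <- (1 - bf) * p_px
  frac_fat <- matrix(0, rows, cols); frac_fat[idx] <- (1 - bf) * (1 - p_px)
  frac_binder <- matrix(0, rows, cols); frac_binder[idx] <- bf
  frac_background <- matrix(1, rows, cols); frac_background[idx] <- 0

  truth <- list(mask = mask, grade = grade, form = form,
                lean_fraction = p_sample, gain = gain, wiggle = wig_coef,
                fractions = list(lean = frac_lean, fat = frac_fat,
                                 binder = frac_binder,
                                 background = frac_background),
                reflectance = spectral_cube(refl, axis, kind = "reflectance"))
  list(raw = spectral_cube(raw, axis, kind = "raw"),
       white = refs$white, dark = refs$dark, truth = truth)
}

#' Simulate one hyperspectral sausage acquisition
#'
#' Draws a sample of the requested grade and form, rasterizes its geometry,
#' mixes the lean/fat/binder endmember spectra per pixel, applies the
#' per-sample scatter gain and baseline undulation, and passes the
#' reflectance field through the sensor model
#' `raw = dark + R * (white - dark) + noise`. With `noise_sd = 0`,
#' [correct_reflectance()] applied to the output recovers the true
#' reflectance field exactly.
#'
#' @param config a [synthetic_config()].
#' @param grade grade code 1 (top), 2 (first) or 3 (second).
#' @param form `"intact"` or `"sliced"`.
#' @param seed integer seed; defaults to the config seed. Identical seeds
#'   give bit-identical output.
#' @return list with elements `raw`, `white`, `dark` (each a
#'   [spectral_cube()]) and `truth` (mask, per-pixel component fractions,
#'   sample-level lean fraction, scatter parameters and the clean
#'   reflectance cube).
#' @export
simulate_sample <- function(config, grade, form = c("intact", "sliced"),
                            seed = NULL) {
  form <- match.arg(form)
  stop_if_not(grade %in% 1:3, "grade must be 1, 2 or 3")
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    refs <- make_reference_frames(config)
    simulate_sample_core(config, grade, form, refs)
  })
}

#' Simulate a full graded dataset on disk
#'
#' Writes ENVI cubes for `n_intact_per_grade` intact sausages per grade and
#' `slices_per_sausage` slices per sausage (inheriting the parent grade),
#' together with one shared white/dark reference pair and a CSV manifest.
#' The manifest's first line records the master seed as a `#`-comment.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame (columns `id`, `path`, `grade`, `form`,
#'   `parent_id`), invisibly.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(file.path(dir, "cubes"), recursive = TRUE, showWarnings = FALSE)
  stop_if_not(dir.exists(dir), "cannot create output directory '%s'", dir)
  refs <- with_seed(derive_seed(config$seed, 0), make_reference_frames(config))
  write_envi(refs$white, file.path(dir, "white"))
  write_envi(refs$dark, file.path(dir, "dark"))

  rows <- list(); k <- 0L
  for (grade in 1:3) {
    for (i in seq_len(config$n_intact_per_grade)) {
      k <- k + 1L
      id <- sprintf("intact_g%d_%03d", grade, i)
      smp <- with_seed(derive_seed(config$seed, k),
                       simulate_sample_core(config, grade, "intact", refs))
      path <- file.path("cubes", paste0(id, ".hdr"))
      write_envi(smp$raw, file.path(dir, "cubes", id))
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, path = path, grade = grade, form = "intact", parent_id = NA)
      for (s in seq_len(config$slices_per_sausage)) {
        k <- k + 1L
        sid <- sprintf("slice_g%d_%03d_s%d", grade, i, s)
        sl <- with_seed(derive_seed(config$seed, k),
                        simulate_sample_core(config, grade, "sliced", refs))
        spath <- file.path("cubes", paste0(sid, ".hdr"))
        write_envi(sl$raw, file.path(dir, "cubes", sid))
        rows[[length(rows) + 1L]] <- data.frame(
          id = sid, path = spath, grade = grade, form = "sliced",
          parent_id = id)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  con <- file(mpath, "w")
  writeLines(sprintf("# seed %d", config$seed), con)
  write.csv(manifest, con, row.names = FALSE)
  close(con)
  invisible(manifest)
}

#' Read a dataset manifest written by [simulate_dataset()]
#'
#' @param dir dataset directory.
#' @return manifest data.frame with the recorded seed as attribute `"seed"`.
#' @export
read_manifest <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  stop_if_not(file.exists(mpath), "no manifest.csv under '%s'", dir)
  first <- readLines(mpath, n = 1)
  manifest <- read.csv(mpath, comment.char = "#", stringsAsFactors = FALSE)
  seed <- if (grepl("^# seed ", first)) {
    as.integer(sub("^# seed ", "", first))
  } else NA_integer_
  attr(manifest, "seed") <- seed
  manifest
}

#' Draw ROI-mean spectra directly from the sampling model
#'
#' Shortcut past the imaging stage: returns the per-sample mean spectrum a
#' perfectly segmented, noise-averaged ROI would yield. Used for fast
#' statistical checks of the chemometric stages; the imaging stage itself is
#' exercised by [simulate_sample()] / [simulate_dataset()].
#'
#' @param config a [synthetic_config()].
#' @param form `"intact"` or `"sliced"`.
#' @param n_per_grade samples per grade; defaults to the config's counts
#'   (intact count, or intact count times slices for sliced).
#' @param seed integer seed (default: config seed).
#' @return a [spectrum_table()].
#' @export
simulate_spectrum_table <- function(config, form = c("intact", "sliced"),
                                    n_per_grade = NULL, seed = NULL) {
  form <- match.arg(form)
  if (is.null(seed)) seed <- config$seed
  if (is.null(n_per_grade)) {
    n_per_grade <- config$n_intact_per_grade *
      if (form == "sliced") config$slices_per_sausage else 1L
  }
  axis <- config$wavelength
  em <- config$endmembers
  L <- endmember_reflectance(em$lean, axis)
  F_ <- endmember_reflectance(em$fat, axis)
  B <- endmember_reflectance(em$binder, axis)
  Phi <- wiggle_basis(axis, config$range_lo, config$range_hi)
  mult <- if (form == "sliced") config$slice_variance_multiplier else 1
  kappa <- config$fraction_kappa / mult
  sd_scale <- sqrt(mult)
  bf <- config$binder_fraction
  with_seed(seed, {
    grades <- rep(1:3, each = n_per_grade)
    m <- config$lean_fraction_means[grades]
    p <- rbeta(length(m), m * kappa, (1 - m) * kappa)
    gain <- rnorm(length(m), 1, config$scatter_gain_sd * sd_scale)
    W <- matrix(rnorm(length(m) * 6, 0, config$baseline_wiggle_sd * sd_scale),
                ncol = 6) %*% t(Phi)
    mix <- bf * matrix(B, length(m), length(axis), byrow = TRUE) +
      (1 - bf) * (outer(p, L) + outer(1 - p, F_))
    X <- mix * gain + W +
      matrix(rnorm(length(m) * length(axis), 0, 5e-4), ncol = length(axis))
    spectrum_table(X, axis, grade = grades, form = rep(form, length(m)),
                   id = sprintf("%s_g%d_%03d", form, grades,
                                sequence(rep(n_per_grade, 3))))
  })
}
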