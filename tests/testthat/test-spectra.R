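flat_cube <- function(vals, bands = 200) {
  # vals: vector of per-pixel levels laid out in a 1 x length(vals) frame
  arr <- array(rep(vals, bands), c(1, length(vals), bands))
  spectral_cube(arr, seq(1000, by = 2, length.out = bands), "reflectance")
}

test_that("ROI mean without denoising is the plain pixel average", {
  cube <- flat_cube(c(0.2, 0.4))
  mask <- matrix(TRUE, 1, 2)
  expect_equal(extract_mean_spectrum(cube, mask, denoise = FALSE),
               rep(0.3, 200))
})

test_that("a single-pixel mask returns that pixel's denoised spectrum", {
  set.seed(2)
  arr <- array(runif(2 * 200), c(1, 2, 200))
  cube <- spectral_cube(arr, seq(1000, by = 2, length.out = 200),
                        "reflectance")
  mask <- matrix(c(TRUE, FALSE), 1, 2)
  expect_equal(extract_mean_spectrum(cube, mask),
               denoise_spectrum(arr[1, 1, ]))
})

test_that("the pipeline denoises before averaging, and the order matters", {
  set.seed(7)
  clean <- 0.5 + 0.1 * sin(seq_len(200) / 12)
  p1 <- clean + rnorm(200, 0, 0.05)
  p2 <- clean + rnorm(200, 0, 0.05)
  arr <- array(c(p1, p2), c(1, 2, 200))
  arr <- aperm(array(c(p1, p2), c(200, 2, 1)), c(3, 2, 1))
  cube <- spectral_cube(arr, seq(1000, by = 2, length.out = 200),
                        "reflectance")
  mask <- matrix(TRUE, 1, 2)
  mean_of_denoised <- (denoise_spectrum(p1) + denoise_spectrum(p2)) / 2
  denoise_of_mean <- denoise_spectrum((p1 + p2) / 2)
  expect_gt(max(abs(mean_of_denoised - denoise_of_mean)), 1e-6)
  expect_equal(extract_mean_spectrum(cube, mask), mean_of_denoised)
})

test_that("ROI averaging is permutation-invariant over pixels", {
  set.seed(8)
  arr <- array(runif(6 * 64), c(2, 3, 64))
  wl <- seq(1000, by = 5, length.out = 64)
  cube <- spectral_cube(arr, wl, "reflectance")
  flipped <- spectral_cube(arr[2:1, 3:1, , drop = FALSE], wl, "reflectance")
  mask <- matrix(TRUE, 2, 3)
  expect_equal(extract_mean_spectrum(cube, mask, denoise = FALSE),
               extract_mean_spectrum(flipped, mask, denoise = FALSE))
})

test_that("an empty mask errors", {
  cube <- flat_cube(c(0.2, 0.4))
  expect_error(extract_mean_spectrum(cube, matrix(FALSE, 1, 2)), "no pixels")
})

test_that("identical samples give zero SD at designated bands", {
  tab <- quick_table(n_per_grade = 2)
  tab$spectra <- tab$spectra[rep(1, nrow(tab$spectra)), ]
  tab$spectra <- tab$spectra + 0.01 * tab$grade  # constant per-grade offset
  s <- summarize_grades(tab)
  expect_true(all(s$sd < 1e-12))
  # constant offset between grades shows up exactly in the means
  expect_equal(unique(round(s$grade_means[2, ] - s$grade_means[1, ], 10)),
               0.01)
})

test_that("grades with fewer than two samples are rejected", {
  tab <- quick_table(n_per_grade = 3)
  expect_error(summarize_grades(hsgrade:::table_rows(tab, c(1, 4, 7))),
               "at least 2")
})

test_that("sliced SD exceeds intact SD at the designated bands across seeds", {
  for (seed in 1:20) {
    ti <- quick_table("intact", n_per_grade = 15, seed = seed)
    ts <- quick_table("sliced", n_per_grade = 15, seed = seed + 500)
    si <- summarize_grades(ti)
    ss <- summarize_grades(ts)
    expect_gt(mean(ss$sd), mean(si$sd))
  }
})

test_that("grade-mean spectra overlap within the between-sample SD envelope", {
  # default-size sampling model: max pairwise distance between grade means
  # stays below the aggregated +-1 SD envelope
  tab <- subset_bands(simulate_spectrum_table(synthetic_config(), "intact",
                                              seed = 17))
  mu <- sapply(1:3, function(g) colMeans(tab$spectra[tab$grade == g, ]))
  sds <- sapply(1:3, function(g) apply(tab$spectra[tab$grade == g, ], 2, sd))
  pairs <- utils::combn(3, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dist <- sqrt(sum((mu[, a] - mu[, b])^2))
    envelope <- sqrt(sum((sds[, a] + sds[, b])^2))
    expect_lt(dist, envelope)
  }
})

test_that("spectrum tables round-trip through CSV", {
  tab <- quick_table(n_per_grade = 3)
  path <- tempfile(fileext = ".csv")
  write_spectrum_table(tab, path)
  rt <- read_spectrum_table(path)
  expect_equal(rt$grade, tab$grade)
  expect_equal(rt$form, tab$form)
  expect_equal(rt$id, tab$id)
  expect_equal(rt$spectra, tab$spectra, tolerance = 1e-6)
  expect_equal(rt$wavelength, as.numeric(formatC(tab$wavelength,
                                                 format = "f", digits = 2)))
})
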