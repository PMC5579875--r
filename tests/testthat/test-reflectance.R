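frames <- function(raw, white, dark, bands = 4) {
  wl <- seq(1000, by = 50, length.out = bands)
  list(raw = spectral_cube(array(raw, c(3, 3, bands)), wl, "raw"),
       white = spectral_cube(array(white, c(3, 3, bands)), wl, "raw"),
       dark = spectral_cube(array(dark, c(3, 3, bands)), wl, "raw"))
}

test_that("calibration identities: white maps to 1, dark to 0, midpoint to ratio", {
  f <- frames(90, 90, 10)
  expect_equal(unique(as.vector(correct_reflectance(f$raw, f$white, f$dark)$data)), 1)
  f <- frames(10, 90, 10)
  expect_equal(unique(as.vector(correct_reflectance(f$raw, f$white, f$dark)$data)), 0)
  f <- frames(50, 90, 10)
  out <- correct_reflectance(f$raw, f$white, f$dark)
  expect_equal(unique(as.vector(out$data)), 0.5)
  expect_identical(out$kind, "reflectance")
})

test_that("calibration is invariant under common affine sensor rescaling", {
  set.seed(4)
  wl <- seq(1000, by = 20, length.out = 5)
  dark <- array(runif(45, 90, 110), c(3, 3, 5))
  white <- dark + array(runif(45, 1000, 3000), c(3, 3, 5))
  raw <- dark + array(runif(45), c(3, 3, 5)) * (white - dark)
  base <- correct_reflectance(spectral_cube(raw, wl, "raw"),
                              spectral_cube(white, wl, "raw"),
                              spectral_cube(dark, wl, "raw"))
  for (ab in list(c(2.5, 30), c(0.3, -5))) {
    a <- ab[1]; b <- ab[2]
    scaled <- correct_reflectance(
      spectral_cube(a * raw + b, wl, "raw"),
      spectral_cube(a * white + b, wl, "raw"),
      spectral_cube(a * dark + b, wl, "raw"))
    expect_equal(scaled$data, base$data, tolerance = 1e-10)
  }
})

test_that("degenerate references are reported with positions", {
  f <- frames(50, 90, 10)
  f$white$data[2, 3, 1] <- f$dark$data[2, 3, 1]
  expect_error(correct_reflectance(f$raw, f$white, f$dark), "2,3,1")
})

test_that("column-averaged correction uses line-collapsed references", {
  set.seed(9)
  wl <- c(1000, 1100)
  raw <- array(runif(12, 500, 600), c(3, 2, 2))
  white <- array(runif(12, 2000, 2500), c(3, 2, 2))
  dark <- array(runif(12, 90, 110), c(3, 2, 2))
  out <- correct_reflectance(spectral_cube(raw, wl, "raw"),
                             spectral_cube(white, wl, "raw"),
                             spectral_cube(dark, wl, "raw"),
                             column_average = TRUE)
  wm <- apply(white, c(2, 3), mean); dm <- apply(dark, c(2, 3), mean)
  expect_equal(out$data[2, 1, 2],
               (raw[2, 1, 2] - dm[1, 2]) / (wm[1, 2] - dm[1, 2]))
})

test_that("band subsetting keeps the closed interval and is idempotent", {
  wl <- seq(900, 1700, by = 100)
  cube <- spectral_cube(array(runif(9 * 4), c(2, 2, 9)), wl, "reflectance")
  sub <- subset_bands(cube, 975, 1646)
  expect_equal(sub$wavelength, seq(1000, 1600, 100))
  expect_equal(dim(sub$data)[3], 7)
  expect_equal(subset_bands(sub, 975, 1646)$data, sub$data)
  expect_error(subset_bands(cube, 1800, 1900), "no bands")
  # default synthetic axis retains exactly 200 bands with exact endpoints
  cfg <- synthetic_config()
  full <- spectral_cube(array(0.5, c(2, 2, 256)), cfg$wavelength,
                        "reflectance")
  kept <- subset_bands(full)
  expect_equal(dim(kept$data)[3], 200)
  expect_equal(kept$wavelength[1], 975.01)
  expect_equal(kept$wavelength[200], 1645.82)
})
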