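test_that("reflectance correction inverts the noise-free sensor model exactly", {
  cfg <- tiny_config(noise_sd = 0)
  s <- simulate_sample(cfg, 2, "sliced", seed = 5)
  r <- correct_reflectance(s$raw, s$white, s$dark)
  expect_equal(r$data, s$truth$reflectance$data, tolerance = 1e-12)
})

test_that("the same seed reproduces a bit-identical acquisition", {
  cfg <- tiny_config()
  a <- simulate_sample(cfg, 1, "intact", seed = 42)
  b <- simulate_sample(cfg, 1, "intact", seed = 42)
  expect_identical(a$raw$data, b$raw$data)
  expect_identical(a$truth$lean_fraction, b$truth$lean_fraction)
})

test_that("simulated reflectance and raw counts stay within sensor range", {
  cfg <- tiny_config()
  for (form in c("intact", "sliced")) {
    s <- simulate_sample(cfg, 3, form, seed = 8)
    expect_true(all(s$truth$reflectance$data > 0 &
                      s$truth$reflectance$data < 1))
    expect_true(all(s$raw$data > 0 & s$raw$data < 65535))
    fr <- s$truth$fractions
    expect_equal(fr$lean + fr$fat + fr$binder + fr$background,
                 matrix(1, cfg$rows, cfg$cols))
    expect_equal(fr$background == 1, !s$truth$mask)
  }
})

test_that("grade-mean ROI reflectance at a lean absorption band is ordered", {
  # expected mixture oracle: at a band where lean absorbs more than fat,
  # reflectance must increase from top (leanest) to second grade
  cfg <- table_config(scatter_gain_sd = 0, baseline_wiggle_sd = 0)
  tab <- simulate_spectrum_table(cfg, "intact", n_per_grade = 40, seed = 2)
  band <- which.min(abs(tab$wavelength - 1450))   # strong water/protein band
  m <- as.numeric(tapply(tab$spectra[, band], tab$grade, mean))
  expect_true(m[1] < m[2] && m[2] < m[3])
  # oracle value: fraction-weighted endmember mix at the grade means
  em <- cfg$endmembers
  mix <- function(p) {
    0.12 * endmember_reflectance(em$binder, tab$wavelength[band]) +
      0.88 * (p * endmember_reflectance(em$lean, tab$wavelength[band]) +
                (1 - p) * endmember_reflectance(em$fat, tab$wavelength[band]))
  }
  expected <- sapply(c(0.75, 0.60, 0.45), mix)
  expect_equal(m, expected, tolerance = 0.02)
})

test_that("vanishing dispersion and noise collapse each sample to one spectrum", {
  cfg <- tiny_config(noise_sd = 0, pixel_kappa = 1e9, fraction_kappa = 1e9,
                     scatter_gain_sd = 0, baseline_wiggle_sd = 0)
  s <- simulate_sample(cfg, 2, "intact", seed = 3)
  r <- correct_reflectance(s$raw, s$white, s$dark)
  px <- matrix(r$data, ncol = dim(r$data)[3])[which(s$truth$mask), ]
  expect_lt(max(apply(px, 2, sd)), 1e-4)
})

test_that("sliced between-sample SD dominates intact SD at every band", {
  cfg <- table_config()
  for (seed in 1:20) {
    ti <- simulate_spectrum_table(cfg, "intact", n_per_grade = 25,
                                  seed = seed)
    ts <- simulate_spectrum_table(cfg, "sliced", n_per_grade = 25,
                                  seed = seed + 1000)
    sdi <- apply(ti$spectra, 2, sd)
    sds <- apply(ts$spectra, 2, sd)
    expect_true(all(sds > sdi), info = paste("seed", seed))
  }
})

test_that("grade separation grows with the configured lean-fraction gap", {
  gaps <- c(0.04, 0.10, 0.16)
  dists <- sapply(gaps, function(g) {
    cfg <- table_config(lean_fraction_means = c(top = 0.5 + g, first = 0.5,
                                                second = 0.5 - g))
    tab <- simulate_spectrum_table(cfg, "intact", n_per_grade = 40, seed = 5)
    m1 <- colMeans(tab$spectra[tab$grade == 1, ])
    m3 <- colMeans(tab$spectra[tab$grade == 3, ])
    sqrt(sum((m1 - m3)^2))
  })
  expect_true(all(diff(dists) > 0))
})

test_that("simulate_dataset writes a consistent manifest and cube files", {
  cfg <- tiny_config(slices_per_sausage = 2)
  dir <- withr::local_tempdir()
  manifest <- simulate_dataset(cfg, dir)
  # counting oracle: 3 * n_intact * (1 + slices)
  expect_equal(nrow(manifest), 3 * 2 * (1 + 2))
  expect_equal(sum(manifest$form == "sliced"), 3 * 2 * 2)
  expect_true(all(file.exists(file.path(dir, manifest$path))))
  expect_true(all(manifest$parent_id[manifest$form == "sliced"] %in%
                    manifest$id[manifest$form == "intact"]))
  rt <- read_manifest(dir)
  expect_equal(attr(rt, "seed"), cfg$seed)
  expect_equal(rt$id, manifest$id)
  # slices inherit the parent grade
  sl <- rt[rt$form == "sliced", ]
  expect_equal(sl$grade,
               rt$grade[match(sl$parent_id, rt$id)])
})

test_that("zero slices yields intact records only", {
  cfg <- tiny_config(n_intact_per_grade = 1, slices_per_sausage = 0)
  dir <- withr::local_tempdir()
  manifest <- simulate_dataset(cfg, dir)
  expect_equal(nrow(manifest), 3)
  expect_true(all(manifest$form == "intact"))
})
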