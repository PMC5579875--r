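# independent minimal ENVI reader used as a cross-check oracle: parses the
# header with its own logic and reads the payload directly with readBin
naive_envi_read <- function(stem) {
  lines <- readLines(paste0(stem, ".hdr"))
  grab <- function(key) {
    ln <- grep(paste0("^", key, " ="), lines, value = TRUE)[1]
    trimws(sub(".*=", "", ln))
  }
  samples <- as.integer(grab("samples"))
  nlines <- as.integer(grab("lines"))
  bands <- as.integer(grab("bands"))
  dtype <- as.integer(grab("data type"))
  interleave <- grab("interleave")
  wl <- as.numeric(strsplit(gsub("[{}]", "", grab("wavelength")), ",")[[1]])
  n <- samples * nlines * bands
  con <- file(paste0(stem, ".img"), "rb")
  on.exit(close(con))
  vals <- if (dtype == 12) {
    as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                       endian = "little"))
  } else {
    readBin(con, "numeric", n, size = if (dtype == 5) 8 else 4,
            endian = "little")
  }
  arr <- if (interleave == "bil") {
    aperm(array(vals, c(samples, bands, nlines)), c(3, 1, 2))
  } else {
    aperm(array(vals, c(samples, nlines, bands)), c(2, 1, 3))
  }
  list(data = arr, wavelength = wl)
}

random_cube <- function(rows = 4, cols = 5, bands = 6, kind = "reflectance") {
  set.seed(1)
  spectral_cube(array(runif(rows * cols * bands), c(rows, cols, bands)),
                seq(1000, by = 10, length.out = bands), kind = kind)
}

test_that("write/read round trip is lossless in both interleaves", {
  cube <- random_cube()
  for (il in c("bil", "bsq")) {
    stem <- tempfile()
    write_envi(cube, stem, il, double_precision = TRUE)
    rt <- read_envi(stem)
    expect_identical(rt$data, cube$data)
    expect_identical(rt$wavelength, cube$wavelength)
    expect_identical(rt$kind, "reflectance")
  }
})

test_that("float32 storage round-trips to single precision", {
  cube <- random_cube()
  stem <- tempfile()
  write_envi(cube, stem)
  rt <- read_envi(stem)
  expect_equal(rt$data, cube$data, tolerance = 1e-6)
})

test_that("raw cubes round-trip as 16-bit integers", {
  cube <- random_cube(kind = "raw")
  cube$data <- cube$data * 4000
  stem <- tempfile()
  write_envi(cube, stem)
  rt <- read_envi(stem)
  expect_identical(rt$kind, "raw")
  expect_equal(rt$data, round(cube$data))
})

test_that("interleave is honored: independent reader agrees for BIL and BSQ", {
  cube <- random_cube(3, 7, 5)
  for (il in c("bil", "bsq")) {
    stem <- tempfile()
    write_envi(cube, stem, il, double_precision = TRUE)
    naive <- naive_envi_read(stem)
    expect_identical(naive$data, cube$data, info = il)
    expect_identical(naive$wavelength, cube$wavelength)
  }
})

test_that("header/payload inconsistencies raise distinct errors", {
  cube <- random_cube()
  stem <- tempfile()
  write_envi(cube, stem, double_precision = TRUE)
  # corrupt bands count
  hdr <- readLines(paste0(stem, ".hdr"))
  writeLines(sub("bands = 6", "bands = 10", hdr), paste0(stem, ".hdr"))
  expect_error(read_envi(stem), "wavelength list length")
  # drop wavelength list entirely
  writeLines(hdr[!grepl("^wavelength", hdr)], paste0(stem, ".hdr"))
  expect_error(read_envi(stem), "no wavelength list")
  # unknown interleave
  writeLines(sub("interleave = bil", "interleave = bip", hdr),
             paste0(stem, ".hdr"))
  expect_error(read_envi(stem), "unsupported interleave")
  # truncated payload
  writeLines(hdr, paste0(stem, ".hdr"))
  writeBin(raw(10), paste0(stem, ".img"))
  expect_error(read_envi(stem), "payload size")
  expect_error(read_envi(tempfile()), "missing ENVI header")
})

test_that("cube construction validates axis and dimensions", {
  expect_error(spectral_cube(array(0, c(2, 2, 3)), c(1000, 1010)),
               "does not match")
  expect_error(spectral_cube(array(0, c(2, 2, 2)), c(1010, 1000)),
               "strictly increasing")
})
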