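#' Hyperspectral cube container
#'
#' A 3-D intensity grid (`rows x cols x bands`) plus a strictly increasing
#' wavelength axis in nm and a kind flag distinguishing raw digital numbers
#' from reflectance.
#'
#' @param data numeric 3-D array, dimensions rows, cols, bands.
#' @param wavelength numeric axis, one value per band, strictly increasing.
#' @param kind `"raw"` or `"reflectance"`.
#' @return object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelength, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  stop_if_not(length(dim(data)) == 3, "cube data must be a 3-D array")
  stop_if_not(dim(data)[3] == length(wavelength),
              "band count (%d) does not match axis length (%d)",
              dim(data)[3], length(wavelength))
  stop_if_not(all(diff(wavelength) > 0),
              "wavelength axis must be strictly increasing")
  structure(list(data = data, wavelength = wavelength, kind = kind),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube %s> %d x %d px, %d bands (%.2f-%.2f nm)\n",
              x$kind, d[1], d[2], d[3], min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

envi_dtype <- function(kind, double_precision = FALSE) {
  if (kind == "raw") 12L else if (double_precision) 5L else 4L
}

# strip ".hdr"/".img" so callers may pass either form or a bare stem
envi_stem <- function(path) sub("\\.(hdr|img)$", "", path)

#' Write a cube as an ENVI raster
#'
#' Writes `<path>.hdr` (text header carrying dimensions, interleave, data
#' type, byte order and the wavelength list) and `<path>.img` (binary
#' payload, little-endian). Raw cubes are stored as 16-bit unsigned integers
#' (values rounded and clamped to 0-65535), reflectance cubes as 32-bit
#' floats.
#'
#' @param cube a [spectral_cube()].
#' @param path output path; any `.hdr`/`.img` extension is stripped.
#' @param interleave `"bil"` (band-interleaved-by-line) or `"bsq"`
#'   (band-sequential).
#' @param double_precision store reflectance as 64-bit floats (ENVI data
#'   type 5) for a lossless round trip instead of the conventional 32-bit.
#' @return `path` stem, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq"),
                       double_precision = FALSE) {
  interleave <- match.arg(interleave)
  stem <- envi_stem(path)
  d <- dim(cube$data)
  dtype <- envi_dtype(cube$kind, double_precision)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("cube kind = %s", cube$kind),
    sprintf("wavelength = {%s}",
            paste(formatC(cube$wavelength, format = "g", digits = 17),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(stem, ".hdr"))
  # disk order: BIL = (col, band, row); BSQ = (col, row, band)
  perm <- if (interleave == "bil") c(2, 3, 1) else c(2, 1, 3)
  vals <- as.vector(aperm(cube$data, perm))
  con <- file(paste0(stem, ".img"), "wb")
  on.exit(close(con))
  if (dtype == 12L) {
    v <- as.integer(pmin(pmax(round(vals), 0), 65535))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = if (dtype == 5L) 8 else 4,
             endian = "little")
  }
  invisible(stem)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  # join continuation lines of brace-enclosed lists
  txt <- paste(lines, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(sprintf("%s\\s*=\\s*([0-9]+)", key), txt))[[1]]
    if (length(m) < 2) NA_integer_ else as.integer(m[2])
  }
  get_str <- function(key) {
    m <- regmatches(txt, regexec(sprintf("%s\\s*=\\s*([a-zA-Z]+)", key),
                                 txt))[[1]]
    if (length(m) < 2) NA_character_ else tolower(m[2])
  }
  wl <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  wavelength <- if (length(wl) < 2) NULL else
    as.numeric(strsplit(wl[2], ",")[[1]])
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), data_type = get_num("data type"),
       interleave = get_str("interleave"), byte_order = get_num("byte order"),
       kind = get_str("cube kind"), wavelength = wavelength)
}

#' Read an ENVI raster into a [spectral_cube()]
#'
#' Supports BIL and BSQ interleaves, 16-bit unsigned (data type 12) and
#' 32-bit float (data type 4) payloads, little-endian byte order, and
#' requires a `wavelength` list in the header.
#'
#' @param path path to the `.hdr` or `.img` file (or bare stem).
#' @return a [spectral_cube()].
#' @export
read_envi <- function(path) {
  stem <- envi_stem(path)
  hdr_path <- paste0(stem, ".hdr")
  img_path <- paste0(stem, ".img")
  stop_if_not(file.exists(hdr_path), "missing ENVI header '%s'", hdr_path)
  stop_if_not(file.exists(img_path), "missing ENVI payload '%s'", img_path)
  h <- parse_envi_header(hdr_path)
  stop_if_not(!is.null(h$wavelength),
              "ENVI header '%s' has no wavelength list", hdr_path)
  stop_if_not(h$interleave %in% c("bil", "bsq"),
              "unsupported interleave '%s' (only bil/bsq)", h$interleave)
  stop_if_not(h$data_type %in% c(4L, 5L, 12L),
              "unsupported data type %d (only 4=float32, 5=float64, 12=uint16)",
              h$data_type)
  stop_if_not(identical(h$byte_order, 0L), "only little-endian supported")
  n <- h$samples * h$lines * h$bands
  stop_if_not(length(h$wavelength) == h$bands,
              "wavelength list length (%d) does not match bands (%d)",
              length(h$wavelength), h$bands)
  size <- c(`4` = 4L, `5` = 8L, `12` = 2L)[[as.character(h$data_type)]]
  stop_if_not(file.size(img_path) == n * size,
              "payload size %d does not match header dims (%d x %d x %d, %d bytes/value)",
              file.size(img_path), h$lines, h$samples, h$bands, size)
  con <- file(img_path, "rb")
  on.exit(close(con))
  vals <- if (h$data_type == 12L) {
    as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                       endian = "little"))
  } else {
    readBin(con, "numeric", n = n, size = size, endian = "little")
  }
  if (h$interleave == "bil") {
    arr <- array(vals, dim = c(h$samples, h$bands, h$lines))
    data <- aperm(arr, c(3, 1, 2))
  } else {
    arr <- array(vals, dim = c(h$samples, h$lines, h$bands))
    data <- aperm(arr, c(2, 1, 3))
  }
  kind <- if (!is.na(h$kind) && h$kind %in% c("raw", "reflectance")) h$kind
  else if (h$data_type == 12L) "raw" else "reflectance"
  spectral_cube(data, h$wavelength, kind = kind)
}
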