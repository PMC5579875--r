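#' Table of per-sample mean spectra
#'
#' The modelling dataset: one row per sample (ROI-mean reflectance), with
#' grade label (1 = top, 2 = first, 3 = second), form label and sample id.
#'
#' @param spectra numeric matrix, samples x bands.
#' @param wavelength numeric axis matching the columns.
#' @param grade integer grade labels in 1..3.
#' @param form character form labels (`"intact"`/`"sliced"`).
#' @param id character sample ids.
#' @return object of class `spectrum_table`.
#' @export
spectrum_table <- function(spectra, wavelength, grade, form, id) {
  spectra <- as.matrix(spectra)
  stop_if_not(ncol(spectra) == length(wavelength),
              "spectra width (%d) does not match axis (%d)",
              ncol(spectra), length(wavelength))
  stop_if_not(nrow(spectra) == length(grade),
              "row count (%d) does not match grade labels (%d)",
              nrow(spectra), length(grade))
  stop_if_not(all(grade %in% 1:3), "grades must be coded 1, 2, 3")
  stop_if_not(length(form) == nrow(spectra) && length(id) == nrow(spectra),
              "form/id labels must match the row count")
  dimnames(spectra) <- NULL
  structure(list(spectra = spectra, wavelength = wavelength,
                 grade = as.integer(grade), form = as.character(form),
                 id = as.character(id)),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("<spectrum_table> %d samples x %d bands (%.2f-%.2f nm)\n",
              nrow(x$spectra), ncol(x$spectra), min(x$wavelength),
              max(x$wavelength)))
  tab <- table(grade = x$grade, form = x$form)
  print(tab)
  invisible(x)
}

#' @export
dim.spectrum_table <- function(x) dim(x$spectra)

# row subset preserving labels
table_rows <- function(x, i) {
  spectrum_table(x$spectra[i, , drop = FALSE], x$wavelength,
                 x$grade[i], x$form[i], x$id[i])
}

#' Write / read a spectrum table as CSV
#'
#' Columns: `id`, `grade`, `form`, then one column per band named by its
#' wavelength at two decimals.
#'
#' @param x a [spectrum_table()].
#' @param path CSV path.
#' @return `path` (write) or a [spectrum_table()] (read).
#' @export
write_spectrum_table <- function(x, path) {
  df <- data.frame(id = x$id, grade = x$grade, form = x$form,
                   check.names = FALSE)
  sp <- as.data.frame(x$spectra)
  names(sp) <- formatC(x$wavelength, format = "f", digits = 2)
  write.csv(cbind(df, sp), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_table
#' @export
read_spectrum_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("id", "grade", "form")
  stop_if_not(all(meta %in% names(df)), "missing id/grade/form columns")
  wl_cols <- setdiff(names(df), meta)
  spectrum_table(as.matrix(df[wl_cols]), as.numeric(wl_cols),
                 df$grade, df$form, df$id)
}

# Local extrema (peaks and valleys) of a vector, greedily enforcing a
# minimum index separation, strongest curvature first.
locate_extrema <- function(y, min_separation = 5) {
  d <- diff(y)
  s <- sign(d)
  # run-length to be robust against flat stretches
  turn <- which(s[-1] * s[-length(s)] < 0) + 1L
  if (!length(turn)) return(integer(0))
  curv <- abs(diff(y, differences = 2))[pmax(turn - 1L, 1L)]
  ord <- turn[order(curv, decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Per-grade mean spectra with SD at spectral peaks and valleys
#'
#' Computes grade-mean spectra, locates the peaks and valleys of the pooled
#' mean spectrum (local extrema with a minimum five-band separation), and
#' reports the across-sample SD of each grade at those designated bands.
#'
#' @param table a [spectrum_table()] with at least two samples per grade.
#' @param min_separation minimum band separation between designated extrema.
#' @return object of class `spectrum_summary`: grade means (3 x bands),
#'   designated band indices and wavelengths, and a 3 x n_designated SD
#'   matrix.
#' @export
summarize_grades <- function(table, min_separation = 5) {
  counts <- table(factor(table$grade, levels = 1:3))
  stop_if_not(all(counts >= 2), "each grade needs at least 2 samples")
  means <- t(sapply(1:3, function(g) {
    colMeans(table$spectra[table$grade == g, , drop = FALSE])
  }))
  pooled <- colMeans(table$spectra)
  bands <- locate_extrema(pooled, min_separation)
  if (!length(bands)) bands <- which.max(abs(pooled - mean(pooled)))
  sds <- t(sapply(1:3, function(g) {
    apply(table$spectra[table$grade == g, bands, drop = FALSE], 2, sd)
  }))
  structure(list(grade_means = means, band_idx = bands,
                 band_nm = table$wavelength[bands], sd = sds,
                 wavelength = table$wavelength),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> %d designated peak/valley bands\n",
              length(x$band_idx)))
  cat("  bands (nm):", paste(round(x$band_nm, 1), collapse = ", "), "\n")
  cat(sprintf("  mean SD at designated bands: %.4f / %.4f / %.4f (grades 1/2/3)\n",
              mean(x$sd[1, ]), mean(x$sd[2, ]), mean(x$sd[3, ])))
  invisible(x)
}
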