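#' Kennard-Stone farthest-point selection
#'
#' Classic deterministic algorithm: seed with the two most mutually distant
#' samples (Euclidean distance), then repeatedly add the sample whose
#' minimum distance to the already-chosen set is largest, until `k` samples
#' are chosen. Ties break toward the lowest row index.
#'
#' @param x numeric matrix (samples x features).
#' @param k number of samples to select (2 <= k <= nrow).
#' @return integer indices in selection order.
#' @export
kennard_stone <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stop_if_not(k >= 2 && k <= n, "k must lie in [2, %d]", n)
  D <- as.matrix(dist(x))
  if (max(D) == 0) {
    warning("all samples identical; falling back to index order")
    return(seq_len(k))
  }
  # farthest pair, lowest indices on ties
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[far[, 1] < far[, 2], , drop = FALSE]
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE]
  sel <- as.integer(far[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- as.integer(which.max(mind))  # which.max takes the first on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  sel
}

#' Split a spectrum table into calibration and prediction sets
#'
#' Applies [kennard_stone()] independently within each grade, selecting
#' `round(cal_fraction * n_grade)` calibration samples per grade; the rest
#' form the prediction set. At the conventional fraction 0.74, 50 samples
#' per grade split 37/13 and 150 split 111/39.
#'
#' @param table a [spectrum_table()].
#' @param cal_fraction calibration fraction in (0, 1).
#' @return object of class `split_assignment`: `calibration` and
#'   `prediction` row indices and a per-grade count table.
#' @export
kennard_stone_split <- function(table, cal_fraction = 0.74) {
  stop_if_not(cal_fraction > 0 && cal_fraction < 1,
              "cal_fraction must lie in (0,1)")
  cal <- integer(0)
  counts <- matrix(0L, 3, 2, dimnames = list(grade = 1:3,
                                             set = c("calibration",
                                                     "prediction")))
  for (g in 1:3) {
    idx <- which(table$grade == g)
    stop_if_not(length(idx) >= 2, "grade %d has fewer than 2 samples", g)
    n_cal <- round(cal_fraction * length(idx))
    stop_if_not(n_cal >= 2, "calibration set for grade %d would have < 2 samples", g)
    stop_if_not(n_cal < length(idx),
                "grade %d: calibration fraction leaves an empty prediction set", g)
    sel <- kennard_stone(table$spectra[idx, , drop = FALSE], n_cal)
    cal <- c(cal, idx[sel])
    counts[g, ] <- c(n_cal, length(idx) - n_cal)
  }
  cal <- sort(cal)
  structure(list(calibration = cal,
                 prediction = setdiff(seq_len(nrow(table$spectra)), cal),
                 counts = counts),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment>\n")
  print(x$counts)
  invisible(x)
}
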