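#' Published reference confusion matrices
#'
#' Loads the confusion matrices of grid-tuned full-spectrum SVM and RF
#' graders reported for intact and sliced three-grade sausage sets
#' (calibration and prediction), shipped as plain CSV. Useful for checking
#' [overall_accuracy()] arithmetic against the published totals.
#'
#' @return list with one element per form/family/set combination, each
#'   containing the 3 x 3 `confusion` matrix and the
#'   `reported_total_pct`.
#' @export
reference_confusions <- function() {
  path <- system.file("extdata", "reference_confusions.csv",
                      package = "hsgrade", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (form in unique(df$form)) {
    for (family in unique(df$family)) {
      for (set in unique(df$set)) {
        rows <- df[df$form == form & df$family == family & df$set == set, ]
        rows <- rows[order(rows$true_grade), ]
        cm <- as.matrix(rows[, c("pred_1", "pred_2", "pred_3")])
        dimnames(cm) <- list(true = 1:3, predicted = 1:3)
        out[[paste(form, family, set, sep = ".")]] <-
          list(confusion = cm,
               reported_total_pct = rows$reported_total_pct[1])
      }
    }
  }
  out
}
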