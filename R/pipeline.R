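# End-to-end orchestration: dataset -> spectra -> split -> full-spectrum
# models -> wavelength selection -> reduced models -> report.

#' Pipeline run configuration
#'
#' @param dataset_dir dataset directory holding `manifest.csv`, shared
#'   `white`/`dark` references and the `cubes/` folder (see
#'   [simulate_dataset()]).
#' @param output_dir where [report_tables()] and intermediates are written
#'   by [run_full()]; `NULL` keeps everything in memory.
#' @param forms forms to process (`"intact"`, `"sliced"` or both).
#' @param selectors wavelength-selection methods (`"d2"`, `"rf"`).
#' @param families model families (`"svm"`, `"rf"`).
#' @param lo_nm,hi_nm retained spectral interval (nm).
#' @param denoise wavelet-denoise pixel spectra during extraction.
#' @param cal_fraction Kennard-Stone calibration fraction.
#' @param d2_k wavelengths kept by the second-derivative selector.
#' @param d2_window,d2_polyorder Savitzky-Golay settings.
#' @param svm_folds cross-validation folds of the SVM grid.
#' @param svm_cost_exponents,svm_gamma_exponents base-2 exponent grids of
#'   the SVM search.
#' @param rf_reps seeded repetitions of the RF grid.
#' @param rf_trees,rf_mtry random-forest hyperparameter grids.
#' @param models_per_round forests per elimination round of [select_by_rf()].
#' @param selection_trees,selection_mtry forest size and features-per-split
#'   of the selection forests (the many cheap forests of the elimination
#'   rounds; 50 trees matches the tuned forest size of the reference
#'   setting, `NULL` mtry means the square-root default).
#' @param eliminate_per_round,stop_at elimination schedule.
#' @param seed master seed; every random stage derives its stream from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(dataset_dir = NULL, output_dir = NULL,
                       forms = c("intact", "sliced"),
                       selectors = c("d2", "rf"),
                       families = c("svm", "rf"),
                       lo_nm = 975.01, hi_nm = 1645.82,
                       denoise = TRUE, cal_fraction = 0.74, d2_k = 14,
                       d2_window = 11, d2_polyorder = 3,
                       svm_folds = 5,
                       svm_cost_exponents = svm_exponent_grid(),
                       svm_gamma_exponents = svm_exponent_grid(),
                       rf_reps = 10,
                       rf_trees = seq(50, 500, by = 50),
                       rf_mtry = seq(10, 100, by = 10),
                       models_per_round = 100,
                       selection_trees = 50, selection_mtry = NULL,
                       eliminate_per_round = 20,
                       stop_at = 20, seed = 17) {
  forms <- match.arg(forms, several.ok = TRUE)
  selectors <- match.arg(selectors, several.ok = TRUE)
  families <- match.arg(families, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Extract ROI-mean spectra for every cube of a dataset
#'
#' For each manifest record: read the raw ENVI cube, correct it against the
#' dataset's shared white/dark references, segment the sample, wavelet-
#' denoise the masked pixel spectra and average them.
#'
#' @param dir dataset directory.
#' @param denoise apply [denoise_spectrum()] pixel-wise.
#' @param segmentation_band band (nm) used by [segment_sample()].
#' @return a [spectrum_table()] on the full instrument axis.
#' @export
extract_spectra <- function(dir, denoise = TRUE, segmentation_band = 1100) {
  manifest <- read_manifest(dir)
  white <- read_envi(file.path(dir, "white"))
  dark <- read_envi(file.path(dir, "dark"))
  spectra <- matrix(NA_real_, nrow(manifest), length(white$wavelength))
  for (i in seq_len(nrow(manifest))) {
    raw <- read_envi(file.path(dir, envi_stem(manifest$path[i])))
    refl <- correct_reflectance(raw, white, dark)
    mask <- segment_sample(refl, band_nm = segmentation_band)
    spectra[i, ] <- extract_mean_spectrum(refl, mask, denoise = denoise)
  }
  spectrum_table(spectra, white$wavelength, manifest$grade, manifest$form,
                 manifest$id)
}

fit_family <- function(family, tbl, config, seed) {
  if (family == "svm") {
    train_svm_grid(tbl, cost_exponents = config$svm_cost_exponents,
                   gamma_exponents = config$svm_gamma_exponents,
                   folds = config$svm_folds, seed = seed)
  } else {
    train_rf_grid(tbl, num_trees = config$rf_trees, mtry = config$rf_mtry,
                  reps = config$rf_reps, seed = seed)
  }
}

model_params <- function(model) {
  if (model$family == "svm") {
    sprintf("%.4f, %.4f", model$cost, model$gamma)
  } else {
    sprintf("%d, %d", model$num_trees, model$mtry)
  }
}

#' Run the full grading workflow
#'
#' For each requested form: band subsetting, Kennard-Stone split,
#' grid-tuned full-spectrum SVM and RF graders, second-derivative and
#' RF-recursive wavelength selection on the calibration set, reduced-
#' variable graders on each selected subset, and evaluation of every model
#' on both sets.
#'
#' @param config a [run_config()].
#' @param tables optional named list of pre-extracted [spectrum_table()]s
#'   (one per form, full axis); when `NULL` they are extracted from
#'   `config$dataset_dir`.
#' @return object of class `run_report`: `results` (one row per form x
#'   feature set x family with parameters and accuracies), `evals`,
#'   `subsets`, `splits`, `reduction` and a text `log`.
#' @export
run_full <- function(config, tables = NULL) {
  t0 <- Sys.time()
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, sprintf("[%.1fs] %s",
                           as.numeric(difftime(Sys.time(), t0, units = "secs")),
                           msg))
    message(msg)
  }
  say("master seed %d; SVM exponent grid 2^[-8..8] step 0.8", config$seed)

  stage <- "extract"
  res <- try({
    if (is.null(tables)) {
      stop_if_not(!is.null(config$dataset_dir),
                  "run_config needs dataset_dir (or pass `tables`)")
      full <- extract_spectra(config$dataset_dir, denoise = config$denoise)
      tables <- lapply(config$forms, function(f) {
        table_rows(full, which(full$form == f))
      })
      names(tables) <- config$forms
    }
    TRUE
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    stop(sprintf("stage '%s' failed: %s", stage, attr(res, "condition")$message),
         call. = FALSE)
  }

  results <- list(); evals <- list(); subsets <- list(); splits <- list()
  n_full_by_form <- list()
  tryCatch(
  for (form in config$forms) {
    tbl <- tables[[form]]
    stop_if_not(!is.null(tbl), "no table for form '%s'", form)
    stop_if_not(all(1:3 %in% tbl$grade),
                "form '%s' is missing one or more grades", form)
    tbl <- subset_bands(tbl, config$lo_nm, config$hi_nm)
    n_full <- ncol(tbl$spectra)
    n_full_by_form[[form]] <- n_full
    say("form %s: %d samples, %d bands retained", form, nrow(tbl$spectra),
        n_full)

    stage <- paste0(form, "/split")
    split <- kennard_stone_split(tbl, config$cal_fraction)
    splits[[form]] <- split
    cal <- table_rows(tbl, split$calibration)
    pred <- table_rows(tbl, split$prediction)
    say("form %s: split %s calibration / %s prediction per grade", form,
        paste(split$counts[, 1], collapse = "/"),
        paste(split$counts[, 2], collapse = "/"))

    feature_sets <- list(full = seq_len(n_full))
    full_models <- list()
    for (family in config$families) {
      stage <- paste(form, "full", family, sep = "/")
      mdl <- fit_family(family, cal, config,
                        derive_seed(config$seed, match(form, config$forms) * 100 +
                                      match(family, config$families)))
      say("form %s: full-spectrum %s -> %s", form, family, model_params(mdl))
      full_models[[family]] <- mdl
      for (set in c("calibration", "prediction")) {
        ev <- evaluate(mdl, if (set == "calibration") cal else pred)
        key <- paste(form, "full", family, set, sep = ".")
        evals[[key]] <- ev
        results[[length(results) + 1L]] <- data.frame(
          form = form, feature_set = "full", family = family,
          n_features = n_full, parameters = model_params(mdl), set = set,
          accuracy = ev$accuracy)
      }
    }

    for (selector in config$selectors) {
      stage <- paste(form, "select", selector, sep = "/")
      sub <- if (selector == "d2") {
        d2 <- second_derivative(cal, window = config$d2_window,
                                polyorder = config$d2_polyorder)
        select_by_d2(d2, cal$wavelength, cal$grade, k = config$d2_k)
      } else {
        sc <- selection_config(
          models_per_round = config$models_per_round,
          eliminate_per_round = config$eliminate_per_round,
          stop_at = config$stop_at,
          num_trees = config$selection_trees,
          mtry = config$selection_mtry,
          seed = derive_seed(config$seed, match(form, config$forms) * 1000))
        suppressWarnings(select_by_rf(cal, sc))
      }
      subsets[[paste(form, selector, sep = ".")]] <- sub
      say("form %s: selector %s kept %d bands (%s nm)", form, selector,
          length(sub$indices), paste(round(sub$wavelength_nm), collapse = ", "))

      cal_red <- spectrum_table(cal$spectra[, sub$indices, drop = FALSE],
                                cal$wavelength[sub$indices], cal$grade,
                                cal$form, cal$id)
      pred_red <- spectrum_table(pred$spectra[, sub$indices, drop = FALSE],
                                 pred$wavelength[sub$indices], pred$grade,
                                 pred$form, pred$id)
      for (family in config$families) {
        stage <- paste(form, selector, family, sep = "/")
        mdl <- fit_family(family, cal_red, config,
                          derive_seed(config$seed,
                                      match(form, config$forms) * 100 +
                                        10 * match(selector, config$selectors) +
                                        match(family, config$families)))
        say("form %s: %s-reduced %s -> %s", form, selector, family,
            model_params(mdl))
        for (set in c("calibration", "prediction")) {
          ev <- evaluate(mdl, if (set == "calibration") cal_red else pred_red)
          key <- paste(form, selector, family, set, sep = ".")
          evals[[key]] <- ev
          results[[length(results) + 1L]] <- data.frame(
            form = form, feature_set = selector, family = family,
            n_features = length(sub$indices), parameters = model_params(mdl),
            set = set, accuracy = ev$accuracy)
        }
      }
    }
  },
  error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  results <- do.call(rbind, results)
  reduction <- do.call(rbind, lapply(names(subsets), function(k) {
    form_k <- strsplit(k, ".", fixed = TRUE)[[1]][1]
    nf <- n_full_by_form[[form_k]]
    ns <- length(subsets[[k]]$indices)
    data.frame(selection = k, n_full = nf, n_selected = ns,
               reduction_pct = round_half_up(100 * (nf - ns) / nf, 2))
  }))
  if (is.null(reduction)) {
    reduction <- data.frame(selection = character(0), n_full = integer(0),
                            n_selected = integer(0),
                            reduction_pct = numeric(0))
  }
  report <- structure(list(results = results, evals = evals,
                           subsets = subsets, splits = splits,
                           reduction = reduction, config = config, log = log),
                      class = "run_report")
  if (!is.null(config$output_dir)) {
    report_tables(report, config$output_dir)
    writeLines(log, file.path(config$output_dir, "run.log"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  wide <- stats::reshape(x$results,
                         idvar = c("form", "feature_set", "family",
                                   "n_features", "parameters"),
                         timevar = "set", direction = "wide")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  print(wide, row.names = FALSE)
  if (nrow(x$reduction)) {
    cat("\nData reduction:\n")
    print(x$reduction, row.names = FALSE)
  }
  invisible(x)
}

#' Write the report as CSV tables
#'
#' `table1.csv` holds the full-spectrum confusion matrices and totals (one
#' row per form x family x set x true grade), `table2.csv` one row per
#' selected wavelength, `table3.csv` the reduced-variable model accuracies.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
report_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  t1 <- data.frame(form = character(0), family = character(0),
                   parameters = character(0), set = character(0),
                   true_grade = integer(0), pred_1 = integer(0),
                   pred_2 = integer(0), pred_3 = integer(0),
                   total_pct = numeric(0))
  rows <- report$results
  if (!is.null(rows) && nrow(rows)) {
    full <- rows[rows$feature_set == "full", ]
    for (i in seq_len(nrow(full))) {
      key <- paste(full$form[i], "full", full$family[i], full$set[i],
                   sep = ".")
      cm <- report$evals[[key]]$confusion
      for (g in 1:3) {
        t1 <- rbind(t1, data.frame(
          form = full$form[i], family = full$family[i],
          parameters = full$parameters[i], set = full$set[i], true_grade = g,
          pred_1 = cm[g, 1], pred_2 = cm[g, 2], pred_3 = cm[g, 3],
          total_pct = full$accuracy[i]))
      }
    }
  }
  write.csv(t1, file.path(dir, "table1.csv"), row.names = FALSE)

  t2 <- data.frame(method = character(0), form = character(0),
                   rank = integer(0), band_index = integer(0),
                   wavelength_nm = numeric(0))
  for (key in names(report$subsets)) {
    sub <- report$subsets[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    t2 <- rbind(t2, data.frame(
      method = sub$method, form = parts[1],
      rank = seq_along(sub$indices), band_index = sub$indices,
      wavelength_nm = sub$wavelength_nm))
  }
  write.csv(t2, file.path(dir, "table2.csv"), row.names = FALSE)

  t3 <- data.frame(form = character(0), selector = character(0),
                   family = character(0), parameters = character(0),
                   n_features = integer(0), set = character(0),
                   accuracy = numeric(0))
  if (!is.null(rows) && nrow(rows)) {
    red <- rows[rows$feature_set != "full", ]
    if (nrow(red)) {
      t3 <- data.frame(form = red$form, selector = red$feature_set,
                       family = red$family, parameters = red$parameters,
                       n_features = red$n_features, set = red$set,
                       accuracy = red$accuracy)
    }
  }
  write.csv(t3, file.path(dir, "table3.csv"), row.names = FALSE)
  invisible(dir)
}
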