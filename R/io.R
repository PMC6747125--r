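# CSV/TSV/JSON readers and writers for descriptor tables, affinity
# measurements, models, predictions, evaluation tables and search reports.
#
# Dialects: CSV/TSV are comma/tab separated, UTF-8, "." decimal, header
# mandatory. Complex ids are free text matched exactly (the en-dash in ids
# like "mWnt3a-mFzd5" is preserved verbatim). All writers are
# deterministic: no timestamps, bit-identical output for identical input.

MEASUREMENT_SET_LABELS <- c("training", "test")

#' Descriptor class annotation of a descriptor table
#'
#' Every descriptor column carries a class: `"protein-protein"` for
#' docking/statistical-potential scores of the protein-protein interface,
#' `"lipid-protein"` for MM-GBSA-derived terms describing the lipid-CRD
#' contribution. The annotation lives as an attribute on the table; when
#' absent, a provenance heuristic assigns `"lipid-protein"` to descriptors
#' whose name starts with `MMGBSA` and `"protein-protein"` to the rest.
#'
#' @param descriptors Data frame with a `complex` column plus numeric
#'   descriptor columns.
#' @return Named character vector descriptor name -> class.
#' @export
descriptor_classes <- function(descriptors) {
  stopifnot(is.data.frame(descriptors))
  cls <- attr(descriptors, "descriptor_classes")
  desc_names <- setdiff(trimws(names(descriptors)), "complex")
  if (is.null(cls)) {
    return(stats::setNames(
      ifelse(grepl("^MMGBSA", desc_names), "lipid-protein",
             "protein-protein"),
      desc_names))
  }
  missing <- setdiff(desc_names, names(cls))
  if (length(missing) > 0L) {
    stop("descriptor(s) without a class annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cls[desc_names]
}

#' Attach a descriptor class annotation
#'
#' @param descriptors Descriptor table.
#' @param classes Named character vector descriptor name -> class (values
#'   `"protein-protein"` or `"lipid-protein"`), or a path to a JSON file
#'   holding such a mapping.
#' @return The table with the annotation attached.
#' @export
set_descriptor_classes <- function(descriptors, classes) {
  stopifnot(is.data.frame(descriptors))
  if (is.character(classes) && length(classes) == 1L && is.null(names(classes)) &&
      file.exists(classes)) {
    classes <- unlist(jsonlite::read_json(classes, simplifyVector = TRUE))
  }
  stopifnot(is.character(classes), !is.null(names(classes)))
  if (!all(classes %in% DESCRIPTOR_CLASSES)) {
    stop("descriptor classes must be one of: ",
         paste(DESCRIPTOR_CLASSES, collapse = ", "), call. = FALSE)
  }
  attr(descriptors, "descriptor_classes") <- classes
  descriptors
}

#' Read a descriptor table from CSV
#'
#' Expects a header row whose first column is `complex` followed by one
#' numeric column per descriptor (interface scoring-function export
#' style). Header names are normalised for surrounding whitespace only;
#' matching elsewhere is exact-string.
#'
#' @param path CSV file path.
#' @param classes Optional class annotation passed to
#'   [set_descriptor_classes()]; when `NULL` the `MMGBSA` prefix heuristic
#'   applies lazily.
#' @return Data frame with `complex` plus numeric descriptor columns, row
#'   order preserved.
#' @export
read_descriptor_table <- function(path, classes = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE, colClasses = "character")
  names(raw) <- trimws(names(raw))
  if (ncol(raw) < 2L || names(raw)[1L] != "complex") {
    stop("malformed header in ", path,
         ": first column must be `complex` followed by descriptor columns",
         call. = FALSE)
  }
  if (anyDuplicated(names(raw))) {
    stop("malformed header in ", path, ": duplicate column name(s): ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$complex)) {
    stop("duplicate complex id(s) in ", path, ": ",
         paste(unique(raw$complex[duplicated(raw$complex)]), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(complex = raw$complex, stringsAsFactors = FALSE)
  for (col in names(raw)[-1L]) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0L) {
      stop("non-numeric or non-finite value in ", path, ", column `", col,
           "`, data row ", bad[1L], " (value: \"", raw[[col]][bad[1L]],
           "\")", call. = FALSE)
    }
    out[[col]] <- vals
  }
  if (!is.null(classes)) {
    out <- set_descriptor_classes(out, classes)
  }
  out
}

#' Write a descriptor table to CSV
#'
#' @param descriptors Descriptor table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(descriptors, path) {
  stopifnot(is.data.frame(descriptors))
  utils::write.csv(descriptors, path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read affinity measurements from CSV
#'
#' Expects columns `complex`, `kd_nM`, optional `kd_err_nM`, and `set`
#' with values `training` or `test`.
#'
#' @param path CSV file path.
#' @return Data frame of measurements; `kd_err_nM` is `NA` when the column
#'   is absent.
#' @export
read_measurements <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  names(raw) <- trimws(names(raw))
  needed <- c("complex", "kd_nM", "set")
  if (!all(needed %in% names(raw))) {
    stop("measurement file ", path, " must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(raw$kd_nM) || any(!is.finite(raw$kd_nM)) ||
      any(raw$kd_nM <= 0)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(raw$kd_nM))) |
                   suppressWarnings(as.numeric(raw$kd_nM)) <= 0)
    stop("non-positive or non-numeric kd_nM in ", path, ", data row ",
         if (length(bad)) bad[1L] else "?", call. = FALSE)
  }
  if (!all(raw$set %in% MEASUREMENT_SET_LABELS)) {
    stop("unknown set label(s) in ", path, ": ",
         paste(unique(setdiff(raw$set, MEASUREMENT_SET_LABELS)),
               collapse = ", "),
         "; expected training/test", call. = FALSE)
  }
  err <- if ("kd_err_nM" %in% names(raw)) {
    e <- raw$kd_err_nM
    if (any(!is.na(e) & e < 0)) {
      stop("negative kd_err_nM in ", path, call. = FALSE)
    }
    e
  } else {
    rep(NA_real_, nrow(raw))
  }
  data.frame(complex = as.character(raw$complex),
             kd_nM = as.numeric(raw$kd_nM),
             kd_err_nM = as.numeric(err),
             set = raw$set,
             stringsAsFactors = FALSE)
}

#' Write affinity measurements to CSV
#'
#' @param measurements Measurement data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(is.data.frame(measurements))
  utils::write.csv(measurements, path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Write predictions to TSV
#'
#' Columns: `complex_id`, `delta_G_kcal_mol`, `Kd_nM`, `range`.
#'
#' @param predictions Data frame from [predict_affinity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(is.data.frame(predictions),
            all(c("complex", "delta_G_kcal_mol", "Kd_nM", "range") %in%
                  names(predictions)))
  out <- data.frame(complex_id = predictions$complex,
                    delta_G_kcal_mol = predictions$delta_G_kcal_mol,
                    Kd_nM = predictions$Kd_nM,
                    range = as.character(predictions$range),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read predictions from TSV
#'
#' @param path TSV written by [write_predictions()].
#' @return Data frame with columns `complex`, `delta_G_kcal_mol`, `Kd_nM`,
#'   `range` (ordered factor).
#' @export
read_predictions <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  needed <- c("complex_id", "delta_G_kcal_mol", "Kd_nM", "range")
  if (!all(needed %in% names(raw))) {
    stop("prediction file ", path, " must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  data.frame(complex = as.character(raw$complex_id),
             delta_G_kcal_mol = as.numeric(raw$delta_G_kcal_mol),
             Kd_nM = as.numeric(raw$Kd_nM),
             range = factor(raw$range, levels = affinity_range_levels(),
                            ordered = TRUE),
             stringsAsFactors = FALSE)
}

#' Write an evaluation table to TSV
#'
#' @param evaluation Data frame from [evaluation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_table <- function(evaluation, path) {
  stopifnot(is.data.frame(evaluation))
  out <- evaluation
  out$range_exp <- as.character(out$range_exp)
  out$range_pred <- as.character(out$range_pred)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a model-search report to JSON
#'
#' Serialises the configuration, the diagnostics counters and the ranked
#' feasible candidates (each with its full model definition and metrics).
#'
#' @param result An `affinity_search_result` from [search_models()].
#' @param path Output path.
#' @param max_models Optional cap on the number of candidates written.
#' @return `path`, invisibly.
#' @export
write_search_report <- function(result, path, max_models = Inf) {
  stopifnot(inherits(result, "affinity_search_result"))
  n <- min(nrow(result$candidates), max_models)
  candidates <- lapply(seq_len(n), function(i) {
    m <- result$models[[i]]
    list(model = list(name = m$name, intercept = m$intercept,
                      terms = m$terms),
         rmse_train = result$candidates$rmse_train[i],
         rmse_test = result$candidates$rmse_test[i],
         inexp_train = result$candidates$inexp_train[i],
         inexp_test = result$candidates$inexp_test[i])
  })
  doc <- list(config = unclass(result$config),
              diagnostics = result$diagnostics,
              candidates = candidates)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a range-agreement summary to JSON
#'
#' @param agreement A `range_agreement` from [compare_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_range_agreement <- function(agreement, path) {
  stopifnot(inherits(agreement, "range_agreement"))
  jsonlite::write_json(unclass(agreement), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
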