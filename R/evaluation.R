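# Model evaluation: RMSE, per-complex evaluation tables and the
# between-model affinity-range agreement statistic.

#' Root-mean-square error between paired free energies
#'
#' @param predicted,observed Numeric vectors of equal non-zero length,
#'   paired by complex.
#' @return RMSE in the units of the inputs (kcal/mol here).
#' @export
rmse <- function(predicted, observed) {
  if (!is.numeric(predicted) || !is.numeric(observed)) {
    stop("`predicted` and `observed` must be numeric", call. = FALSE)
  }
  if (length(predicted) != length(observed)) {
    stop("length mismatch: ", length(predicted), " predicted vs ",
         length(observed), " observed", call. = FALSE)
  }
  if (length(predicted) == 0L) {
    stop("cannot compute RMSE of zero pairs", call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' Per-complex evaluation table
#'
#' Builds a per-complex comparison of predicted and experimental
#' affinities: experimental free energy (from the measured Kd), predicted
#' free energy, their absolute difference, both dissociation constants,
#' both ordinal affinity ranges, and a flag marking complexes whose
#' experimental and predicted Kd fall in different ranges.
#'
#' @param predictions Data frame with columns `complex` and
#'   `delta_G_kcal_mol`.
#' @param measurements Data frame with columns `complex`, `kd_nM` and
#'   optionally `set`.
#' @param temperature Temperature in Kelvin.
#' @return Data frame with columns `complex`, `dg_exp`, `dg_pred`,
#'   `abs_diff`, `kd_exp_nM`, `kd_pred_nM`, `range_exp`, `range_pred`,
#'   `range_mismatch`, `set`; one row per measurement, in measurement
#'   order.
#' @export
evaluation_table <- function(predictions, measurements, temperature = 298) {
  stopifnot(is.data.frame(predictions), is.data.frame(measurements))
  if (!all(c("complex", "delta_G_kcal_mol") %in% names(predictions))) {
    stop("predictions must have columns complex, delta_G_kcal_mol",
         call. = FALSE)
  }
  if (!all(c("complex", "kd_nM") %in% names(measurements))) {
    stop("measurements must have columns complex, kd_nM", call. = FALSE)
  }
  idx <- match(measurements$complex, predictions$complex)
  if (anyNA(idx)) {
    stop("no prediction for complex id(s): ",
         paste(measurements$complex[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(predictions$complex, measurements$complex)
  if (length(extra) > 0L) {
    stop("prediction complex id(s) without measurement: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  dg_exp <- delta_g_from_kd(measurements$kd_nM, temperature)
  dg_pred <- predictions$delta_G_kcal_mol[idx]
  kd_pred <- kd_from_delta_g(dg_pred, temperature)
  range_exp <- classify_affinity(measurements$kd_nM)
  range_pred <- classify_affinity(kd_pred)
  data.frame(
    complex = as.character(measurements$complex),
    dg_exp = dg_exp,
    dg_pred = dg_pred,
    abs_diff = abs(dg_exp - dg_pred),
    kd_exp_nM = measurements$kd_nM,
    kd_pred_nM = kd_pred,
    range_exp = range_exp,
    range_pred = range_pred,
    range_mismatch = as.character(range_exp) != as.character(range_pred),
    set = if ("set" %in% names(measurements)) {
      as.character(measurements$set)
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE
  )
}

#' Affinity-range agreement between two prediction sets
#'
#' Compares two sets of predictions for the same complexes and reports the
#' fraction predicted in the same ordinal affinity range, in adjacent
#' ranges (ordinal distance exactly 1), and more than one range apart.
#'
#' @param predictions_a,predictions_b Data frames with a `complex` column
#'   and either a `range` column or a `Kd_nM` column from which ranges are
#'   derived. Must cover the same complex ids.
#' @return A list of class `range_agreement` with fields `n_compared`,
#'   `frac_same`, `frac_adjacent`, `frac_apart` (summing to 1).
#' @export
compare_models <- function(predictions_a, predictions_b) {
  ra <- prediction_ranges(predictions_a, "predictions_a")
  rb <- prediction_ranges(predictions_b, "predictions_b")
  only_a <- setdiff(names(ra), names(rb))
  only_b <- setdiff(names(rb), names(ra))
  if (length(only_a) > 0L || length(only_b) > 0L) {
    stop("prediction sets cover different complexes; unmatched: ",
         paste(c(only_a, only_b), collapse = ", "), call. = FALSE)
  }
  if (length(ra) == 0L) {
    stop("no complexes to compare", call. = FALSE)
  }
  d <- range_distance(ra, rb[names(ra)])
  structure(list(
    n_compared = length(d),
    frac_same = mean(d == 0),
    frac_adjacent = mean(d == 1),
    frac_apart = mean(d > 1)
  ), class = "range_agreement")
}

#' @export
print.range_agreement <- function(x, ...) {
  cat(sprintf(
    "Range agreement over %d complexes: %.1f%% same, %.1f%% adjacent, %.1f%% more than one range apart\n",
    x$n_compared, 100 * x$frac_same, 100 * x$frac_adjacent,
    100 * x$frac_apart))
  invisible(x)
}

# Named character vector complex id -> range label.
prediction_ranges <- function(predictions, what) {
  stopifnot(is.data.frame(predictions))
  if (!"complex" %in% names(predictions)) {
    stop(what, " must have a `complex` column", call. = FALSE)
  }
  if (anyDuplicated(predictions$complex)) {
    stop(what, " has duplicate complex id(s)", call. = FALSE)
  }
  r <- if ("range" %in% names(predictions)) {
    as.character(predictions$range)
  } else if ("Kd_nM" %in% names(predictions)) {
    as.character(classify_affinity(predictions$Kd_nM))
  } else {
    stop(what, " must have a `range` or `Kd_nM` column", call. = FALSE)
  }
  stats::setNames(r, as.character(predictions$complex))
}
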