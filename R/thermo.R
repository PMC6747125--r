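# Thermodynamic conversion between dissociation constants and binding free
# energies, plus ordinal affinity-range classification.

#' Gas constant in kcal K^-1 mol^-1
#'
#' The value used throughout the package for converting between dissociation
#' constants and binding free energies: 1.987 x 10^-3 kcal K^-1 mol^-1.
#'
#' @format A length-one numeric.
#' @export
GAS_CONSTANT_KCAL <- 1.987e-3

#' Thermal energy RT in kcal/mol
#'
#' @param temperature Temperature in Kelvin (default 298 K, standard
#'   conditions).
#' @return RT in kcal/mol (about 0.5921 kcal/mol at 298 K).
#' @export
rt_kcal <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  GAS_CONSTANT_KCAL * temperature
}

#' Ordinal affinity-range labels
#'
#' The five ordinal affinity classes used to summarise dissociation
#' constants, from weakest (`-`, Kd above 400 nM) to strongest (`++++`,
#' Kd below 10 nM).
#'
#' @return Character vector of the five labels in increasing affinity order.
#' @export
affinity_range_levels <- function() {
  c("-", "+", "++", "+++", "++++")
}

#' Binding free energy from a dissociation constant
#'
#' Converts Kd (nM) to a Gibbs free energy of binding via
#' \eqn{\Delta G = RT \ln K_d}, with Kd expressed in molar units inside the
#' logarithm. Tighter binding (smaller Kd) gives a more negative \eqn{\Delta G}.
#'
#' @param kd_nM Dissociation constant(s) in nanomolar; strictly positive.
#' @param temperature Temperature in Kelvin (default 298).
#' @return Free energy in kcal/mol, same length as `kd_nM`.
#' @examples
#' delta_g_from_kd(3.1)    # about -11.60 kcal/mol
#' delta_g_from_kd(1e9)    # 1 M reference state: 0
#' @export
delta_g_from_kd <- function(kd_nM, temperature = 298) {
  if (!is.numeric(kd_nM)) {
    stop("`kd_nM` must be numeric", call. = FALSE)
  }
  if (length(kd_nM) > 0L && (any(!is.finite(kd_nM)) || any(kd_nM <= 0))) {
    stop("`kd_nM` must be strictly positive and finite", call. = FALSE)
  }
  rt_kcal(temperature) * log(kd_nM * 1e-9)
}

#' Dissociation constant from a binding free energy
#'
#' Exact inverse of [delta_g_from_kd()]: \eqn{K_d = \exp(\Delta G / RT)},
#' returned in nM.
#'
#' @param dg Free energy (kcal/mol); any real value.
#' @param temperature Temperature in Kelvin (default 298).
#' @return Dissociation constant(s) in nM.
#' @examples
#' kd_from_delta_g(-10.87)  # about 10.7 nM
#' kd_from_delta_g(0)       # 1e9 nM = 1 M
#' @export
kd_from_delta_g <- function(dg, temperature = 298) {
  if (!is.numeric(dg)) {
    stop("`dg` must be numeric", call. = FALSE)
  }
  exp(dg / rt_kcal(temperature)) * 1e9
}

#' Classify a dissociation constant into an ordinal affinity range
#'
#' Bins Kd values into the five ordinal classes: below 10 nM `++++`,
#' 10--40 nM `+++`, 40--100 nM `++`, 100--400 nM `+`, above 400 nM `-`.
#' A boundary value belongs to the higher-affinity bin that prints it as an
#' endpoint: exactly 10 or 40 nM is `+++`, 100 nM is `++`, 400 nM is `+`.
#'
#' @param kd_nM Dissociation constant(s) in nM; strictly positive.
#' @return Ordered factor over [affinity_range_levels()].
#' @examples
#' classify_affinity(c(5.4, 15.7, 500))  # ++++, +++, -
#' @export
classify_affinity <- function(kd_nM) {
  if (!is.numeric(kd_nM)) {
    stop("`kd_nM` must be numeric", call. = FALSE)
  }
  if (length(kd_nM) > 0L && (any(!is.finite(kd_nM)) || any(kd_nM <= 0))) {
    stop("`kd_nM` must be strictly positive and finite", call. = FALSE)
  }
  lv <- affinity_range_levels()
  idx <- ifelse(kd_nM < 10, 5L,
         ifelse(kd_nM <= 40, 4L,
         ifelse(kd_nM <= 100, 3L,
         ifelse(kd_nM <= 400, 2L, 1L))))
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Ordinal distance between affinity ranges
#'
#' Absolute difference of the ordinal levels of two range classes; 0 for the
#' same range, 1 for adjacent ranges.
#'
#' @param a,b Range labels: ordered factors from [classify_affinity()] or
#'   character vectors over [affinity_range_levels()]. Recycled to a common
#'   length.
#' @return Non-negative integer vector.
#' @examples
#' range_distance("++++", "+")  # 3
#' @export
range_distance <- function(a, b) {
  abs(range_level(a) - range_level(b))
}

# Ordinal level 0..4 of a range label; errors on unknown labels.
range_level <- function(x) {
  x <- as.character(x)
  lv <- affinity_range_levels()
  bad <- !is.na(x) & !(x %in% lv)
  if (any(bad)) {
    stop("unknown affinity range label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  match(x, lv) - 1L
}
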