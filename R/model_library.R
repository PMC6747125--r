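# Linear binding-energy models over named interface descriptors.
#
# A model is an intercept plus a weighted sum of descriptor values. Each
# descriptor carries a class label: "protein-protein" for docking/statistical
# potentials scored on the protein-protein interface, "lipid-protein" for the
# MM-GBSA-derived term capturing the Wnt palmitoleate-CRD contribution.

DESCRIPTOR_CLASSES <- c("protein-protein", "lipid-protein")

#' Construct a linear binding-affinity model
#'
#' @param name Model label.
#' @param terms Data frame with columns `descriptor` (unique, non-empty
#'   names), `coefficient` (kcal/mol per descriptor unit) and `class`
#'   (`"protein-protein"` or `"lipid-protein"`).
#' @param intercept Intercept in kcal/mol.
#' @return An object of class `linear_affinity_model`.
#' @export
linear_affinity_model <- function(name, terms, intercept) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  required <- c("descriptor", "coefficient", "class")
  if (!all(required %in% names(terms))) {
    stop("`terms` must have columns descriptor, coefficient, class",
         call. = FALSE)
  }
  terms <- terms[required]
  terms$descriptor <- trimws(as.character(terms$descriptor))
  if (nrow(terms) < 1L) {
    stop("a model needs at least one term", call. = FALSE)
  }
  if (any(!nzchar(terms$descriptor))) {
    stop("descriptor names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(terms$descriptor)) {
    stop("duplicate descriptor name in model: ",
         terms$descriptor[duplicated(terms$descriptor)][1L], call. = FALSE)
  }
  if (!is.numeric(terms$coefficient) || any(!is.finite(terms$coefficient))) {
    stop("coefficients must be finite numbers", call. = FALSE)
  }
  if (!all(terms$class %in% DESCRIPTOR_CLASSES)) {
    stop("descriptor class must be one of: ",
         paste(DESCRIPTOR_CLASSES, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  rownames(terms) <- NULL
  structure(list(name = name, terms = terms, intercept = as.numeric(intercept)),
            class = "linear_affinity_model")
}

#' @export
print.linear_affinity_model <- function(x, ...) {
  cat("Linear binding-affinity model:", x$name, "\n")
  sign_chr <- ifelse(x$terms$coefficient < 0, "-", "+")
  cat("  dG =",
      paste(sign_chr, format(abs(x$terms$coefficient)), "x",
            x$terms$descriptor, collapse = " "),
      if (x$intercept < 0) "-" else "+", format(abs(x$intercept)),
      "(kcal/mol)\n")
  cat("  lipid-protein term(s):",
      paste(x$terms$descriptor[x$terms$class == "lipid-protein"],
            collapse = ", "), "\n")
  invisible(x)
}

#' Published Wnt-Frizzled CRD binding-affinity models
#'
#' Returns the four published linear models with their printed coefficients:
#'
#' * `previous` -- the earlier model combining three protein-protein docking
#'   potentials (AP_calRW, HBOND2, FIREDOCK_AB) with the MM-GBSA van der
#'   Waals component as the lipid-protein term. Its lipid term typically
#'   contributes unfavourably because the (typically negative) vdW energy
#'   meets a negative coefficient.
#' * `model1`, `model2`, `model3` -- four-descriptor models built under the
#'   constraint that the lipid-protein term contributes favourably; each
#'   pairs three residue-level statistical potentials with the MM-GBSA
#'   binding-site desolvation term (`MMGBSA dG Bind Solv GB`), whose
#'   negative coefficient against an almost invariably positive desolvation
#'   energy lowers the predicted binding energy.
#'
#' @return Named list of [linear_affinity_model] objects.
#' @examples
#' builtin_models()$model1
#' @export
builtin_models <- function() {
  pp <- "protein-protein"
  lp <- "lipid-protein"
  list(
    previous = linear_affinity_model(
      "previous",
      data.frame(
        descriptor = c("AP_calRW", "MMGBSA dG Bind vdW", "HBOND2",
                       "FIREDOCK_AB"),
        coefficient = c(0.0038165, -0.22506, -0.24626, -0.049875),
        class = c(pp, lp, pp, pp),
        stringsAsFactors = FALSE
      ),
      intercept = -3.3475
    ),
    model1 = linear_affinity_model(
      "model1",
      data.frame(
        descriptor = c("CP_TSC", "CP_ELOCAL_CB", "CP_ELOCAL_MIN",
                       "MMGBSA dG Bind Solv GB"),
        coefficient = c(0.06715, 0.001913, -0.01128, -0.3072),
        class = c(pp, pp, pp, lp),
        stringsAsFactors = FALSE
      ),
      intercept = -6.2941
    ),
    model2 = linear_affinity_model(
      "model2",
      data.frame(
        descriptor = c("CP_ELOCAL_CB", "CP_ELOCAL_MIN", "CP_ZLOCAL_CB",
                       "MMGBSA dG Bind Solv GB"),
        coefficient = c(0.002936, -0.01811, -0.6022, -0.2115),
        class = c(pp, pp, pp, lp),
        stringsAsFactors = FALSE
      ),
      intercept = -7.2704
    ),
    model3 = linear_affinity_model(
      "model3",
      data.frame(
        descriptor = c("CP_TSC", "INSIDE", "FA_PP",
                       "MMGBSA dG Bind Solv GB"),
        coefficient = c(0.0840, 0.2258, -0.06487, -0.4274),
        class = c(pp, pp, pp, lp),
        stringsAsFactors = FALSE
      ),
      intercept = -4.6833
    )
  )
}

# Coerce a descriptor input (data frame with optional `complex` column, or a
# named numeric vector) to a numeric matrix restricted to `wanted` columns.
# Errors explicitly on missing descriptors.
descriptor_values <- function(x, wanted) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- as.data.frame(as.list(x), check.names = FALSE,
                       stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) {
    stop("descriptor input must be a data frame or a named numeric vector",
         call. = FALSE)
  }
  names(x) <- trimws(names(x))
  missing <- setdiff(wanted, names(x))
  if (length(missing) > 0L) {
    stop("missing descriptor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(x[, wanted, drop = FALSE])
  if (nrow(m) == 0L) {
    m <- matrix(numeric(), 0L, length(wanted),
                dimnames = list(NULL, wanted))
  }
  if (!is.numeric(m)) {
    stop("descriptor values must be numeric", call. = FALSE)
  }
  if (nrow(m) > 0L && any(!is.finite(m))) {
    stop("descriptor values must be finite", call. = FALSE)
  }
  m
}

#' Predict binding free energy with a linear model
#'
#' Evaluates intercept + sum(coefficient x descriptor value) for one or more
#' complexes.
#'
#' @param model A [linear_affinity_model].
#' @param descriptors Data frame of descriptor values (one row per complex;
#'   a `complex` id column is ignored) or a named numeric vector for a
#'   single complex.
#' @param temperature Unused here; present for interface symmetry.
#' @return Numeric vector of predicted free energies (kcal/mol).
#' @examples
#' m <- builtin_models()$model1
#' predict_dg(m, c("CP_TSC" = 0, "CP_ELOCAL_CB" = 0, "CP_ELOCAL_MIN" = 0,
#'                 "MMGBSA dG Bind Solv GB" = 0))  # the intercept, -6.2941
#' @export
predict_dg <- function(model, descriptors, temperature = 298) {
  stopifnot(inherits(model, "linear_affinity_model"))
  m <- descriptor_values(descriptors, model$terms$descriptor)
  as.numeric(m %*% model$terms$coefficient) + model$intercept
}

#' Lipid-protein contribution to the predicted binding energy
#'
#' Sum over the model's lipid-class terms only of coefficient x value. A
#' negative (favourable) value lowers the predicted binding energy; the
#' model-search constraint requires this for every training complex.
#'
#' @inheritParams predict_dg
#' @return Numeric vector (kcal/mol), one value per complex.
#' @export
lipid_contribution <- function(model, descriptors) {
  stopifnot(inherits(model, "linear_affinity_model"))
  lip <- model$terms[model$terms$class == "lipid-protein", , drop = FALSE]
  if (nrow(lip) == 0L) {
    stop("model '", model$name, "' has no lipid-protein term", call. = FALSE)
  }
  m <- descriptor_values(descriptors, lip$descriptor)
  as.numeric(m %*% lip$coefficient)
}

#' Protein-protein contribution to the predicted binding energy
#'
#' Sum over the model's protein-protein terms of coefficient x value, so that
#' `predict_dg = protein_contribution + lipid_contribution + intercept`.
#'
#' @inheritParams predict_dg
#' @return Numeric vector (kcal/mol), one value per complex.
#' @export
protein_contribution <- function(model, descriptors) {
  stopifnot(inherits(model, "linear_affinity_model"))
  pp <- model$terms[model$terms$class == "protein-protein", , drop = FALSE]
  if (nrow(pp) == 0L) {
    return(rep(0, nrow(descriptor_values(descriptors, character()))))
  }
  m <- descriptor_values(descriptors, pp$descriptor)
  as.numeric(m %*% pp$coefficient)
}

#' Predict affinities for a table of complexes
#'
#' Applies a model to every row of a descriptor table and returns, per
#' complex, the predicted free energy, the implied dissociation constant and
#' its ordinal affinity range.
#'
#' @param model A [linear_affinity_model].
#' @param descriptors Data frame with a `complex` id column and one numeric
#'   column per descriptor.
#' @param temperature Temperature in Kelvin for the Kd conversion.
#' @return Data frame with columns `complex`, `delta_G_kcal_mol`, `Kd_nM`
#'   and `range` (ordered factor), in input row order.
#' @export
predict_affinity <- function(model, descriptors, temperature = 298) {
  stopifnot(is.data.frame(descriptors))
  names(descriptors) <- trimws(names(descriptors))
  if (!"complex" %in% names(descriptors)) {
    stop("descriptor table must have a `complex` id column", call. = FALSE)
  }
  dg <- predict_dg(model, descriptors, temperature)
  kd <- kd_from_delta_g(dg, temperature)
  data.frame(
    complex = as.character(descriptors$complex),
    delta_G_kcal_mol = dg,
    Kd_nM = kd,
    range = classify_affinity(kd),
    stringsAsFactors = FALSE
  )
}

#' Write a model to JSON
#'
#' Serialises a model as `{name, intercept, terms: [{descriptor,
#' coefficient, class}]}` at full precision, so that re-reading reproduces
#' the coefficients exactly.
#'
#' @param model A [linear_affinity_model].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "linear_affinity_model"))
  doc <- list(name = model$name, intercept = model$intercept,
              terms = model$terms)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path Path to a model JSON document as written by [write_model()].
#' @return A [linear_affinity_model].
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("name", "intercept", "terms") %in% names(doc))) {
    stop("model JSON must contain name, intercept and terms", call. = FALSE)
  }
  linear_affinity_model(doc$name, doc$terms, doc$intercept)
}

# Resolve a model argument that may be a built-in name, a JSON path or a
# model object.
resolve_model <- function(model) {
  if (inherits(model, "linear_affinity_model")) {
    return(model)
  }
  stopifnot(is.character(model), length(model) == 1L)
  builtins <- builtin_models()
  if (model %in% names(builtins)) {
    return(builtins[[model]])
  }
  if (file.exists(model)) {
    return(read_model(model))
  }
  stop("unknown model '", model, "': not a built-in name (",
       paste(names(builtins), collapse = ", "),
       ") and no such file", call. = FALSE)
}
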