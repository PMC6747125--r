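# Exhaustive k-descriptor least-squares model search with the constraint
# that the lipid-protein contribution to the binding energy is favourable,
# evaluated on a fixed training/test split.

#' Model-search configuration
#'
#' @param k Total descriptors per candidate model (default 4).
#' @param n_lipid Required count of lipid-class descriptors per model
#'   (default exactly 1).
#' @param constraint_mode `"per-sample"` (default): the lipid-protein
#'   contribution must be <= 0 for every training complex; `"mean"`: only
#'   its training mean must be <= 0.
#' @param ranking Ranking key for feasible candidates: `"mean_rmse"`
#'   (default; mean of training and test RMSE), `"rmse_train"` or
#'   `"rmse_test"`. Ties are broken by test RMSE, then lexicographically by
#'   descriptor names.
#' @param max_models Maximum number of ranked candidates retained.
#' @param condition_threshold Candidate designs whose condition number
#'   exceeds this are skipped (and tallied), not fitted (default 1e8).
#' @return A list of class `search_config`.
#' @export
search_config <- function(k = 4L,
                          n_lipid = 1L,
                          constraint_mode = c("per-sample", "mean"),
                          ranking = c("mean_rmse", "rmse_train", "rmse_test"),
                          max_models = Inf,
                          condition_threshold = 1e8) {
  constraint_mode <- match.arg(constraint_mode)
  ranking <- match.arg(ranking)
  k <- as.integer(k)
  n_lipid <- as.integer(n_lipid)
  stopifnot(k >= 1L, n_lipid >= 0L, n_lipid <= k,
            max_models >= 1, condition_threshold > 0)
  structure(list(k = k, n_lipid = n_lipid,
                 constraint_mode = constraint_mode, ranking = ranking,
                 max_models = max_models,
                 condition_threshold = condition_threshold),
            class = "search_config")
}

#' Enumerate descriptor subsets with a fixed class composition
#'
#' All size-`k` subsets of the descriptor names containing exactly
#' `n_lipid` lipid-class descriptors, in deterministic lexicographic order.
#'
#' @param classes Named character vector mapping descriptor name to
#'   `"protein-protein"` or `"lipid-protein"`.
#' @param k Subset size.
#' @param n_lipid Required number of lipid-class members.
#' @return List of character vectors (each sorted), lexicographically
#'   ordered.
#' @export
enumerate_subsets <- function(classes, k, n_lipid = 1L) {
  stopifnot(is.character(classes), !is.null(names(classes)))
  k <- as.integer(k)
  n_lipid <- as.integer(n_lipid)
  protein <- sort(names(classes)[classes == "protein-protein"])
  lipid <- sort(names(classes)[classes == "lipid-protein"])
  n_protein <- k - n_lipid
  if (n_lipid < 0L || n_protein < 0L ||
      n_lipid > length(lipid) || n_protein > length(protein)) {
    stop("infeasible composition: need ", n_protein, " protein-protein and ",
         n_lipid, " lipid-protein descriptors, have ", length(protein),
         " and ", length(lipid), call. = FALSE)
  }
  pc <- if (n_protein > 0L) {
    utils::combn(protein, n_protein, simplify = FALSE)
  } else {
    list(character())
  }
  lc <- if (n_lipid > 0L) {
    utils::combn(lipid, n_lipid, simplify = FALSE)
  } else {
    list(character())
  }
  subsets <- vector("list", length(pc) * length(lc))
  i <- 0L
  for (p in pc) {
    for (l in lc) {
      i <- i + 1L
      subsets[[i]] <- sort(c(p, l))
    }
  }
  keys <- vapply(subsets, paste, character(1L), collapse = "\r")
  subsets[order(keys, method = "radix")]
}

#' Ordinary least squares with a conditioning guard
#'
#' Fits `y ~ 1 + X` by QR least squares. Ill-conditioned designs (condition
#' number above `condition_threshold`, or rank-deficient) yield `NULL`
#' rather than an unstable fit.
#'
#' @param x Numeric matrix with named columns (training design, one row per
#'   complex).
#' @param y Numeric response (experimental free energies, kcal/mol).
#' @param condition_threshold Condition-number guard (default 1e8).
#' @return `NULL` if guarded out, else a list with `coefficients` (named as
#'   the columns of `x`) and `intercept`.
#' @export
fit_least_squares <- function(x, y, condition_threshold = 1e8) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), is.numeric(y), nrow(x) == length(y))
  if (nrow(x) < ncol(x) + 1L) {
    stop("need at least ", ncol(x) + 1L, " rows to fit ", ncol(x),
         " coefficients plus an intercept", call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, x)
  if (kappa(design, exact = TRUE) > condition_threshold) {
    return(NULL)
  }
  fit <- stats::lm.fit(design, y)
  beta <- fit$coefficients
  if (any(is.na(beta))) {
    return(NULL)
  }
  list(coefficients = beta[-1L], intercept = unname(beta[1L]))
}

#' Is the lipid-protein contribution favourable?
#'
#' @param model A [linear_affinity_model] with at least one lipid-class
#'   term.
#' @param descriptors Training descriptor table.
#' @param mode `"per-sample"`: contribution <= 0 for every complex;
#'   `"mean"`: mean contribution <= 0.
#' @return Logical flag.
#' @export
check_lipid_favourable <- function(model, descriptors,
                                   mode = c("per-sample", "mean")) {
  mode <- match.arg(mode)
  contrib <- lipid_contribution(model, descriptors)
  if (mode == "per-sample") {
    all(contrib <= 0)
  } else {
    mean(contrib) <= 0
  }
}

#' Count predictions that fall within experimental error
#'
#' A prediction is "within experimental error" when the predicted free
#' energy lies in the interval obtained by converting the measured Kd plus
#' or minus its reported error to free energies. Measurements without an
#' error range never count as within. When the lower Kd bound
#' (Kd - error) is non-positive the free-energy interval is unbounded
#' below.
#'
#' @param predictions Data frame with columns `complex` and
#'   `delta_G_kcal_mol`.
#' @param measurements Data frame with columns `complex`, `kd_nM` and
#'   optionally `kd_err_nM`.
#' @param temperature Temperature in Kelvin.
#' @return Integer count.
#' @export
count_within_experimental_error <- function(predictions, measurements,
                                            temperature = 298) {
  stopifnot(is.data.frame(predictions), is.data.frame(measurements))
  idx <- match(predictions$complex, measurements$complex)
  if (anyNA(idx)) {
    stop("prediction complex id(s) not found in measurements: ",
         paste(predictions$complex[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  kd <- measurements$kd_nM[idx]
  err <- if ("kd_err_nM" %in% names(measurements)) {
    measurements$kd_err_nM[idx]
  } else {
    rep(NA_real_, length(idx))
  }
  dg <- predictions$delta_G_kcal_mol
  within <- rep(FALSE, length(dg))
  has_err <- !is.na(err)
  if (any(has_err)) {
    lo_kd <- kd[has_err] - err[has_err]
    hi_kd <- kd[has_err] + err[has_err]
    dg_lo <- ifelse(lo_kd > 0, delta_g_from_kd(pmax(lo_kd, 1e-300),
                                               temperature), -Inf)
    dg_hi <- delta_g_from_kd(hi_kd, temperature)
    within[has_err] <- dg[has_err] >= dg_lo & dg[has_err] <= dg_hi
  }
  sum(within)
}

#' Exhaustive sign-constrained model search
#'
#' Enumerates every `k`-descriptor subset with the required class
#' composition, fits ordinary least squares on the training complexes
#' (targets are experimental Kd values converted to free energies), keeps
#' only candidates whose lipid-protein contribution is favourable on the
#' training set, and ranks the survivors by the configured RMSE key. The
#' training/test split is taken verbatim from the measurement table's `set`
#' column and never re-randomised; the whole procedure is deterministic.
#'
#' @param descriptors Descriptor table: `complex` id column plus numeric
#'   descriptor columns, with classes attached (see
#'   [descriptor_classes()]).
#' @param measurements Data frame with columns `complex`, `kd_nM`,
#'   optional `kd_err_nM`, and `set` (`"training"` or `"test"`).
#' @param config A [search_config()].
#' @param temperature Temperature in Kelvin.
#' @return An `affinity_search_result`: list with `candidates` (ranked data
#'   frame of feasible models with RMSE and within-error counts), `models`
#'   (list of [linear_affinity_model], same order), `diagnostics`
#'   (enumerated / fitted / skipped-collinear / rejected-constraint counts)
#'   and the `config` echo.
#' @export
search_models <- function(descriptors, measurements,
                          config = search_config(), temperature = 298) {
  stopifnot(is.data.frame(descriptors), is.data.frame(measurements),
            inherits(config, "search_config"))
  names(descriptors) <- trimws(names(descriptors))
  if (!"complex" %in% names(descriptors)) {
    stop("descriptor table must have a `complex` id column", call. = FALSE)
  }
  if (!all(c("complex", "kd_nM", "set") %in% names(measurements))) {
    stop("measurements must have columns complex, kd_nM, set", call. = FALSE)
  }
  idx <- match(measurements$complex, descriptors$complex)
  if (anyNA(idx)) {
    stop("measurement complex id(s) missing from descriptor table: ",
         paste(measurements$complex[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  desc <- descriptors[idx, , drop = FALSE]
  classes <- descriptor_classes(descriptors)
  dg_exp <- delta_g_from_kd(measurements$kd_nM, temperature)
  is_train <- measurements$set == "training"
  is_test <- measurements$set == "test"
  if (!any(is_train)) {
    stop("training set is empty", call. = FALSE)
  }
  if (sum(is_train) < config$k + 2L) {
    stop("need at least k + 2 = ", config$k + 2L, " training complexes, have ",
         sum(is_train), call. = FALSE)
  }
  has_err <- "kd_err_nM" %in% names(measurements)

  subsets <- enumerate_subsets(classes, config$k, config$n_lipid)
  n_fitted <- 0L
  n_collinear <- 0L
  n_rejected <- 0L
  rows <- list()
  models <- list()
  train_desc <- desc[is_train, , drop = FALSE]
  for (subset in subsets) {
    x_train <- as.matrix(train_desc[, subset, drop = FALSE])
    fit <- fit_least_squares(x_train, dg_exp[is_train],
                             config$condition_threshold)
    if (is.null(fit)) {
      n_collinear <- n_collinear + 1L
      next
    }
    n_fitted <- n_fitted + 1L
    model <- linear_affinity_model(
      paste(subset, collapse = " + "),
      data.frame(descriptor = subset,
                 coefficient = unname(fit$coefficients[subset]),
                 class = unname(classes[subset]),
                 stringsAsFactors = FALSE),
      fit$intercept
    )
    if (!check_lipid_favourable(model, train_desc, config$constraint_mode)) {
      n_rejected <- n_rejected + 1L
      next
    }
    dg_pred <- predict_dg(model, desc)
    rmse_train <- rmse(dg_pred[is_train], dg_exp[is_train])
    rmse_test <- if (any(is_test)) {
      rmse(dg_pred[is_test], dg_exp[is_test])
    } else {
      NA_real_
    }
    inexp <- function(sel) {
      if (!has_err || !any(sel)) return(NA_integer_)
      count_within_experimental_error(
        data.frame(complex = measurements$complex[sel],
                   delta_G_kcal_mol = dg_pred[sel],
                   stringsAsFactors = FALSE),
        measurements, temperature)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model = model$name,
      rmse_train = rmse_train,
      rmse_test = rmse_test,
      inexp_train = inexp(is_train),
      inexp_test = inexp(is_test),
      stringsAsFactors = FALSE
    )
    models[[length(models) + 1L]] <- model
  }

  if (length(rows) > 0L) {
    candidates <- do.call(rbind, rows)
    key <- switch(config$ranking,
                  mean_rmse = if (any(is_test)) {
                    (candidates$rmse_train + candidates$rmse_test) / 2
                  } else {
                    candidates$rmse_train
                  },
                  rmse_train = candidates$rmse_train,
                  rmse_test = if (any(is_test)) {
                    candidates$rmse_test
                  } else {
                    candidates$rmse_train
                  })
    ord <- order(key, candidates$rmse_test, candidates$model,
                 method = "radix")
    candidates <- candidates[ord, , drop = FALSE]
    models <- models[ord]
    if (is.finite(config$max_models) &&
        nrow(candidates) > config$max_models) {
      keep <- seq_len(config$max_models)
      candidates <- candidates[keep, , drop = FALSE]
      models <- models[keep]
    }
    rownames(candidates) <- NULL
  } else {
    candidates <- data.frame(model = character(), rmse_train = numeric(),
                             rmse_test = numeric(),
                             inexp_train = integer(),
                             inexp_test = integer(),
                             stringsAsFactors = FALSE)
  }

  structure(list(
    candidates = candidates,
    models = models,
    diagnostics = list(
      n_enumerated = length(subsets),
      n_fitted = n_fitted,
      n_skipped_collinear = n_collinear,
      n_rejected_constraint = n_rejected,
      n_feasible = length(models),
      n_train = sum(is_train),
      n_test = sum(is_test)
    ),
    config = config
  ), class = "affinity_search_result")
}

#' @export
print.affinity_search_result <- function(x, n = 5L, ...) {
  d <- x$diagnostics
  cat("Affinity model search: ", d$n_enumerated, " subsets enumerated, ",
      d$n_fitted, " fitted, ", d$n_skipped_collinear, " skipped (collinear), ",
      d$n_rejected_constraint, " rejected (lipid constraint), ",
      d$n_feasible, " feasible\n", sep = "")
  if (nrow(x$candidates) > 0L) {
    cat("Top candidates (train n=", d$n_train, ", test n=", d$n_test,
        "):\n", sep = "")
    print(utils::head(x$candidates, n))
  }
  invisible(x)
}
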