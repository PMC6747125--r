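# Shared fixtures and an independent brute-force model-search oracle used
# to cross-check search_models().

# Small descriptor table with explicit classes: m_pp protein-protein
# columns ("D1", "D2", ...) and m_lp lipid-protein columns ("L1", ...).
make_descriptors <- function(n, m_pp, m_lp, seed = 42L) {
  set.seed(seed)
  out <- data.frame(complex = sprintf("cx_%02d", seq_len(n)),
                    stringsAsFactors = FALSE)
  cls <- character()
  for (j in seq_len(m_pp)) {
    nm <- paste0("D", j)
    out[[nm]] <- rnorm(n, sd = runif(1, 0.5, 5))
    cls[nm] <- "protein-protein"
  }
  for (j in seq_len(m_lp)) {
    nm <- paste0("L", j)
    out[[nm]] <- rlnorm(n, log(20), 0.3)
    cls[nm] <- "lipid-protein"
  }
  if (length(cls) == 0L) {
    return(out)
  }
  set_descriptor_classes(out, cls)
}

# Noiseless dataset generated by a planted 4-term model over the helper
# tables; the first 15 complexes are the training set.
planted_dataset <- function(n = 23, m_pp = 6, m_lp = 2, seed = 9,
                            lipid_coef = -0.25) {
  desc <- make_descriptors(n, m_pp, m_lp, seed = seed)
  planted <- linear_affinity_model(
    "planted",
    data.frame(descriptor = c("D1", "D2", "D3", "L1"),
               coefficient = c(0.4, -0.3, 0.2, lipid_coef),
               class = c(rep("protein-protein", 3), "lipid-protein"),
               stringsAsFactors = FALSE),
    -6)
  dg <- predict_dg(planted, desc)
  meas <- data.frame(complex = desc$complex, kd_nM = kd_from_delta_g(dg),
                     kd_err_nM = 0.2 * kd_from_delta_g(dg),
                     set = rep(c("training", "test"), c(15, n - 15)),
                     stringsAsFactors = FALSE)
  list(descriptors = desc, measurements = meas, planted = planted)
}

# Independent naive re-implementation of the constrained exhaustive search:
# explicit loops, lm() formula fits, no shared code with search_models().
# Returns a data frame keyed by sorted subset, unordered.
naive_search <- function(descriptors, measurements, k, n_lipid,
                         mode = "per-sample") {
  classes <- attr(descriptors, "descriptor_classes")
  desc_names <- setdiff(names(descriptors), "complex")
  dg_exp <- 1.987e-3 * 298 * log(measurements$kd_nM * 1e-9)
  desc <- descriptors[match(measurements$complex, descriptors$complex), ,
                      drop = FALSE]
  train <- measurements$set == "training"
  rows <- list()
  for (subset in utils::combn(desc_names, k, simplify = FALSE)) {
    if (sum(classes[subset] == "lipid-protein") != n_lipid) next
    dat <- as.data.frame(desc[, subset, drop = FALSE])
    names(dat) <- paste0("v", seq_len(k))
    dat$y <- dg_exp
    fit <- stats::lm(y ~ ., data = dat[train, , drop = FALSE])
    beta <- stats::coef(fit)
    if (any(is.na(beta))) next
    lip_cols <- which(classes[subset] == "lipid-protein")
    lip_contrib <- as.matrix(dat[train, lip_cols, drop = FALSE]) %*%
      beta[1L + lip_cols]
    ok <- if (mode == "per-sample") all(lip_contrib <= 0) else
      mean(lip_contrib) <= 0
    if (!ok) next
    pred <- as.numeric(stats::predict(fit, newdata = dat))
    rows[[length(rows) + 1L]] <- data.frame(
      key = paste(sort(subset), collapse = " + "),
      rmse_train = sqrt(mean((pred[train] - dg_exp[train])^2)),
      rmse_test = sqrt(mean((pred[!train] - dg_exp[!train])^2)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
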