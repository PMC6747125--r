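test_that("subset enumeration respects composition, uniqueness and order", {
  cls <- c(setNames(rep("protein-protein", 4), paste0("D", 1:4)),
           L1 = "lipid-protein")
  s <- enumerate_subsets(cls, k = 4, n_lipid = 1)
  expect_length(s, 4L)  # C(4,3) x 1
  expect_true(all(vapply(s, function(x) "L1" %in% x, logical(1))))
  keys <- vapply(s, paste, character(1), collapse = " ")
  expect_false(any(duplicated(keys)))
  expect_equal(keys, sort(keys))  # lexicographic

  cls2 <- c(setNames(rep("protein-protein", 3), paste0("D", 1:3)),
            setNames(rep("lipid-protein", 2), paste0("L", 1:2)))
  expect_length(enumerate_subsets(cls2, k = 2, n_lipid = 1), 6L)  # 3 x 2
  expect_error(enumerate_subsets(cls, k = 3, n_lipid = 2),
               "infeasible composition")
})

test_that("least squares recovers exact and planted coefficients", {
  # exact line
  x <- matrix(c(1, 2, 3, 4, 5), ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_least_squares(x, 2 * x[, 1] - 1)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-12)
  expect_equal(fit$intercept, -1, tolerance = 1e-12)
  # constant response
  fit0 <- fit_least_squares(x, rep(3.5, 5))
  expect_equal(unname(fit0$coefficients), 0, tolerance = 1e-12)
  expect_equal(fit0$intercept, 3.5, tolerance = 1e-12)
  # planted coefficients, zero noise
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(0.5, -2, 1.3)
  fitp <- fit_least_squares(X, drop(X %*% beta) + 4)
  expect_equal(unname(fitp$coefficients), beta, tolerance = 1e-8)
  expect_equal(fitp$intercept, 4, tolerance = 1e-8)
  # residual orthogonality to the design
  y <- rnorm(10)
  fitr <- fit_least_squares(X, y)
  resid <- y - (drop(X %*% fitr$coefficients) + fitr$intercept)
  expect_lt(max(abs(crossprod(cbind(1, X), resid))), 1e-8)
})

test_that("ill-conditioned designs are guarded out, not fitted", {
  set.seed(6)
  a <- rnorm(12)
  X <- cbind(a = a, b = a)  # exactly collinear
  expect_null(fit_least_squares(X, rnorm(12)))
  Xnear <- cbind(a = a, b = a + rnorm(12, sd = 1e-12))
  expect_null(fit_least_squares(Xnear, rnorm(12), condition_threshold = 1e8))
  expect_error(fit_least_squares(X[1:2, ], rnorm(2)), "at least")
})

test_that("lipid favourability check follows sign and mode", {
  desc <- data.frame(complex = c("a", "b"), L = c(15, 25),
                     stringsAsFactors = FALSE)
  mk <- function(coef) linear_affinity_model(
    "m", data.frame(descriptor = "L", coefficient = coef,
                    class = "lipid-protein"), -5)
  expect_true(check_lipid_favourable(mk(-0.3), desc))
  expect_false(check_lipid_favourable(mk(0.3), desc))
  expect_true(check_lipid_favourable(mk(0), desc))  # 0 <= 0
  # mean mode tolerates a single unfavourable sample
  desc2 <- data.frame(complex = c("a", "b"), L = c(-5, 50),
                      stringsAsFactors = FALSE)
  expect_false(check_lipid_favourable(mk(-0.3), desc2, mode = "per-sample"))
  expect_true(check_lipid_favourable(mk(-0.3), desc2, mode = "mean"))
})

test_that("within-experimental-error counting brackets the free energy", {
  meas <- data.frame(complex = c("a", "b"), kd_nM = c(10, 50),
                     kd_err_nM = c(0, 0), set = "training",
                     stringsAsFactors = FALSE)
  exact <- data.frame(complex = c("a", "b"),
                      delta_G_kcal_mol = delta_g_from_kd(c(10, 50)),
                      stringsAsFactors = FALSE)
  expect_equal(count_within_experimental_error(exact, meas), 2L)
  off <- exact
  off$delta_G_kcal_mol <- off$delta_G_kcal_mol + 0.01
  expect_equal(count_within_experimental_error(off, meas), 0L)
  # Kd 10 +/- 5 nM covers a prediction equivalent to 12 nM
  meas2 <- data.frame(complex = "a", kd_nM = 10, kd_err_nM = 5,
                      set = "training", stringsAsFactors = FALSE)
  p12 <- data.frame(complex = "a",
                    delta_G_kcal_mol = delta_g_from_kd(12),
                    stringsAsFactors = FALSE)
  expect_equal(count_within_experimental_error(p12, meas2), 1L)
  p16 <- p12; p16$delta_G_kcal_mol <- delta_g_from_kd(16)
  expect_equal(count_within_experimental_error(p16, meas2), 0L)
  # measurements without an error range never count as within
  meas3 <- data.frame(complex = "a", kd_nM = 10, kd_err_nM = NA_real_,
                      set = "training", stringsAsFactors = FALSE)
  p10 <- data.frame(complex = "a", delta_G_kcal_mol = delta_g_from_kd(10),
                    stringsAsFactors = FALSE)
  expect_equal(count_within_experimental_error(p10, meas3), 0L)
  expect_error(count_within_experimental_error(
    data.frame(complex = "zz", delta_G_kcal_mol = -10), meas), "zz")
})

test_that("search recovers a planted noiseless model exactly", {
  d <- planted_dataset()
  res <- search_models(d$descriptors, d$measurements,
                       search_config(k = 4, n_lipid = 1))
  expect_gt(nrow(res$candidates), 0L)
  top <- res$models[[1L]]
  expect_setequal(top$terms$descriptor, d$planted$terms$descriptor)
  want <- setNames(d$planted$terms$coefficient, d$planted$terms$descriptor)
  got <- setNames(top$terms$coefficient, top$terms$descriptor)
  expect_equal(got[names(want)], want, tolerance = 1e-6)
  expect_equal(top$intercept, d$planted$intercept, tolerance = 1e-6)
  expect_equal(res$candidates$rmse_train[1L], 0, tolerance = 1e-8)
  # a perfectly-fitting noiseless model predicts within zero-width error
  expect_equal(res$candidates$inexp_train[1L], 15L)
})

test_that("an unfavourable planted lipid term is excluded by construction", {
  d <- planted_dataset(lipid_coef = 0.25)
  res <- search_models(d$descriptors, d$measurements,
                       search_config(k = 4, n_lipid = 1))
  keys <- vapply(res$models, function(m) {
    paste(sort(m$terms$descriptor), collapse = " + ")
  }, character(1))
  expect_false("D1 + D2 + D3 + L1" %in% keys)
})

test_that("search agrees with an independent brute-force enumeration", {
  d <- planted_dataset(n = 18, m_pp = 8, m_lp = 2, seed = 13)
  for (k in 2:3) {
    res <- search_models(d$descriptors, d$measurements,
                         search_config(k = k, n_lipid = 1))
    oracle <- naive_search(d$descriptors, d$measurements, k, 1)
    expect_equal(sort(res$candidates$model), sort(oracle$key))
    m <- match(res$candidates$model, oracle$key)
    expect_equal(res$candidates$rmse_train, oracle$rmse_train[m],
                 tolerance = 1e-10)
    expect_equal(res$candidates$rmse_test, oracle$rmse_test[m],
                 tolerance = 1e-10)
  }
})

test_that("every returned candidate satisfies the lipid constraint", {
  d <- planted_dataset(n = 20, m_pp = 5, m_lp = 2, seed = 21)
  res <- search_models(d$descriptors, d$measurements,
                       search_config(k = 3, n_lipid = 1))
  train_desc <- d$descriptors[
    d$descriptors$complex %in%
      d$measurements$complex[d$measurements$set == "training"], ]
  for (m in res$models) {
    expect_true(check_lipid_favourable(m, train_desc, "per-sample"))
  }
  d2 <- res$diagnostics
  expect_equal(d2$n_feasible + d2$n_rejected_constraint, d2$n_fitted)
  expect_equal(d2$n_fitted + d2$n_skipped_collinear, d2$n_enumerated)
})

test_that("least squares beats perturbed coefficients on training RMSE", {
  d <- planted_dataset()
  res <- search_models(d$descriptors, d$measurements,
                       search_config(k = 4, n_lipid = 1,
                                     ranking = "rmse_train"))
  top <- res$models[[1L]]
  is_train <- d$measurements$set == "training"
  desc <- d$descriptors[match(d$measurements$complex,
                              d$descriptors$complex), ]
  dg_exp <- delta_g_from_kd(d$measurements$kd_nM)
  base_rmse <- rmse(predict_dg(top, desc)[is_train], dg_exp[is_train])
  set.seed(2)
  for (i in 1:20) {
    pert <- top
    pert$terms$coefficient <- pert$terms$coefficient * (1 + rnorm(4, 0, 0.1))
    pert_rmse <- rmse(predict_dg(pert, desc)[is_train], dg_exp[is_train])
    expect_lte(base_rmse, pert_rmse + 1e-12)
  }
  # top candidate under rmse_train ranking minimises rmse_train
  expect_equal(res$candidates$rmse_train[1L],
               min(res$candidates$rmse_train))
})

test_that("an infeasible search returns diagnostics, not a crash", {
  # all lipid coefficients forced unfavourable: response rises with L1
  desc <- make_descriptors(12, 2, 1, seed = 30)
  dg <- -9 + 0.2 * desc$L1
  meas <- data.frame(complex = desc$complex, kd_nM = kd_from_delta_g(dg),
                     kd_err_nM = NA_real_,
                     set = rep(c("training", "test"), c(8, 4)),
                     stringsAsFactors = FALSE)
  res <- search_models(desc, meas, search_config(k = 2, n_lipid = 1))
  expect_equal(nrow(res$candidates), 0L)
  expect_equal(res$diagnostics$n_rejected_constraint,
               res$diagnostics$n_fitted)
})
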