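test_that("built-in models have the published structure", {
  models <- builtin_models()
  expect_named(models, c("previous", "model1", "model2", "model3"))
  expect_equal(models$model1$intercept, -6.2941)
  expect_equal(models$previous$intercept, -3.3475)
  m2 <- models$model2$terms
  expect_equal(m2$coefficient[m2$descriptor == "CP_ZLOCAL_CB"], -0.6022)
  for (m in models) {
    expect_s3_class(m, "linear_affinity_model")
    lip <- m$terms$descriptor[m$terms$class == "lipid-protein"]
    expect_length(lip, 1L)  # each published model has exactly one lipid term
  }
  # the favourable-lipid models all use the desolvation term
  for (nm in c("model1", "model2", "model3")) {
    terms <- models[[nm]]$terms
    expect_equal(terms$descriptor[terms$class == "lipid-protein"],
                 "MMGBSA dG Bind Solv GB")
    expect_lt(terms$coefficient[terms$class == "lipid-protein"], 0)
  }
})

test_that("model construction validates its terms", {
  terms <- data.frame(descriptor = c("a", "a"), coefficient = c(1, 2),
                      class = "protein-protein")
  expect_error(linear_affinity_model("m", terms, 0), "duplicate")
  expect_error(linear_affinity_model("m", terms[0, ], 0), "at least one")
  terms2 <- data.frame(descriptor = "a", coefficient = 1, class = "lipid")
  expect_error(linear_affinity_model("m", terms2, 0), "class")
})

test_that("predict_dg is the intercept plus the weighted descriptor sum", {
  m1 <- builtin_models()$model1
  zeros <- c("CP_TSC" = 0, "CP_ELOCAL_CB" = 0, "CP_ELOCAL_MIN" = 0,
             "MMGBSA dG Bind Solv GB" = 0)
  expect_equal(predict_dg(m1, zeros), -6.2941)
  expect_equal(predict_dg(builtin_models()$previous,
                          c("AP_calRW" = 0, "MMGBSA dG Bind vdW" = 0,
                            "HBOND2" = 0, "FIREDOCK_AB" = 0)),
               -3.3475)
  # hand-summed: 0.6715 + 0.1913 - 0.564 - 6.144 - 6.2941
  rec <- c("CP_TSC" = 10, "CP_ELOCAL_CB" = 100, "CP_ELOCAL_MIN" = 50,
           "MMGBSA dG Bind Solv GB" = 20)
  expect_equal(predict_dg(m1, rec), -12.1393, tolerance = 1e-12)
  expect_error(predict_dg(m1, rec[-1]), "missing descriptor.*CP_TSC")
})

test_that("lipid and protein contributions decompose the prediction", {
  m1 <- builtin_models()$model1
  expect_equal(lipid_contribution(m1, c("MMGBSA dG Bind Solv GB" = 20)),
               -6.144)
  expect_equal(lipid_contribution(m1, c("MMGBSA dG Bind Solv GB" = 0)), 0)
  expect_equal(lipid_contribution(m1, c("MMGBSA dG Bind Solv GB" = 10)),
               -3.072)
  no_lip <- linear_affinity_model(
    "pp-only", data.frame(descriptor = "x", coefficient = 1,
                          class = "protein-protein"), 0)
  expect_error(lipid_contribution(no_lip, c(x = 1)), "no lipid-protein term")
  # decomposition holds on random records
  set.seed(11)
  recs <- make_descriptors(20, 0, 0)
  recs[m1$terms$descriptor] <- lapply(m1$terms$descriptor,
                                      function(d) rnorm(20, sd = 30))
  expect_equal(predict_dg(m1, recs),
               protein_contribution(m1, recs) +
                 lipid_contribution(m1, recs) + m1$intercept,
               tolerance = 1e-12)
})

test_that("the intercept-free part of the model is linear", {
  m1 <- builtin_models()$model1
  f <- function(x) predict_dg(m1, x) - m1$intercept
  set.seed(3)
  nm <- m1$terms$descriptor
  for (i in 1:10) {
    x <- setNames(rnorm(4, sd = 50), nm)
    y <- setNames(rnorm(4, sd = 50), nm)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(f(a * x + b * y), a * f(x) + b * f(y), tolerance = 1e-9)
  }
})

test_that("model JSON serialisation round-trips coefficients exactly", {
  for (m in builtin_models()) {
    path <- tempfile(fileext = ".json")
    on.exit(unlink(path), add = TRUE)
    write_model(m, path)
    back <- read_model(path)
    expect_identical(back$terms$coefficient, m$terms$coefficient)
    expect_identical(back$intercept, m$intercept)
    expect_identical(back$terms$descriptor, m$terms$descriptor)
    expect_identical(back$terms$class, m$terms$class)
  }
})

test_that("predict_affinity yields internally consistent rows in order", {
  m1 <- builtin_models()$model1
  desc <- data.frame(complex = c("b", "a"), check.names = FALSE,
                     stringsAsFactors = FALSE)
  desc[m1$terms$descriptor] <- list(c(10, 0), c(100, 0), c(50, 0), c(20, 0))
  pred <- predict_affinity(m1, desc)
  expect_equal(pred$complex, c("b", "a"))  # input order preserved
  expect_equal(pred$delta_G_kcal_mol, c(-12.1393, -6.2941))
  expect_equal(pred$Kd_nM, kd_from_delta_g(pred$delta_G_kcal_mol))
  expect_equal(pred$range, classify_affinity(pred$Kd_nM))
  expect_equal(nrow(predict_affinity(m1, desc[0, , drop = FALSE])), 0L)
})
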