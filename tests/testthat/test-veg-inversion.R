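test_that("vegetation indices match their closed-form expressions", {
  v <- compute_vegetation_indices(blue = 0.05, green = 0.08,
                                  red = 0.1, nir = 0.4)
  expect_equal(v$ndvi, 0.6, tolerance = 1e-12)
  expect_equal(v$rvi, 4, tolerance = 1e-12)
  expect_equal(v$osavi, 0.3 / 0.66, tolerance = 1e-12)
  expect_equal(v$msr, 1, tolerance = 1e-12)
  expect_equal(v$evi2, 0.75 / 1.64, tolerance = 1e-12)
  expect_equal(v$evi, 0.75 / 1.625, tolerance = 1e-12)

  # NIR = R makes the difference indices zero
  v0 <- compute_vegetation_indices(0.05, 0.08, 0.2, 0.2)
  expect_equal(v0$ndvi, 0)
  expect_equal(v0$osavi, 0)
  expect_equal(v0$rvi, 1)
})

test_that("index formulas agree with an independent evaluation on random bands", {
  set.seed(7)
  n <- 100
  b <- runif(n, 0, 0.2); r <- runif(n, 0.01, 0.3)
  g <- runif(n, 0, 0.3); nir <- runif(n, 0.1, 0.9)
  v <- compute_vegetation_indices(b, g, r, nir)
  sr <- nir / r
  expect_equal(v$evi, 2.5 * (nir - r) / (nir + 6 * r - 7.5 * b + 1),
               tolerance = 1e-12)
  expect_equal(v$evi2, 2.5 * (nir - r) / (nir + 2.4 * r + 1),
               tolerance = 1e-12)
  expect_equal(v$msr, (sr - 1) / (sqrt(sr) + 1), tolerance = 1e-12)
  expect_equal(v$ndvi, (nir - r) / (nir + r), tolerance = 1e-12)
  expect_equal(v$osavi, (nir - r) / (nir + r + 0.16), tolerance = 1e-12)
  expect_equal(v$rvi, sr, tolerance = 1e-12)
  expect_true(all(v$ndvi >= -1 & v$ndvi <= 1))
  expect_true(all(v$rvi >= 0))
})

test_that("zero red band flags ratio indices without killing the rest", {
  v <- compute_vegetation_indices(0.05, 0.08, 0, 0.4)
  expect_true(is.na(v$rvi) && is.na(v$msr))
  expect_false(is.na(v$ndvi))
  expect_error(compute_vegetation_indices(0.05, 0.08, 1.2, 0.4), "0, 1")
})

test_that("univariate fits recover the published model coefficients", {
  x <- seq(0.05, 0.75, length.out = 20)
  # exponential: y = 0.21 e^(4.68 x)
  m_exp <- fit_univariate_inversion(x, 0.21 * exp(4.68 * x),
                                    "exponential", index = "osavi")
  expect_equal(m_exp$a, 0.21, tolerance = 1e-6)
  expect_equal(m_exp$b, 4.68, tolerance = 1e-6)
  # linear: y = 0.18 x + 0.89
  xr <- seq(0.5, 8, length.out = 20)
  m_lin <- fit_univariate_inversion(xr, 0.18 * xr + 0.89, "linear",
                                    index = "rvi")
  expect_equal(m_lin$a, 0.18, tolerance = 1e-9)
  expect_equal(m_lin$b, 0.89, tolerance = 1e-9)
  # power: y = 8.51 x^1.61
  m_pow <- fit_univariate_inversion(x, 8.51 * x^1.61, "power")
  expect_equal(m_pow$a, 8.51, tolerance = 1e-6)
  expect_equal(m_pow$b, 1.61, tolerance = 1e-6)
  # constant response under the linear form
  m_const <- fit_univariate_inversion(x, rep(2.5, 20), "linear")
  expect_equal(m_const$a, 0, tolerance = 1e-12)
  expect_equal(m_const$b, 2.5, tolerance = 1e-12)
  expect_error(fit_univariate_inversion(rep(1, 5), 1:5, "linear"),
               "constant")
})

test_that("coefficient recovery converges as noise shrinks", {
  set.seed(11)
  x <- seq(0.1, 0.7, length.out = 40)
  y0 <- 0.21 * exp(4.68 * x)
  err <- sapply(c(0.2, 0.02, 0.002), function(s) {
    y <- y0 + rnorm(length(x), 0, s)
    m <- fit_univariate_inversion(x, pmax(y, 1e-3), "exponential")
    abs(m$a - 0.21) + abs(m$b - 4.68)
  })
  expect_true(all(diff(err) < 0))
})

test_that("predict_lai evaluates the model and floors at zero", {
  m <- osavi_reference_model()
  expect_equal(predict_lai(m, 0), 0.21)
  expect_equal(predict_lai(m, 0.3 / 0.66), 1.76230917265416,
               tolerance = 1e-9)
  rvi_m <- new_inversion_model("rvi", "linear", a = 0.18, b = 0.89)
  expect_equal(predict_lai(rvi_m, 4), 1.61, tolerance = 1e-12)
  expect_equal(predict_lai(rvi_m, -100), 0)  # floored
  # fit-then-predict reproduces fitted values on training inputs
  x <- seq(0.1, 0.6, length.out = 15)
  y <- 0.3 * exp(4 * x)
  m2 <- fit_univariate_inversion(x, y, "exponential")
  expect_equal(predict_lai(m2, x), y, tolerance = 1e-8)
})

test_that("PLSR with full rank matches OLS; 1 component fits exact 1-d signal", {
  set.seed(21)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  y <- drop(X %*% c(1, -2, 0.5, 0)) + rnorm(n, 0, 0.1)
  m_full <- fit_plsr(X, y, ncomp = 4)
  ols <- lm(y ~ X)
  expect_equal(predict_lai(m_full, X),
               pmax(unname(fitted(ols)), 0), tolerance = 1e-8)
  # y exactly linear in one predictor: one component suffices
  y1 <- 3 * X[, 2]
  m1 <- fit_plsr(X[, 2, drop = FALSE], y1, ncomp = 1)
  expect_lt(max(abs(predict_lai(m1, X[, 2, drop = FALSE]) -
                    pmax(y1, 0))), 1e-8)
  # permutation invariance of the fitted coefficients
  perm <- sample(n)
  m_perm <- fit_plsr(X[perm, ], y[perm], ncomp = 4)
  expect_equal(m_perm$coefficients, m_full$coefficients,
               tolerance = 1e-8)
  expect_error(fit_plsr(X, y, ncomp = 5), "ncomp")
})

test_that("split_and_evaluate reproduces the 256/128 split and is deterministic", {
  set.seed(3)
  n <- 384
  date <- rep(1:8, each = 48)
  osavi <- runif(n, 0.1, 0.8)
  lai <- 0.21 * exp(4.68 * osavi)
  idx <- data.frame(evi = runif(n, 0.1, 0.6), evi2 = runif(n, 0.1, 0.6),
                    msr = runif(n, 0.5, 3), ndvi = runif(n, 0.2, 0.9),
                    osavi = osavi, rvi = runif(n, 1, 8))
  res <- split_and_evaluate(idx, lai, date, seed = 9)
  expect_length(res$modeling, 256)
  expect_length(res$validation, 128)
  # noiseless exponential data: the osavi model validates perfectly
  osavi_row <- res$table[res$table$index == "osavi", ]
  expect_gt(osavi_row$r2_valid, 1 - 1e-9)
  expect_identical(osavi_row$rank, 1L)
  res2 <- split_and_evaluate(idx, lai, date, seed = 9)
  expect_identical(res$modeling, res2$modeling)
  expect_equal(res$table, res2$table)
})

test_that("inversion models round-trip through JSON", {
  m <- fit_univariate_inversion(seq(0.1, 0.7, length.out = 10),
                                0.21 * exp(4.68 * seq(0.1, 0.7,
                                                      length.out = 10)),
                                "exponential", index = "osavi")
  path <- withr::local_tempfile(fileext = ".json")
  write_inversion_model(m, path)
  m2 <- read_inversion_model(path)
  expect_equal(m2$a, m$a)
  expect_equal(m2$b, m$b)
  expect_identical(m2$form, m$form)
})
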