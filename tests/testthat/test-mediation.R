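test_that("ols recovers exact structure on degenerate-noise designs", {
  x <- c(0, 1, 2, 3, 4, 5)
  X <- cbind(intercept = 1, x = x)
  # response identically a predictor column
  fit <- ols(X, x)
  expect_equal(unname(fit$coefficients), c(0, 1))
  expect_equal(max(abs(fit$residuals)), 0)
  # intercept-only design gives the mean
  y <- c(2, 4, 9)
  expect_equal(unname(ols(matrix(1, 3, 1), y)$coefficients), mean(y))
})

test_that("ols matches the normal-equations oracle on a 6-point fixture", {
  X <- cbind(intercept = 1,
             x1 = c(0.2, -1.1, 0.5, 2.0, -0.3, 1.4),
             x2 = c(1.0, 0.4, -0.8, 0.1, 0.9, -1.5))
  y <- c(0.7, -0.2, 1.1, 2.5, 0.3, 0.8)
  fit <- ols(X, y)
  ora <- oracle_ols(X, y)
  expect_equal(unname(fit$coefficients), unname(ora$coefficients),
               tolerance = 1e-12)
  expect_equal(unname(fit$se), unname(ora$se), tolerance = 1e-12)
})

test_that("ols names collinear columns on rank-deficient designs", {
  X <- cbind(intercept = 1, a = 1:6, twice_a = 2 * (1:6))
  expect_error(ols(X, rnorm(6)), "twice_a")
  expect_error(ols(cbind(a = 1:3), 1:2), "design row")
})

test_that("percentile_ci follows the sort-and-interpolate rule", {
  expect_equal(percentile_ci(rep(3.5, 150)), c(3.5, 3.5))
  # type-7: h = (n-1)p + 1; for 1..100 at level .90 -> 5.95 and 95.05
  expect_equal(percentile_ci(1:100, level = 0.90), c(5.95, 95.05))
  set.seed(1)
  sym <- rnorm(501)
  sym <- c(sym, -sym) # exactly symmetric about 0
  ci <- percentile_ci(sym)
  expect_equal(ci[1], -ci[2], tolerance = 1e-12)
  expect_error(percentile_ci(1:99), "at least 100")
  expect_error(percentile_ci(1:200, level = 1.2), "level")
})

test_that("sobel matches closed forms and rejects bad SEs", {
  s <- sobel(0, 1, 2, 1)
  expect_equal(s$z, 0)
  expect_equal(s$p, 1)
  expect_equal(sobel(1, 1, 1, 1)$z, 1 / sqrt(2))
  expect_error(sobel(1, 0, 1, 1), "positive")
})

test_that("fit_model4 reproduces per-regression oracle fits on a printed fixture", {
  # 8 rows: condition, mediator, outcome, one covariate
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  m <- c(0.3, -0.5, 0.8, 0.1, -0.9, -0.2, -1.1, 0.4)
  y <- c(1.2, 0.1, 1.9, 0.8, -0.6, 0.9, -1.2, 1.1)
  cv <- c(0.5, -0.1, 0.9, 0.2, -0.4, 0.3, -0.8, 0.6)
  fit <- fit_model4(x, m, y, covariates = cbind(pre = cv), n_boot = 0)
  om <- oracle_ols(cbind(1, x, cv), m)
  oy <- oracle_ols(cbind(1, m, x, cv), y)
  oc <- oracle_ols(cbind(1, x, cv), y)
  est <- setNames(fit$paths$estimate, fit$paths$path)
  expect_equal(est[["a"]], unname(om$coefficients[2]), tolerance = 1e-12)
  expect_equal(est[["b"]], unname(oy$coefficients[2]), tolerance = 1e-12)
  expect_equal(est[["c_prime"]], unname(oy$coefficients[3]), tolerance = 1e-12)
  expect_equal(est[["c"]], unname(oc$coefficients[2]), tolerance = 1e-12)
  expect_equal(est[["ab"]], est[["a"]] * est[["b"]], tolerance = 1e-15)
})

test_that("total effect decomposes exactly into direct plus indirect", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    x <- rbinom(n, 1, 0.5)
    cv <- cbind(c1 = rnorm(n), c2 = rnorm(n))
    m <- 0.4 * x + 0.2 * cv[, 1] + rnorm(n)
    y <- 0.5 * m - 0.3 * x + rnorm(n)
    fit <- fit_model4(x, m, y, covariates = cv, n_boot = 0)
    est <- setNames(fit$paths$estimate, fit$paths$path)
    expect_lt(abs(est[["c"]] - (est[["c_prime"]] + est[["ab"]])), 1e-10)
  }
})

test_that("rescaling the mediator leaves the indirect and direct effects unchanged", {
  set.seed(5)
  n <- 60
  x <- rep(0:1, each = 30)
  m <- 0.5 * x + rnorm(n)
  y <- 0.7 * m + 0.2 * x + rnorm(n)
  f1 <- fit_model4(x, m, y, n_boot = 0)
  f2 <- fit_model4(x, 10 * m, y, n_boot = 0)
  e1 <- setNames(f1$paths$estimate, f1$paths$path)
  e2 <- setNames(f2$paths$estimate, f2$paths$path)
  expect_equal(e2[["a"]], 10 * e1[["a"]], tolerance = 1e-12)
  expect_equal(e2[["b"]], e1[["b"]] / 10, tolerance = 1e-12)
  expect_equal(e2[["ab"]], e1[["ab"]], tolerance = 1e-12)
  expect_equal(e2[["c"]], e1[["c"]], tolerance = 1e-12)
  expect_equal(e2[["c_prime"]], e1[["c_prime"]], tolerance = 1e-12)
})

test_that("bootstrap inference is seed-deterministic and sane under a null mediator", {
  set.seed(21)
  n <- 80
  x <- rep(0:1, each = 40)
  m <- rnorm(n) # independent of x and y
  y <- 0.3 * x + rnorm(n)
  f1 <- fit_model4(x, m, y, n_boot = 400, seed = 99)
  f2 <- fit_model4(x, m, y, n_boot = 400, seed = 99)
  expect_identical(f1$paths, f2$paths)
  expect_identical(f1$boot, f2$boot)
  ab <- f1$paths[f1$paths$path == "ab", ]
  expect_lte(ab$ci_low, 0)
  expect_gte(ab$ci_high, 0)
})

test_that("fit_model4 validates its inputs", {
  expect_error(fit_model4(rep(1, 10), rnorm(10), rnorm(10), n_boot = 0),
               "distinct")
  expect_error(fit_model4(0:9, rnorm(5), rnorm(10), n_boot = 0),
               "equal lengths")
  expect_error(fit_model4(0:9, c(NA, rnorm(9)), rnorm(10), n_boot = 0),
               "missing")
})
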