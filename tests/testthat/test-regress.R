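test_that("a noiseless line is fitted exactly", {
  x <- matrix(1:6, 6, 1, dimnames = list(NULL, "x"))
  y <- 1 + 2 * x[, 1]
  m <- fit_ols(x, y)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  expect_equal(m$terms$X, 2, tolerance = 1e-12)
  expect_equal(m$R2, 1)
  expect_equal(m$s2, 0)
  expect_equal(m$Q2, 1)
  expect_equal(m$F, Inf)
})

test_that("a constant response gives R2 = 0 and zero descriptor coefficients", {
  set.seed(21)
  x <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(3.5, 8)
  expect_warning(m <- fit_ols(x, y), "zero total variance")
  expect_equal(m$R2, 0)
  expect_equal(m$Q2, 0)
  expect_equal(m$terms$X, c(0, 0), tolerance = 1e-12)
  expect_equal(m$intercept, 3.5, tolerance = 1e-12)
})

test_that("fit statistics match the normal-equations oracle and summary.lm", {
  set.seed(22)
  X <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + X %*% c(1.5, -0.7, 0.3) + rnorm(12, 0, 0.4)
  y <- drop(y)
  m <- fit_ols(X, y)
  o <- ne_oracle(X, y)
  expect_equal(unname(m$coefficients), unname(o$coef), tolerance = 1e-10)
  expect_equal(c(m$intercept_DX, m$terms$DX), unname(o$dx), tolerance = 1e-10)
  expect_equal(c(m$intercept_t, m$terms$t), unname(o$t), tolerance = 1e-10)
  expect_equal(m$R2, o$r2, tolerance = 1e-10)
  expect_equal(m$s2, o$s2, tolerance = 1e-10)
  expect_equal(m$F, o$f, tolerance = 1e-10)
  # cross-check against the standard modelling function
  sl <- summary(lm(y ~ X))
  expect_equal(m$R2, sl$r.squared, tolerance = 1e-12)
  expect_equal(m$F, unname(sl$fstatistic["value"]), tolerance = 1e-10)
  expect_equal(c(m$intercept_DX, m$terms$DX), unname(sl$coefficients[, 2]),
               tolerance = 1e-10)
})

test_that("simple regression agrees with the analytic closed form", {
  set.seed(23)
  x <- rnorm(20); y <- 3 - 2 * x + rnorm(20)
  m <- fit_ols(matrix(x, dimnames = list(NULL, "x")), y)
  beta <- cov(x, y) / var(x)
  expect_equal(m$terms$X, beta, tolerance = 1e-12)
  expect_equal(m$intercept, mean(y) - beta * mean(x), tolerance = 1e-12)
  expect_equal(m$R2, cor(x, y)^2, tolerance = 1e-12)
})

test_that("hat-matrix leave-one-out equals explicit refits and never exceeds R2", {
  set.seed(24)
  X <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + X %*% c(1, 0.5, -1) + rnorm(15, 0, 0.6)
  y <- drop(y)
  expect_equal(loo_q2(X, y), loo_oracle(X, y), tolerance = 1e-10)
  for (seed in 25:29) {
    set.seed(seed)
    Xr <- matrix(rnorm(14 * 2), 14, 2, dimnames = list(NULL, c("a", "b")))
    yr <- rnorm(14)
    m <- fit_ols(Xr, yr)
    expect_lte(m$Q2, m$R2 + 1e-12)
    expect_equal(m$Q2, loo_oracle(Xr, yr), tolerance = 1e-10)
  }
})

test_that("statistics are scale-equivariant and permutation-invariant", {
  set.seed(30)
  X <- matrix(rnorm(48), 16, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(2 + X %*% c(1, -2, 0.5) + rnorm(16, 0, 0.3))
  m0 <- fit_ols(X, y)
  # multiply a column by c: its X and DX divide by c; t, R2, F, Q2 unchanged
  Xs <- X; Xs[, 2] <- X[, 2] * 100
  m1 <- fit_ols(Xs, y)
  expect_equal(m1$terms$X[2], m0$terms$X[2] / 100, tolerance = 1e-10)
  expect_equal(m1$terms$DX[2], m0$terms$DX[2] / 100, tolerance = 1e-10)
  expect_equal(m1$terms$t, m0$terms$t, tolerance = 1e-10)
  expect_equal(m1$R2, m0$R2, tolerance = 1e-12)
  expect_equal(m1$F, m0$F, tolerance = 1e-10)
  expect_equal(m1$Q2, m0$Q2, tolerance = 1e-10)
  # permuting compounds changes nothing
  perm <- sample(16)
  m2 <- fit_ols(X[perm, ], y[perm])
  expect_equal(m2$coefficients, m0$coefficients, tolerance = 1e-10)
  expect_equal(m2$R2, m0$R2, tolerance = 1e-12)
  expect_equal(m2$Q2, m0$Q2, tolerance = 1e-10)
})

test_that("adding a descriptor never decreases R2", {
  for (seed in 31:35) {
    set.seed(seed)
    X <- matrix(rnorm(60), 15, 4, dimnames = list(NULL, letters[1:4]))
    y <- rnorm(15)
    r2_small <- fit_ols(X[, 1:2], y, q2 = FALSE)$R2
    r2_big <- fit_ols(X[, 1:3], y, q2 = FALSE)$R2
    expect_gte(r2_big, r2_small - 1e-12)
  }
})

test_that("degenerate designs raise informative errors", {
  set.seed(36)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  Xc <- cbind(X, c = X[, 1] + X[, 2])
  y <- rnorm(10)
  expect_error(fit_ols(Xc, y), "rank deficient")
  expect_error(fit_ols(X[1:3, ], y[1:3]), "too few compounds")
  expect_error(loo_q2(X[1:4, ], y[1:4]), "too few compounds")
})

test_that("predict applies intercept + sum of terms and errors on missing descriptors", {
  x <- matrix(1:6, 6, 1, dimnames = list(NULL, "x"))
  m <- fit_ols(x, 1 + 2 * x[, 1])
  expect_equal(unname(predict(m, matrix(3, dimnames = list(NULL, "x")))), 7)
  # training design reproduces fitted values and RSS
  set.seed(37)
  X <- matrix(rnorm(33), 11, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(11)
  mf <- fit_ols(X, y)
  expect_equal(unname(predict(mf, X)), unname(mf$fitted), tolerance = 1e-12)
  expect_equal(sum((y - predict(mf, X))^2), sum(mf$residuals^2), tolerance = 1e-12)
  # elementwise dot-product oracle on fresh rows
  Xnew <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  oracle <- mf$intercept + Xnew %*% mf$terms$X
  expect_equal(unname(predict(mf, Xnew)), drop(oracle), tolerance = 1e-12)
  expect_error(predict(mf, Xnew[, 1:2]), "c")
})

test_that("model JSON serialization round-trips coefficients and statistics", {
  set.seed(38)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(1 + X %*% c(2, -1, 0.5) + rnorm(10, 0, 0.2))
  m <- fit_ols(X, y)
  f <- tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(m2$terms$t, m$terms$t, tolerance = 1e-12)
  expect_equal(m2$R2, m$R2, tolerance = 1e-12)
  expect_equal(m2$Q2, m$Q2, tolerance = 1e-12)
  expect_equal(unname(predict(m2, X)), unname(m$fitted), tolerance = 1e-12)
})
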