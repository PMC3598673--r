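# helpers shared across the test files

# small random descriptor matrix with controllable structure
make_dm <- function(n = 12, p = 6, seed = 1, classes = NULL, role = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%02d", seq_len(n)),
                              sprintf("d%02d", seq_len(p))))
  if (is.null(classes))
    classes <- rep_len(DESCRIPTOR_CLASSES, p)
  descriptor_matrix(v, dclass = classes, role = role)
}

# independent normal-equations OLS oracle: explicit inversion of X'X
ne_oracle <- function(X, y) {
  Xd <- cbind(1, X)
  xtx_inv <- solve(t(Xd) %*% Xd)
  coef <- drop(xtx_inv %*% t(Xd) %*% y)
  res <- y - drop(Xd %*% coef)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  n <- nrow(Xd); k <- ncol(X)
  s2 <- rss / (n - k - 1)
  r2 <- 1 - rss / tss
  dx <- sqrt(s2 * diag(xtx_inv))
  list(coef = coef, dx = dx, t = abs(coef) / dx, r2 = r2, s2 = s2,
       f = (r2 / k) / ((1 - r2) / (n - k - 1)))
}

# explicit leave-one-out Q2 oracle: n refits
loo_oracle <- function(X, y) {
  n <- nrow(X)
  press <- sum(vapply(seq_len(n), function(i) {
    fit <- lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
    (y[i] - sum(c(1, X[i, ]) * fit$coefficients))^2
  }, numeric(1)))
  1 - press / sum((y - mean(y))^2)
}

# exhaustive best-subset enumeration oracle: max R2 per size via lm()
enum_best_r2 <- function(X, y, sizes) {
  vapply(sizes, function(k) {
    max(combn(ncol(X), k, FUN = function(idx) {
      summary(lm(y ~ X[, idx]))$r.squared
    }))
  }, numeric(1))
}
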