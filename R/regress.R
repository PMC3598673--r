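design_values <- function(X) {
  if (inherits(X, "descriptor_matrix")) X <- X$values
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Ordinary least squares with the classical QSAR fit statistics
#'
#' Fits `y = intercept + sum_j X_j x_j` by QR-decomposition least squares
#' and reports, for the intercept and each descriptor term, the coefficient
#' `X`, its standard error `DX` and the t value `|X|/DX`, together with the
#' global statistics: `N` (compounds), `R2 = 1 - RSS/TSS` (TSS about the
#' mean of `y`), residual variance `s2 = RSS/(N - k - 1)`, overall
#' `F = (R2/k) / ((1 - R2)/(N - k - 1))` and leave-one-out `Q2` (see
#' [loo_q2()]).
#'
#' A response with zero total variance is handled by the convention
#' `R2 = 0`, `Q2 = 0` (with a warning) so that degenerate cases cannot
#' propagate NaN through a model search.
#'
#' @param X design of selected descriptors: numeric matrix (compounds x
#'   descriptors, named columns) or a [descriptor_matrix()]. The intercept
#'   is always added internally.
#' @param y numeric response, one value per row of `X`.
#' @param q2 logical; also compute leave-one-out Q2 (default `TRUE`).
#' @return an object of class `qsar_model`: list with `intercept`, `terms`
#'   (data frame `name`, `X`, `DX`, `t`), `coefficients` (named vector,
#'   intercept first), `N`, `size` (number of descriptor terms), `R2`, `s2`,
#'   `F`, `Q2`, `fitted`, `residuals`.
#' @export
fit_ols <- function(X, y, q2 = TRUE) {
  X <- design_values(X)
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values in the design or response")
  if (n < k + 2)
    stop(sprintf("too few compounds: n = %d but k + 2 = %d required", n, k + 2))
  Xd <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) {
    coll <- colnames(Xd)[qx$pivot[(qx$rank + 1L):ncol(Xd)]]
    stop("design is rank deficient; collinear term(s): ",
         paste(coll, collapse = ", "))
  }
  coef <- qr.coef(qx, y)
  fitted <- drop(Xd %*% coef)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- n - k - 1L
  s2 <- rss / df
  degenerate <- tss <= 0
  if (degenerate) {
    warning("response has zero total variance; R2 and Q2 set to 0 by convention")
    r2 <- 0
  } else {
    r2 <- 1 - rss / tss
  }
  fstat <- if (k == 0) NA_real_
           else if (r2 >= 1) Inf
           else (r2 / k) / ((1 - r2) / df)
  # (X'X)^{-1} from the R factor, honouring any column pivoting
  Rm <- qr.R(qx)
  Ri <- backsolve(Rm, diag(ncol(Xd)))
  xtxinv_p <- Ri %*% t(Ri)
  xtxinv <- matrix(0, ncol(Xd), ncol(Xd))
  xtxinv[qx$pivot, qx$pivot] <- xtxinv_p
  dx <- sqrt(pmax(s2 * diag(xtxinv), 0))
  tval <- ifelse(dx > 0, abs(coef) / dx, ifelse(abs(coef) > 0, Inf, 0))
  model <- structure(list(
    intercept = unname(coef[1]),
    terms = data.frame(name = colnames(X),
                       X = unname(coef[-1]),
                       DX = unname(dx[-1]),
                       t = unname(tval[-1]),
                       stringsAsFactors = FALSE),
    coefficients = coef,
    intercept_DX = unname(dx[1]), intercept_t = unname(tval[1]),
    N = n, size = k, R2 = r2, s2 = s2, F = fstat, Q2 = NA_real_,
    fitted = fitted, residuals = res
  ), class = "qsar_model")
  if (q2) model$Q2 <- if (degenerate) 0 else loo_q2(X, y)
  model
}

#' Leave-one-out cross-validated Q2
#'
#' `Q2 = 1 - PRESS/TSS` where PRESS is the sum of squared leave-one-out
#' prediction errors. Computed via the hat-matrix identity
#' `e_i / (1 - h_ii)` from a single full fit; when any leverage approaches 1
#' (`h_ii > 1 - 1e-8`) the function falls back to n explicit refits, each
#' excluding one compound.
#'
#' @inheritParams fit_ols
#' @return the Q2 value (at most the R2 of the same fit).
#' @export
loo_q2 <- function(X, y) {
  X <- design_values(X)
  y <- as.numeric(y)
  n <- nrow(X); k <- ncol(X)
  if (n < k + 3)
    stop(sprintf("too few compounds for leave-one-out: n = %d, need >= %d", n, k + 3))
  Xd <- cbind(1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) stop("design is rank deficient")
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) {
    warning("response has zero total variance; Q2 set to 0 by convention")
    return(0)
  }
  res <- qr.resid(qx, y)
  h <- rowSums(qr.Q(qx)^2)
  if (any(h > 1 - 1e-8)) {
    press <- sum(vapply(seq_len(n), function(i) {
      qi <- qr(Xd[-i, , drop = FALSE])
      ci <- qr.coef(qi, y[-i])
      (y[i] - sum(Xd[i, ] * ci))^2
    }, numeric(1)))
  } else {
    press <- sum((res / (1 - h))^2)
  }
  1 - press / tss
}

#' Predict from a fitted QSAR model
#'
#' @param object a `qsar_model` from [fit_ols()].
#' @param newdata numeric matrix, data frame or [descriptor_matrix()]
#'   containing a column for every model term.
#' @param ... ignored.
#' @return numeric vector `intercept + sum_j X_j x_j` per row.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  V <- design_values(newdata)
  need <- object$terms$name
  miss <- setdiff(need, colnames(V))
  if (length(miss))
    stop("newdata lacks model descriptor(s): ", paste(miss, collapse = ", "))
  drop(object$intercept + V[, need, drop = FALSE] %*% object$terms$X)
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> N=%d  R2=%.4f  F=%.4g  s2=%.4g  Q2=%s  (%d, RANK)\n",
              x$N, x$R2, x$F, x$s2,
              if (is.na(x$Q2)) "NA" else sprintf("%.4f", x$Q2), x$size))
  tab <- rbind(
    data.frame(name = "Intercept", X = x$intercept, DX = x$intercept_DX,
               t = x$intercept_t, stringsAsFactors = FALSE),
    x$terms)
  rownames(tab) <- seq_len(nrow(tab)) - 1L
  print(tab, digits = 5)
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Mirrors the printed best-linear-model layout: one row per term
#' (row 0 = intercept) with `X`, `DX`, `t`, plus the header statistics and
#' the `(size, RANK)` annotation.
#'
#' @param model a `qsar_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  rows <- c(list(list(row = 0L, name = "Intercept", X = model$intercept,
                      DX = model$intercept_DX, t = model$intercept_t)),
            lapply(seq_len(model$size), function(j)
              list(row = j, name = model$terms$name[j], X = model$terms$X[j],
                   DX = model$terms$DX[j], t = model$terms$t[j])))
  jsonlite::write_json(list(
    N = model$N, R2 = model$R2, F = model$F, s2 = model$s2, Q2 = model$Q2,
    size_rank = sprintf("(%d, RANK)", model$size), terms = rows
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model_json()]
#'
#' @param path path to the JSON file.
#' @return a `qsar_model` (without fitted values or residuals).
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- j$terms[j$terms$row > 0, , drop = FALSE]
  ic <- j$terms[j$terms$row == 0, , drop = FALSE]
  coef <- stats::setNames(c(ic$X, terms$X), c("(Intercept)", terms$name))
  structure(list(
    intercept = ic$X,
    terms = data.frame(name = terms$name, X = terms$X, DX = terms$DX,
                       t = terms$t, stringsAsFactors = FALSE),
    coefficients = coef,
    intercept_DX = ic$DX, intercept_t = ic$t,
    N = j$N, size = nrow(terms), R2 = j$R2, s2 = j$s2, F = j$F, Q2 = j$Q2,
    fitted = NULL, residuals = NULL
  ), class = "qsar_model")
}
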