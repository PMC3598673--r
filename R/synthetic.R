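#' Specification of a synthetic QSAR benchmark dataset
#'
#' Describes a class-labelled descriptor matrix with correlated blocks and a
#' sparse linear response, mirroring the structure the model-building
#' pipeline assumes: 18 training and 7 test compounds, about 40 descriptors
#' spread over the six descriptor classes, within-class equicorrelation,
#' and a response driven by a small support of descriptors (default four
#' terms, one dominant positive and one negative coefficient) plus Gaussian
#' noise. Planted confounders — near-duplicate, constant and incomplete
#' descriptors, always outside the support — exercise the preselection
#' screens.
#'
#' @param n_train,n_test training and test set sizes (defaults 18 and 7).
#' @param class_sizes named integer vector of descriptor counts per class;
#'   default `c(constitutional = 8, topological = 6, geometrical = 5,
#'   electrostatic = 6, thermodynamic = 5, quantum_chemical = 10)` (40 in
#'   total).
#' @param block_rho within-class equicorrelation in `[0, 1)`; default 0.3.
#' @param support named numeric vector of true coefficients, names =
#'   descriptor column indices as integers; default
#'   `c(40, -25, 15, 10)` placed on the first descriptor of four different
#'   classes.
#' @param intercept true intercept; default 200 (a percent-of-control
#'   scale).
#' @param noise_sd Gaussian noise standard deviation; `NULL` (default) uses
#'   5% of the standard deviation of the noiseless signal.
#' @param n_dup,n_const,n_missing planted near-duplicate, constant and
#'   incomplete descriptors (defaults 2 each), never placed on the support.
#' @param scale_mix if `TRUE`, multiply each descriptor column by a
#'   log-uniform factor in `[1e-3, 1e3]` to emulate mixed descriptor units.
#' @param seed integer seed; the dataset is a pure function of these settings.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_train = 18L, n_test = 7L,
                           class_sizes = c(constitutional = 8L, topological = 6L,
                                           geometrical = 5L, electrostatic = 6L,
                                           thermodynamic = 5L, quantum_chemical = 10L),
                           block_rho = 0.3,
                           support = NULL, intercept = 200,
                           noise_sd = NULL,
                           n_dup = 2L, n_const = 2L, n_missing = 2L,
                           scale_mix = FALSE, seed = 1L) {
  stopifnot(n_train >= 4, n_test >= 0, block_rho >= 0, block_rho < 1,
            all(class_sizes >= 0), sum(class_sizes) >= 1,
            n_dup >= 0, n_const >= 0, n_missing >= 0)
  if (is.null(names(class_sizes)) ||
      !all(names(class_sizes) %in% DESCRIPTOR_CLASSES))
    stop("class_sizes must be named by descriptor class")
  p <- sum(class_sizes)
  if (is.null(support)) {
    # first column of the four largest classes, strongest effect first
    starts <- cumsum(c(0, class_sizes[-length(class_sizes)])) + 1L
    names(starts) <- names(class_sizes)
    ord <- order(-class_sizes)
    idx <- starts[ord[1:4]]
    support <- stats::setNames(c(40, -25, 15, 10), idx)
  }
  s_idx <- as.integer(names(support))
  if (anyDuplicated(s_idx) || any(s_idx < 1) || any(s_idx > p))
    stop("support indices must be distinct and within 1..", p)
  if (n_train < 3 * length(support) + 2)
    stop("n_train must be at least 3 * |support| + 2")
  if (n_dup + n_const + n_missing > p - length(support))
    stop("not enough non-support descriptors to plant confounders on")
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 class_sizes = class_sizes, block_rho = block_rho,
                 support = support, intercept = intercept, noise_sd = noise_sd,
                 n_dup = as.integer(n_dup), n_const = as.integer(n_const),
                 n_missing = as.integer(n_missing),
                 scale_mix = isTRUE(scale_mix), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic descriptor matrix and response
#'
#' Draws standard-normal descriptor columns with equicorrelation
#' `block_rho` within each class and independence across classes, plants
#' the confounders requested in the [synthetic_spec()], and computes
#' `y = intercept + sum_j beta_j x_j + N(0, noise_sd)`. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` (a [descriptor_matrix()] of
#'   `n_train + n_test` compounds with roles assigned), `y` (numeric
#'   response) and `truth` (list: `support` indices, `beta`, `support_names`,
#'   `intercept`, `noise_sd`, `signal` — the noiseless response — `noise`,
#'   and the planted `dup`, `const`, `missing` descriptor names).
#' @export
generate_qsar_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_train + spec$n_test
  p <- sum(spec$class_sizes)
  cls <- rep(names(spec$class_sizes), spec$class_sizes)
  rho <- spec$block_rho
  X <- matrix(0, n, p)
  start <- 1L
  for (ci in seq_along(spec$class_sizes)) {
    pc <- spec$class_sizes[ci]
    if (pc == 0) next
    shared <- stats::rnorm(n)
    E <- matrix(stats::rnorm(n * pc), n, pc)
    X[, start:(start + pc - 1L)] <- sqrt(rho) * shared + sqrt(1 - rho) * E
    start <- start + pc
  }
  colnames(X) <- sprintf("%s_%02d", cls, stats::ave(seq_len(p), cls, FUN = seq_along))
  rownames(X) <- sprintf("cmpd_%02d", seq_len(n))

  s_idx <- as.integer(names(spec$support))
  beta <- unname(spec$support)
  signal <- spec$intercept + drop(X[, s_idx, drop = FALSE] %*% beta)
  noise_sd <- if (is.null(spec$noise_sd)) 0.05 * stats::sd(signal) else spec$noise_sd
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  y <- signal + noise

  # plant confounders on non-support columns (dup sources also non-support)
  free <- setdiff(seq_len(p), s_idx)
  n_plant <- spec$n_dup + spec$n_const + spec$n_missing
  planted <- if (n_plant > 0) sample(free, n_plant) else integer(0)
  dup_cols <- utils::head(planted, spec$n_dup)
  const_cols <- planted[seq_len(spec$n_const) + spec$n_dup]
  miss_cols <- utils::tail(planted, spec$n_missing)
  dup_src <- if (spec$n_dup > 0)
    sample(setdiff(free, planted), spec$n_dup) else integer(0)
  for (i in seq_along(dup_cols)) {
    # sd 0.04 perturbation of a unit-variance column gives |r| ~ 0.9992 > 0.99
    X[, dup_cols[i]] <- X[, dup_src[i]] + stats::rnorm(n, 0, 0.04)
  }
  if (length(const_cols)) X[, const_cols] <- rep(stats::rnorm(length(const_cols)),
                                                 each = n)
  for (j in miss_cols) {
    # at least one missing cell among the training compounds
    X[sample(spec$n_train, 1L), j] <- NA
  }
  if (spec$scale_mix) {
    fac <- 10^stats::runif(p, -3, 3)
    keepna <- is.na(X)
    X <- sweep(X, 2, fac, `*`)
    X[keepna] <- NA
  }

  role <- rep(c("training", "test"), c(spec$n_train, spec$n_test))
  m <- descriptor_matrix(X, dclass = cls, role = role)
  truth <- list(support = s_idx, beta = beta,
                support_names = colnames(X)[s_idx],
                intercept = spec$intercept, noise_sd = noise_sd,
                signal = signal, noise = noise,
                dup = colnames(X)[dup_cols], dup_source = colnames(X)[dup_src],
                const = colnames(X)[const_cols],
                missing = colnames(X)[miss_cols])
  list(matrix = m, y = y, truth = truth)
}

#' Support-recovery experiment
#'
#' Runs the full pipeline — generate, preselect, heuristic search, external
#' validation — over `n_reps` replicates (replicate `r` uses seed
#' `spec$seed + r - 1`) and summarizes how often the chosen model's
#' descriptor support equals the planted support.
#'
#' @param spec a [synthetic_spec()].
#' @param config a [search_config()].
#' @param n_reps number of replicates (>= 1).
#' @param r_dup,invariant_tol preselection thresholds.
#' @return a `recovery_summary`: list with `n_reps`, `recovery_rate`
#'   (fraction of replicates whose chosen support is exactly the planted
#'   one), `mean_coef_rmse` (root-mean-square coefficient error over the
#'   exactly-recovered fits), `mean_test_ARE`, `mean_r2_q2_gap`
#'   (mean `R2 - Q2` of the chosen models), `q2_gt_r2_violations`, and
#'   `per_rep` (data frame log, one row per replicate).
#' @export
recovery_experiment <- function(spec, config = search_config(), n_reps = 100L,
                                r_dup = 0.99, invariant_tol = 1e-12) {
  stopifnot(inherits(spec, "synthetic_spec"), n_reps >= 1)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sp <- spec
    sp$seed <- spec$seed + r - 1L
    dat <- generate_qsar_data(sp)
    split <- split_train_test(dat$matrix)
    tr_idx <- match(split$training$compounds$id, dat$matrix$compounds$id)
    te_idx <- match(split$test$compounds$id, dat$matrix$compounds$id)
    pre <- preselect(split$training, dat$y[tr_idx],
                     r_dup = r_dup, invariant_tol = invariant_tol)
    ladder <- heuristic_search(pre$matrix, dat$y[tr_idx], config)
    chosen <- ladder$chosen
    recovered <- FALSE; rmse <- NA_real_; mean_are <- NA_real_
    r2 <- NA_real_; q2 <- NA_real_
    if (!is.null(chosen)) {
      recovered <- setequal(chosen$terms$name, dat$truth$support_names)
      if (recovered) {
        bhat <- chosen$terms$X[match(dat$truth$support_names, chosen$terms$name)]
        rmse <- sqrt(mean((bhat - dat$truth$beta)^2))
      }
      val <- external_validation(chosen, split$test[, pre$survivors],
                                 dat$y[te_idx])
      mean_are <- val$mean_ARE
      r2 <- chosen$R2; q2 <- chosen$Q2
    }
    rows[[r]] <- data.frame(rep = r, seed = sp$seed, recovered = recovered,
                            coef_rmse = rmse, mean_test_ARE = mean_are,
                            R2 = r2, Q2 = q2,
                            chosen_size = if (is.null(chosen)) NA_integer_ else chosen$size,
                            stringsAsFactors = FALSE)
  }
  per_rep <- do.call(rbind, rows)
  structure(list(
    n_reps = n_reps,
    recovery_rate = mean(per_rep$recovered),
    mean_coef_rmse = if (any(per_rep$recovered))
      mean(per_rep$coef_rmse[per_rep$recovered]) else NA_real_,
    mean_test_ARE = mean(per_rep$mean_test_ARE, na.rm = TRUE),
    mean_r2_q2_gap = mean(per_rep$R2 - per_rep$Q2, na.rm = TRUE),
    q2_gt_r2_violations = sum(per_rep$Q2 > per_rep$R2 + 1e-12, na.rm = TRUE),
    per_rep = per_rep
  ), class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery_summary> %d reps | support recovery %.1f%% | coef RMSE %.4g | mean test ARE %.4f | mean R2-Q2 gap %.4f\n",
              x$n_reps, 100 * x$recovery_rate, x$mean_coef_rmse,
              x$mean_test_ARE, x$mean_r2_q2_gap))
  invisible(x)
}
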