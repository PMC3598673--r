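#' Absolute relative error
#'
#' `|actual - predicted| / |actual|`, the external-validation statistic used
#' to compare predicted and experimental uptake values. Scale invariant:
#' multiplying both arguments by a non-zero constant leaves it unchanged.
#'
#' @param actual experimental value(s), non-zero.
#' @param predicted predicted value(s).
#' @return numeric vector of non-negative errors.
#' @examples
#' absolute_relative_error(181, 188)  # ~0.0387
#' @export
absolute_relative_error <- function(actual, predicted) {
  if (any(actual == 0)) stop("ARE is undefined for actual == 0")
  abs(actual - predicted) / abs(actual)
}

#' External validation of a fitted model on held-out compounds
#'
#' Predicts the test-set responses, computes the per-compound absolute
#' relative error, and summarizes predictive performance.
#'
#' @param model a `qsar_model` from [fit_ols()].
#' @param test_matrix a [descriptor_matrix()] (or named numeric matrix) with
#'   the test compounds; must contain every model term.
#' @param y_test experimental responses for the test compounds, non-zero.
#' @param threshold ARE pass level per compound (default 0.10).
#' @return a `validation_report`: list with `per_compound` (data frame of
#'   compound, experimental, predicted, ARE, pass), `test_R2` (squared
#'   Pearson correlation of experimental vs predicted), `test_Q2_analog`
#'   (`1 - sum((e - p)^2) / sum((e - mean(e))^2)` on the test set),
#'   `mean_ARE`, `max_ARE`, `n_pass` (compounds with ARE <= threshold),
#'   `threshold` and `overall_pass` (every ARE <= threshold).
#' @export
external_validation <- function(model, test_matrix, y_test, threshold = 0.10) {
  stopifnot(inherits(model, "qsar_model"))
  pred <- stats::predict(model, test_matrix)
  y_test <- as.numeric(y_test)
  if (length(y_test) != length(pred))
    stop("y_test length does not match the number of test compounds")
  are <- absolute_relative_error(y_test, pred)
  ids <- if (inherits(test_matrix, "descriptor_matrix"))
    test_matrix$compounds$id else rownames(design_values(test_matrix))
  if (is.null(ids)) ids <- paste0("compound_", seq_along(pred))
  tss <- sum((y_test - mean(y_test))^2)
  r2 <- if (stats::sd(pred) == 0 || tss == 0) NA_real_
        else stats::cor(y_test, pred)^2
  q2a <- if (tss == 0) NA_real_ else 1 - sum((y_test - pred)^2) / tss
  structure(list(
    per_compound = data.frame(compound = ids, experimental = y_test,
                              predicted = unname(pred), ARE = unname(are),
                              pass = unname(are <= threshold),
                              stringsAsFactors = FALSE),
    test_R2 = r2, test_Q2_analog = q2a,
    mean_ARE = mean(are), max_ARE = max(are),
    n_pass = sum(are <= threshold), threshold = threshold,
    overall_pass = all(are <= threshold)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n=%d  test R2=%s  mean ARE=%.4f  pass %d/%d (<= %.0f%%): %s\n",
              nrow(x$per_compound),
              if (is.na(x$test_R2)) "NA" else sprintf("%.4f", x$test_R2),
              x$mean_ARE, x$n_pass, nrow(x$per_compound), 100 * x$threshold,
              if (x$overall_pass) "PASS" else "FAIL"))
  print(x$per_compound, digits = 4)
  invisible(x)
}

#' Median-split odds ratio of each descriptor against the response
#'
#' A screening statistic for ranking descriptors as potential contributors:
#' descriptor and response are each dichotomized at their medians, the 2x2
#' table of (descriptor high/low) x (response high/low) is formed with the
#' Haldane-Anscombe correction (0.5 added to every cell), and the odds
#' ratio `(a*d)/(b*c)` is returned. Values far from 1 mark concordant
#' (OR > 1) or discordant (OR < 1) descriptors. This is a screening report
#' only; it does not gate the model search.
#'
#' @param m a [descriptor_matrix()] or named numeric matrix, at least 4
#'   compounds.
#' @param y numeric response aligned with the rows.
#' @return named numeric vector of odds ratios, one per descriptor.
#' @export
descriptor_odds_ratio <- function(m, y) {
  X <- design_values(m)
  y <- as.numeric(y)
  if (nrow(X) < 4) stop("need at least 4 compounds")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  yhi <- y > stats::median(y)
  apply(X, 2, function(x) {
    med <- stats::median(x)
    if (all(x == med)) stop("descriptor equal to its median everywhere; drop invariants first")
    xhi <- x > med
    a <- sum(xhi & yhi) + 0.5
    b <- sum(xhi & !yhi) + 0.5
    c <- sum(!xhi & yhi) + 0.5
    d <- sum(!xhi & !yhi) + 0.5
    (a * d) / (b * c)
  })
}

#' Two-fold cross-validation scheme
#'
#' Runs the full model-building and validation scheme: (1) split the
#' compounds into training and test sets by the supplied roles; (2)
#' categorize the descriptors by class; (3) compute the median-split odds
#' ratio screen on the training set; (4) preselect and search on the
#' training set only, then score every per-size candidate model on the test
#' set by mean absolute relative error. The scheme's selected model is the
#' candidate with the lowest mean test ARE; its training-set overall F-test
#' p-value is reported as the model-consistency check (significant when
#' below `p_max`). Descriptor randomization uses the seed in `config`, so
#' identical inputs give identical reports.
#'
#' @param m a [descriptor_matrix()] covering training and test compounds.
#' @param y numeric response aligned with the rows of `m`.
#' @param roles named character vector id -> `"training"`/`"test"`;
#'   defaults to the roles stored in `m`.
#' @param config a [search_config()].
#' @param r_dup,invariant_tol preselection thresholds (see [preselect()]).
#' @param are_threshold per-compound ARE pass level (default 0.10).
#' @param p_max significance level for the consistency check (default 0.05).
#' @return a `cv_scheme_report`: list with `selected` (`qsar_model`),
#'   `selected_size`, `validation` (the selected model's
#'   [external_validation()] report), `candidates` (data frame per size:
#'   training R2/Q2/F, mean and max test ARE), `ladder`, `preselect`,
#'   `class_table`, `odds_ratio` (screen with seeded descriptor numbers),
#'   `consistency_p`, `consistent`, and `seed`.
#' @export
crossvalidate_scheme <- function(m, y, roles = NULL, config = search_config(),
                                 r_dup = 0.99, invariant_tol = 1e-12,
                                 are_threshold = 0.10, p_max = 0.05) {
  stopifnot(inherits(m, "descriptor_matrix"))
  y <- as.numeric(y)
  if (length(y) != nrow(m$values)) stop("length(y) must match the compounds")
  # step 1: partition
  sp <- split_train_test(m, roles)
  tr_idx <- match(sp$training$compounds$id, m$compounds$id)
  te_idx <- match(sp$test$compounds$id, m$compounds$id)
  y_tr <- y[tr_idx]; y_te <- y[te_idx]
  # step 2: class categorization
  class_table <- table(factor(sp$training$descriptors$dclass,
                              levels = DESCRIPTOR_CLASSES))
  # preselection on training compounds only
  pre <- preselect(sp$training, y_tr, r_dup = r_dup, invariant_tol = invariant_tol)
  # step 3: odds-ratio screen, with a seeded random number per descriptor
  # (a reproducible stand-in for assigning descriptors random labels)
  or_screen <- descriptor_odds_ratio(pre$matrix, y_tr)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  rng <- sample.int(10000L, length(or_screen))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  odds_ratio <- data.frame(descriptor = names(or_screen),
                           random_number = rng,
                           odds_ratio = unname(or_screen),
                           stringsAsFactors = FALSE)
  # step 4: search on training, score candidates on the test set
  ladder <- heuristic_search(pre$matrix, y_tr, config)
  test_m <- sp$test[, pre$survivors]
  cand <- lapply(seq_along(ladder$best_per_size), function(k) {
    mod <- ladder$best_per_size[[k]]
    val <- external_validation(mod, test_m, y_te, threshold = are_threshold)
    data.frame(size = k, R2 = mod$R2, Q2 = mod$Q2, F = mod$F,
               mean_test_ARE = val$mean_ARE, max_test_ARE = val$max_ARE,
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand)
  sel_size <- cand$size[order(cand$mean_test_ARE, cand$size)][1]
  selected <- ladder$best_per_size[[sel_size]]
  validation <- external_validation(selected, test_m, y_te,
                                    threshold = are_threshold)
  consistency_p <- stats::pf(selected$F, selected$size,
                             selected$N - selected$size - 1, lower.tail = FALSE)
  structure(list(selected = selected, selected_size = sel_size,
                 validation = validation, candidates = cand,
                 ladder = ladder, preselect = pre,
                 class_table = class_table, odds_ratio = odds_ratio,
                 consistency_p = consistency_p,
                 consistent = is.finite(consistency_p) && consistency_p < p_max,
                 seed = config$seed),
            class = "cv_scheme_report")
}

#' @export
print.cv_scheme_report <- function(x, ...) {
  cat(sprintf("<cv_scheme_report> selected size %d | mean test ARE %.4f | consistency p %.3g (%s) | seed %d\n",
              x$selected_size, x$validation$mean_ARE, x$consistency_p,
              if (x$consistent) "significant" else "not significant", x$seed))
  print(x$candidates, digits = 4)
  invisible(x)
}
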