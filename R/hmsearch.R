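#' Configuration of the heuristic model search
#'
#' @param r_pair maximum absolute pairwise correlation allowed between
#'   descriptors co-occurring in one model (default 0.8).
#' @param max_size largest model size, or `"auto"` for `floor(N/3)` — the
#'   convention that a final model carries fewer descriptors than one third
#'   of the number of compounds.
#' @param beam_width number of models retained per size during the search.
#' @param t_min minimum t value required of every descriptor term, or
#'   `"auto"` for a two-sided critical value at alpha = 0.05 with
#'   `N - k - 1` degrees of freedom (recomputed at each size `k`). With
#'   `"auto"` the stage filter uses the plain per-term critical value, while
#'   the final acceptability gate Bonferroni-corrects it for the number of
#'   candidate-entry tests the search has examined, so that a term selected
#'   for having the maximum spurious t among many candidates is not
#'   mistaken for a significant one. A numeric `t_min` is used as-is in
#'   both places.
#' @param q2_min leave-one-out Q2 acceptability gate for the final choice
#'   (default 0.5).
#' @param rank_by stage ranking criterion, `"R2"` (default). Within a fixed
#'   size R2 and F order models identically; the option exists for clarity.
#' @param choose_by criterion comparing the per-size best models when
#'   selecting the final model: `"F"` (default; the overall F-statistic
#'   penalizes superfluous terms) or `"R2"`.
#' @param exhaustive if `TRUE` the beam is never truncated, so the search
#'   enumerates every reachable subset (use only for small descriptor
#'   counts).
#' @param seed integer seed recorded in reports (the search itself is
#'   deterministic).
#' @return a `search_config` list.
#' @export
search_config <- function(r_pair = 0.8, max_size = "auto", beam_width = 50L,
                          t_min = "auto", q2_min = 0.5,
                          rank_by = c("R2", "F"), choose_by = c("F", "R2"),
                          exhaustive = FALSE, seed = 1L) {
  stopifnot(r_pair > 0, r_pair <= 1, beam_width >= 1,
            identical(max_size, "auto") || max_size >= 1)
  structure(list(r_pair = r_pair, max_size = max_size,
                 beam_width = as.integer(beam_width), t_min = t_min,
                 q2_min = q2_min, rank_by = match.arg(rank_by),
                 choose_by = match.arg(choose_by),
                 exhaustive = isTRUE(exhaustive), seed = as.integer(seed)),
            class = "search_config")
}

# t gate at size k with n - k - 1 residual df. With t_min = "auto" the
# critical value is two-sided alpha = 0.05; m > 1 Bonferroni-corrects it for
# the m descriptors that competed to enter at that size. The stage filter
# uses m = 1 (a mild screen, so multi-step paths to a good model stay open);
# the final acceptability gate uses the corrected value, because the best
# model of each size carries the maximum spurious t over all m candidate
# extensions, which exceeds the uncorrected critical value far too often —
# and any term passing the stage gate also inflates R2, F and Q2, so no
# goodness-of-fit comparison alone can reject it.
t_min_at <- function(config, n, k, m = 1L) {
  if (identical(config$t_min, "auto"))
    stats::qt(1 - 0.025 / max(m, 1L), df = n - k - 1)
  else config$t_min
}

# fast OLS summary used inside the search: coefficients, RSS and per-term t.
# Xd already carries the intercept column.
ols_core <- function(Xd, y) {
  z <- .lm.fit(Xd, y)
  p <- ncol(Xd)
  if (z$rank < p) return(NULL)
  rss <- sum(z$residuals^2)
  df <- nrow(Xd) - p
  s2 <- rss / df
  Rm <- z$qr[seq_len(p), , drop = FALSE]
  Rm[lower.tri(Rm)] <- 0
  Ri <- backsolve(Rm, diag(p))
  d <- rowSums(Ri * Ri)  # diag of (X'X)^{-1}, pivoted order
  dx2 <- numeric(p); dx2[z$pivot] <- d * s2
  coef <- numeric(p); coef[z$pivot] <- z$coefficients[seq_len(p)]
  dx <- sqrt(pmax(dx2, 0))
  tval <- ifelse(dx > 0, abs(coef) / dx, ifelse(abs(coef) > 0, Inf, 0))
  list(coef = coef, rss = rss, t = tval)
}

subset_key <- function(idx) paste(sprintf("%04d", sort(idx)), collapse = ".")

#' Heuristic best-subset search for the best linear model
#'
#' Incremental best-subset multiple linear regression over a preselected
#' descriptor matrix. The size-1 stage fits every descriptor and keeps the
#' top `beam_width` models by R2. Each later stage extends every kept model
#' by every descriptor whose absolute correlation with each included
#' descriptor is at most `r_pair`, refits, discards models in which any
#' descriptor term has `t < t_min`, and again keeps the top `beam_width` by
#' R2. The search stops at `max_size` or when no candidate survives.
#'
#' The final model is chosen among the per-size best models that pass the
#' acceptability gates: leave-one-out `Q2 >= q2_min`, and every descriptor
#' term significant at the gate threshold (with `t_min = "auto"` this is
#' the alpha = 0.05 critical value Bonferroni-corrected for all the
#' candidate-entry tests examined up to that size — see [search_config()]).
#' Among the gated models the default picks the one with the highest
#' overall F-statistic (ties go to the smaller size, then to earlier
#' descriptor order); `choose_by = "R2"` picks the highest-R2 gated model
#' instead.
#'
#' @param m a preselected [descriptor_matrix()] (training compounds) or a
#'   plain numeric matrix with named columns.
#' @param y numeric response aligned with the rows.
#' @param config a [search_config()].
#' @return a `model_ladder`: list with `best_per_size` (list of
#'   `qsar_model`, indexed by size), `subsets_per_size` (descriptor index
#'   vectors), `chosen` (a `qsar_model`, or `NULL` if no model passes the
#'   gates), `chosen_size`, `audit` (per-size data frame of candidate
#'   counts and rejection reasons) and `config`.
#' @export
heuristic_search <- function(m, y, config = search_config()) {
  X <- design_values(m)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 1) stop("no descriptors to search over")
  if (n < 4) stop("need at least 4 compounds for a size-1 model")
  if (anyNA(X)) stop("missing values present; run preselect() first")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance descriptor(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  max_size <- if (identical(config$max_size, "auto")) floor(n / 3) else config$max_size
  max_size <- min(max_size, p, n - 3L)
  beam_w <- if (config$exhaustive) .Machine$integer.max else config$beam_width
  acor <- abs(stats::cor(X))
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("response has zero variance")

  best_per_size <- list()
  subsets_per_size <- list()
  audit <- list()

  # stage 1: every single descriptor, ranked by R2 (no t filter at size 1)
  r1 <- as.vector(stats::cor(X, y))^2
  ord <- order(-r1, seq_len(p))
  beam <- lapply(ord[seq_len(min(beam_w, p))], function(j) j)
  best_per_size[[1]] <- fit_ols(X[, beam[[1]], drop = FALSE], y)
  subsets_per_size[[1]] <- beam[[1]]
  audit[[1]] <- data.frame(size = 1L, evaluated = p, blocked_corr = 0L,
                           duplicate = 0L, t_rejected = 0L,
                           kept = length(beam))

  size <- 1L
  while (size < max_size) {
    k <- size + 1L
    tmin <- t_min_at(config, n, k)
    cand_subset <- list(); cand_r2 <- numeric(0); cand_key <- character(0)
    n_eval <- 0L; n_block <- 0L; n_dup <- 0L; n_trej <- 0L
    seen <- new.env(parent = emptyenv())
    for (S in beam) {
      free <- setdiff(seq_len(p), S)
      if (!length(free)) next
      okc <- free[apply(acor[free, S, drop = FALSE], 1, max) <= config$r_pair]
      n_block <- n_block + (length(free) - length(okc))
      if (!length(okc)) next
      qx <- qr(cbind(1, X[, S, drop = FALSE]))
      ry <- qr.resid(qx, y)
      rssS <- sum(ry^2)
      Z <- qr.resid(qx, X[, okc, drop = FALSE])
      zz <- colSums(Z^2)
      zy <- as.vector(crossprod(Z, ry))
      valid <- zz > 1e-12 * n
      delta <- rep(0, length(okc))
      delta[valid] <- zy[valid]^2 / zz[valid]
      rss_new <- pmax(rssS - delta, 0)
      # t of the added term in the refit model, computed in closed form
      t_new <- ifelse(rss_new > 0,
                      sqrt(delta * (n - k - 1) / rss_new),
                      ifelse(delta > 0, Inf, 0))
      for (ii in seq_along(okc)) {
        if (!valid[ii]) { n_block <- n_block + 1L; next }
        n_eval <- n_eval + 1L
        if (t_new[ii] < tmin) { n_trej <- n_trej + 1L; next }
        sub <- c(S, okc[ii])
        key <- subset_key(sub)
        if (!is.null(seen[[key]])) { n_dup <- n_dup + 1L; next }
        assign(key, TRUE, envir = seen)
        cand_subset[[length(cand_subset) + 1L]] <- sub
        cand_r2 <- c(cand_r2, 1 - rss_new[ii] / tss)
        cand_key <- c(cand_key, key)
      }
    }
    if (!length(cand_subset)) break
    ordc <- order(-cand_r2, cand_key)
    kept_sub <- list(); kept_first_fit <- NULL
    for (ci in ordc) {
      sub <- cand_subset[[ci]]
      fit <- ols_core(cbind(1, X[, sub, drop = FALSE]), y)
      if (is.null(fit)) next
      if (any(fit$t[-1] < tmin)) { n_trej <- n_trej + 1L; next }
      kept_sub[[length(kept_sub) + 1L]] <- sub
      if (length(kept_sub) == 1L) kept_first_fit <- fit
      if (length(kept_sub) >= beam_w) break
    }
    audit[[k]] <- data.frame(size = k, evaluated = n_eval, blocked_corr = n_block,
                             duplicate = n_dup, t_rejected = n_trej,
                             kept = length(kept_sub))
    if (!length(kept_sub)) break
    beam <- kept_sub
    best_per_size[[k]] <- fit_ols(X[, kept_sub[[1]], drop = FALSE], y)
    subsets_per_size[[k]] <- kept_sub[[1]]
    size <- k
  }

  # final choice among per-size best models passing the acceptability gates
  sizes <- seq_along(best_per_size)
  # cumulative count of candidate-entry tests examined up to size k: p single
  # models, then p - j + 1 eligible descriptors at each stage j
  m_cum <- function(k) p + if (k >= 2) sum(p - 2:k + 1L) else 0L
  gate <- vapply(sizes, function(k) {
    mod <- best_per_size[[k]]
    tmin <- t_min_at(config, n, k, m = m_cum(k))
    is.finite(mod$Q2) && mod$Q2 >= config$q2_min && all(mod$terms$t >= tmin)
  }, logical(1))
  chosen <- NULL; chosen_size <- NA_integer_
  if (any(gate)) {
    crit <- vapply(sizes, function(k) {
      mod <- best_per_size[[k]]
      if (config$choose_by == "F") mod$F else mod$R2
    }, numeric(1))
    crit[!gate] <- -Inf
    keys <- vapply(sizes, function(k) subset_key(subsets_per_size[[k]]), character(1))
    chosen_size <- sizes[order(-crit, sizes, keys)][1]
    chosen <- best_per_size[[chosen_size]]
  } else {
    warning("no model passed the Q2/t acceptability gates; `chosen` is NULL")
  }
  structure(list(best_per_size = best_per_size,
                 subsets_per_size = subsets_per_size,
                 chosen = chosen, chosen_size = chosen_size,
                 audit = do.call(rbind, audit), config = config,
                 descriptor_names = colnames(X)),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat(sprintf("<model_ladder> sizes 1..%d, chosen size: %s\n",
              length(x$best_per_size),
              if (is.na(x$chosen_size)) "none" else x$chosen_size))
  print(rank_report(x), digits = 4)
  invisible(x)
}

#' Per-size summary of a model ladder
#'
#' @param ladder a `model_ladder` from [heuristic_search()].
#' @return data frame with one row per size: `size`, `R2`, `Q2`, `F`, `s2`,
#'   `chosen` flag and the descriptor names of the best model of that size.
#' @export
rank_report <- function(ladder) {
  stopifnot(inherits(ladder, "model_ladder"))
  if (!length(ladder$best_per_size)) stop("empty ladder")
  rows <- lapply(seq_along(ladder$best_per_size), function(k) {
    mod <- ladder$best_per_size[[k]]
    data.frame(size = k, R2 = mod$R2, Q2 = mod$Q2, F = mod$F, s2 = mod$s2,
               chosen = identical(k, ladder$chosen_size),
               descriptors = paste(mod$terms$name, collapse = " + "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
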