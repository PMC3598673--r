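#' Drop descriptors with missing values
#'
#' Removes every descriptor that is not observed for all compounds in the
#' matrix (the completeness rule of heuristic preselection). Run on the
#' training compounds only so the test set cannot influence selection.
#'
#' @param m a [descriptor_matrix()].
#' @return list with `matrix` (the reduced `descriptor_matrix`) and
#'   `dropped` (character vector of removed descriptor names).
#' @export
drop_incomplete <- function(m) {
  stopifnot(inherits(m, "descriptor_matrix"))
  bad <- colSums(is.na(m$values)) > 0
  list(matrix = m[, !bad], dropped = colnames(m$values)[bad])
}

#' Drop invariant descriptors
#'
#' Removes descriptors whose values do not vary across the compounds: the
#' column range (max minus min) is at most `tol`.
#'
#' @param m a [descriptor_matrix()] with no missing values.
#' @param tol non-negative absolute tolerance on the value range
#'   (default 1e-12).
#' @return list with `matrix` and `dropped` as in [drop_incomplete()].
#' @export
drop_invariant <- function(m, tol = 1e-12) {
  stopifnot(inherits(m, "descriptor_matrix"), tol >= 0)
  v <- m$values
  rng <- apply(v, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) 0 else max(x) - min(x)
  })
  bad <- rng <= tol
  list(matrix = m[, !bad], dropped = colnames(v)[bad])
}

#' Pearson correlation matrix of the descriptors
#'
#' @param m a [descriptor_matrix()] with no missing values and no
#'   zero-variance columns.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(m) {
  stopifnot(inherits(m, "descriptor_matrix"))
  v <- m$values
  if (anyNA(v)) stop("missing values present; run drop_incomplete() first")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance descriptor(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "),
         "; run drop_invariant() first")
  r <- stats::cor(v)
  (r + t(r)) / 2  # enforce exact symmetry against rounding
}

#' Collapse near-duplicate descriptors
#'
#' Within any group of descriptors whose pairwise absolute Pearson
#' correlation exceeds `r_dup`, keeps the one most correlated (in absolute
#' value) with the response and drops the rest. Ties keep the descriptor
#' that comes first in column order.
#'
#' @param m a [descriptor_matrix()], complete and non-invariant.
#' @param y numeric response aligned with the rows of `m`.
#' @param r_dup duplicate threshold on `|r|`, in (0, 1]; default 0.99.
#' @return list with `matrix`, `dropped` (names) and `pairs` (data frame
#'   of `kept`/`dropped` descriptor names).
#' @export
collapse_duplicates <- function(m, y, r_dup = 0.99) {
  stopifnot(inherits(m, "descriptor_matrix"),
            length(y) == nrow(m$values), r_dup > 0, r_dup <= 1)
  r <- correlation_matrix(m)
  p <- ncol(r)
  if (stats::sd(y) == 0) stop("response has zero variance")
  ry <- abs(as.vector(stats::cor(m$values, y)))
  adj <- abs(r) > r_dup
  diag(adj) <- FALSE
  keep <- rep(TRUE, p)
  pairs <- list()
  # greedy: visit descriptors by decreasing |cor with y| (ties: column order),
  # each survivor absorbs its still-unclaimed neighbours above the threshold
  ord <- order(-ry, seq_len(p))
  claimed <- rep(FALSE, p)
  for (i in ord) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    nb <- which(adj[i, ] & !claimed)
    for (j in nb) {
      claimed[j] <- TRUE
      keep[j] <- FALSE
      pairs[[length(pairs) + 1L]] <- c(kept = colnames(r)[i], dropped = colnames(r)[j])
    }
  }
  pairs <- if (length(pairs)) {
    as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  } else {
    data.frame(kept = character(), dropped = character(), stringsAsFactors = FALSE)
  }
  list(matrix = m[, keep], dropped = colnames(r)[!keep], pairs = pairs)
}

#' Heuristic descriptor preselection
#'
#' Applies the three preselection screens in order: drop descriptors with
#' missing values, drop invariant descriptors, then collapse near-duplicate
#' descriptors (pairwise `|r| > r_dup`), keeping in each duplicate group the
#' member most correlated with the response. Statistics are computed on the
#' matrix passed in, which should contain the training compounds only.
#'
#' @param m a [descriptor_matrix()] of training compounds.
#' @param y numeric response aligned with the rows of `m`.
#' @param r_dup duplicate-collapse threshold; default 0.99.
#' @param invariant_tol range tolerance for [drop_invariant()].
#' @return a `preselect_report`: list with `matrix` (the surviving
#'   `descriptor_matrix`), `survivors`, `dropped_incomplete`,
#'   `dropped_invariant`, `collapsed_duplicates` (data frame kept/dropped)
#'   and `dropped_duplicate` (names).
#' @export
preselect <- function(m, y, r_dup = 0.99, invariant_tol = 1e-12) {
  s1 <- drop_incomplete(m)
  s2 <- drop_invariant(s1$matrix, tol = invariant_tol)
  s3 <- collapse_duplicates(s2$matrix, y, r_dup = r_dup)
  structure(list(
    matrix = s3$matrix,
    survivors = colnames(s3$matrix$values),
    dropped_incomplete = s1$dropped,
    dropped_invariant = s2$dropped,
    collapsed_duplicates = s3$pairs,
    dropped_duplicate = s3$dropped
  ), class = "preselect_report")
}

#' @export
print.preselect_report <- function(x, ...) {
  cat(sprintf("<preselect_report> %d survivors | dropped: %d incomplete, %d invariant, %d duplicate\n",
              length(x$survivors), length(x$dropped_incomplete),
              length(x$dropped_invariant), length(x$dropped_duplicate)))
  invisible(x)
}

#' Serialize a preselection report to JSON
#'
#' @param x a `preselect_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_preselect_report <- function(x, path) {
  stopifnot(inherits(x, "preselect_report"))
  jsonlite::write_json(list(
    survivors = x$survivors,
    dropped_incomplete = x$dropped_incomplete,
    dropped_invariant = x$dropped_invariant,
    collapsed_duplicates = x$collapsed_duplicates
  ), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
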