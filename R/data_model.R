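#' @keywords internal
"_PACKAGE"

#' Descriptor classes
#'
#' The six descriptor classes used to categorize molecular descriptors:
#' constitutional, topological, geometrical, electrostatic, thermodynamic
#' and quantum-chemical.
#'
#' @export
DESCRIPTOR_CLASSES <- c("constitutional", "topological", "geometrical",
                        "electrostatic", "thermodynamic", "quantum_chemical")

#' The three BCRP-482 polymorphs
#' @export
POLYMORPHS <- c("482R", "482G", "482T")

#' Build a compound identifier from a free-text name
#'
#' Lower-cases the name and collapses runs of non-alphanumeric characters to
#' a single underscore, so that e.g. "Rhodamine 123" becomes "rhodamine_123".
#'
#' @param name character vector of compound names.
#' @return character vector of identifiers.
#' @export
compound_id <- function(name) {
  id <- tolower(trimws(name))
  id <- gsub("[^a-z0-9]+", "_", id)
  gsub("^_+|_+$", "", id)
}

#' Construct a descriptor matrix
#'
#' A descriptor matrix holds one row per compound and one column per named
#' molecular descriptor, each descriptor tagged with one of the six classes
#' in [DESCRIPTOR_CLASSES]. Missing values are stored as `NA`.
#'
#' @param values numeric matrix, compounds in rows, descriptors in columns.
#'   Must carry unique row names (compound ids) and column names (descriptor
#'   names).
#' @param dclass character vector of descriptor classes, one per column of
#'   `values`, each an element of [DESCRIPTOR_CLASSES].
#' @param role optional character vector of compound roles, `"training"` or
#'   `"test"`, one per row.
#' @param compound_name optional free-text names, one per row; defaults to
#'   the row names.
#' @param pharm_class optional pharmacological class per compound.
#' @return an object of class `descriptor_matrix`: a list with elements
#'   `values` (the numeric matrix), `compounds` (data frame with columns
#'   `id`, `name`, `role`, `pharm_class`) and `descriptors` (data frame with
#'   columns `name`, `dclass`).
#' @export
descriptor_matrix <- function(values, dclass,
                              role = NULL, compound_name = NULL,
                              pharm_class = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row names (compound ids) and column names (descriptor names)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate compound id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate descriptor name: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  dclass <- rep_len(as.character(dclass), ncol(values))
  bad <- setdiff(unique(dclass), DESCRIPTOR_CLASSES)
  if (length(bad))
    stop("unknown descriptor class: ", paste(bad, collapse = ", "))
  n <- nrow(values)
  if (is.null(role)) role <- rep(NA_character_, n)
  if (!all(is.na(role) | role %in% c("training", "test")))
    stop("roles must be 'training' or 'test'")
  compounds <- data.frame(
    id = rownames(values),
    name = if (is.null(compound_name)) rownames(values) else as.character(compound_name),
    role = rep_len(as.character(role), n),
    pharm_class = if (is.null(pharm_class)) NA_character_ else rep_len(as.character(pharm_class), n),
    stringsAsFactors = FALSE
  )
  descriptors <- data.frame(name = colnames(values), dclass = dclass,
                            stringsAsFactors = FALSE)
  structure(list(values = values, compounds = compounds, descriptors = descriptors),
            class = "descriptor_matrix")
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d compounds x %d descriptors\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(factor(x$descriptors$dclass, levels = DESCRIPTOR_CLASSES))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat("  missing cells:", nmiss, "\n")
  roles <- table(factor(x$compounds$role, levels = c("training", "test")))
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = " "), "\n")
  invisible(x)
}

#' Subset a descriptor matrix
#'
#' @param x a [descriptor_matrix()].
#' @param i row (compound) index: integer, logical, or compound ids.
#' @param j column (descriptor) index: integer, logical, or descriptor names.
#' @param ... ignored.
#' @return a `descriptor_matrix` restricted to the selected compounds and
#'   descriptors.
#' @export
`[.descriptor_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  v <- x$values[i, j, drop = FALSE]
  out <- x
  out$values <- v
  ridx <- match(rownames(v), x$compounds$id)
  cidx <- match(colnames(v), x$descriptors$name)
  out$compounds <- x$compounds[ridx, , drop = FALSE]
  out$descriptors <- x$descriptors[cidx, , drop = FALSE]
  rownames(out$compounds) <- NULL
  rownames(out$descriptors) <- NULL
  out
}

#' Read a descriptor table from delimited text
#'
#' The file must have a header row of descriptor names with the compound id
#' in the first column, one row per compound. Descriptor classes and
#' compound roles come from a JSON sidecar of the form
#' `{"classes": {"descriptor name": "class", ...}, "roles": {"id": "training", ...}}`.
#' Cells that cannot be parsed as numbers become missing values and are
#' counted in the attached parse report.
#'
#' @param path path to the delimited file.
#' @param sidecar path to the JSON sidecar; `NULL` if classes are supplied
#'   via `dclass`.
#' @param sep field delimiter; `NULL` picks "," for `.csv` and tab otherwise.
#' @param dclass optional character vector of classes (recycled) used when no
#'   sidecar is given.
#' @return a [descriptor_matrix()] with attribute `parse_report`, a list with
#'   `n_unparseable` and `unparseable_cells` (data frame of id/descriptor).
#' @export
read_descriptor_table <- function(path, sidecar = NULL, sep = NULL, dclass = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = character(0))
  ids <- trimws(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate compound id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dnames <- colnames(raw)[-1]
  if (anyDuplicated(dnames))
    stop("duplicate descriptor name in ", path, ": ",
         paste(unique(dnames[duplicated(dnames)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  dimnames(vals) <- list(ids, dnames)
  # cells that became missing without carrying the designated "NA" marker
  # (blank cells, stray text) are counted as unparseable
  txt <- trimws(cells)
  is_marker <- !is.na(txt) & toupper(txt) == "NA"
  unparse <- is.na(vals) & !is_marker
  report <- list(
    n_unparseable = sum(unparse),
    unparseable_cells = data.frame(
      id = rownames(vals)[row(vals)[unparse]],
      descriptor = colnames(vals)[col(vals)[unparse]],
      stringsAsFactors = FALSE)
  )
  roles <- NULL
  if (!is.null(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(side$classes)) stop("sidecar lacks a 'classes' map")
    missing_cls <- setdiff(dnames, names(side$classes))
    if (length(missing_cls))
      stop("sidecar gives no class for descriptor(s): ",
           paste(missing_cls, collapse = ", "))
    dclass <- unlist(side$classes)[dnames]
    if (!is.null(side$roles)) roles <- unlist(side$roles)[ids]
  } else if (is.null(dclass)) {
    stop("supply either a sidecar or `dclass`")
  }
  m <- descriptor_matrix(vals, dclass = dclass, role = roles)
  attr(m, "parse_report") <- report
  m
}

#' Write a descriptor table (and optional sidecar) to delimited text
#'
#' Values are written with 17 significant digits so a write-then-read round
#' trip reproduces finite doubles exactly; missing values are written as
#' `NA`.
#'
#' @param m a [descriptor_matrix()].
#' @param path output file path; delimiter chosen as in
#'   [read_descriptor_table()].
#' @param sidecar optional path for the JSON sidecar (classes and roles).
#' @param sep field delimiter override.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(m, path, sidecar = NULL, sep = NULL) {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  quote_field <- function(x) {
    need <- grepl(sep, x, fixed = TRUE) | grepl('"', x, fixed = TRUE)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
  }
  header <- paste(quote_field(c("compound_id", colnames(m$values))), collapse = sep)
  rows <- vapply(seq_len(nrow(m$values)), function(i)
    paste(c(quote_field(rownames(m$values)[i]), fmt(m$values[i, ])), collapse = sep),
    character(1))
  writeLines(c(header, rows), path)
  if (!is.null(sidecar)) {
    side <- list(
      classes = as.list(stats::setNames(m$descriptors$dclass, m$descriptors$name)),
      roles = as.list(stats::setNames(m$compounds$role, m$compounds$id))
    )
    jsonlite::write_json(side, sidecar, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Split a descriptor matrix into training and test sets
#'
#' @param m a [descriptor_matrix()].
#' @param assignment named character vector mapping compound id to
#'   `"training"` or `"test"`; defaults to the roles stored in `m`.
#' @return list with elements `training` and `test`, two disjoint
#'   `descriptor_matrix` objects preserving compound order and sharing the
#'   full descriptor list.
#' @export
split_train_test <- function(m, assignment = NULL) {
  stopifnot(inherits(m, "descriptor_matrix"))
  ids <- m$compounds$id
  if (is.null(assignment))
    assignment <- stats::setNames(m$compounds$role, ids)
  roles <- assignment[ids]
  if (any(is.na(roles)))
    stop("no train/test role for compound(s): ",
         paste(ids[is.na(roles)], collapse = ", "))
  if (!all(roles %in% c("training", "test")))
    stop("roles must be 'training' or 'test'")
  m$compounds$role <- unname(roles)
  list(training = m[roles == "training", ],
       test     = m[roles == "test", ])
}
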