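#' Construct a feature table
#'
#' A feature table is the central exchange object of the pipeline: a numeric
#' matrix with compounds as rows and continuous molecular features as columns,
#' plus a provenance tag per feature recording whether it came from a
#' 2-D descriptor calculation (`"descriptor"`), a reaction-mechanism enthalpy
#' (`"thermo"`), or an electronic-structure scalar (`"electronic"`).
#'
#' @param values Numeric matrix (compounds x features) with unique, non-empty
#'   rownames (compound ids) and colnames (feature names). A data.frame with an
#'   id column is also accepted via [as_feature_table()].
#' @param provenance Named character vector mapping feature name to one of
#'   `"descriptor"`, `"thermo"`, `"electronic"`. Unnamed features default to
#'   `"descriptor"`.
#' @return An object of class `feature_table` with elements `values` and
#'   `provenance`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"), c("TPSA", "MolLogP")))
#' ft <- feature_table(m)
#' dim(ft)
#' @export
feature_table <- function(values, provenance = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  ids <- rownames(values)
  feats <- colnames(values)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stop("`values` must have non-empty rownames (compound ids)", call. = FALSE)
  if (is.null(feats) || anyNA(feats) || any(!nzchar(feats)))
    stop("`values` must have non-empty colnames (feature names)", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(feats))
    stop("duplicate feature names: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "), call. = FALSE)
  prov <- rep("descriptor", length(feats))
  names(prov) <- feats
  if (!is.null(provenance)) {
    bad <- setdiff(names(provenance), feats)
    if (length(bad))
      stop("provenance given for unknown features: ",
           paste(bad, collapse = ", "), call. = FALSE)
    ok <- provenance %in% c("descriptor", "thermo", "electronic")
    if (!all(ok))
      stop("provenance values must be 'descriptor', 'thermo' or 'electronic'",
           call. = FALSE)
    prov[names(provenance)] <- provenance
  }
  structure(list(values = values, provenance = prov), class = "feature_table")
}

#' Coerce to a feature table
#'
#' @param x A data.frame whose first column (or the column named by `id_col`)
#'   holds compound ids, remaining columns numeric features; or a matrix.
#' @param id_col Name of the id column when `x` is a data.frame.
#' @param provenance Optional provenance map, see [feature_table()].
#' @return A `feature_table`.
#' @export
as_feature_table <- function(x, id_col = NULL, provenance = NULL) {
  if (inherits(x, "feature_table")) return(x)
  if (is.matrix(x)) return(feature_table(x, provenance))
  if (!is.data.frame(x)) stop("cannot coerce to feature_table", call. = FALSE)
  if (is.null(id_col)) id_col <- names(x)[1L]
  if (!id_col %in% names(x)) stop("id column '", id_col, "' not found", call. = FALSE)
  ids <- as.character(x[[id_col]])
  vals <- x[setdiff(names(x), id_col)]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric feature columns: ",
         paste(names(vals)[!num], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- ids
  feature_table(m, provenance)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_table> %d compounds x %d features\n", d[1], d[2]))
  tab <- table(x$provenance)
  cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  features:", paste(utils::head(colnames(x$values), 8), collapse = ", "),
      if (d[2] > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  data.frame(id = rownames(x$values), x$values,
             check.names = FALSE, row.names = NULL)
}

#' Row ids of a feature table
#' @param table A `feature_table`.
#' @return Character vector of compound ids.
#' @export
feature_ids <- function(table) rownames(table$values)

#' Feature names of a feature table
#' @param table A `feature_table`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(table) colnames(table$values)

#' Subset a feature table by feature name
#'
#' Keeps provenance in step and preserves column order as given.
#'
#' @param table A `feature_table`.
#' @param features Character vector of feature names to keep.
#' @return A `feature_table` restricted to `features`.
#' @export
select_features <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(features, feature_names(table))
  if (length(missing))
    stop("unknown features: ", paste(missing, collapse = ", "), call. = FALSE)
  feature_table(table$values[, features, drop = FALSE],
                table$provenance[features])
}

#' Bind two feature tables by compound id
#'
#' Left table rows are kept; right-table columns are aligned by id, with
#' missing ids filled with `NA` (the count of unmatched rows is reported via
#' a message).
#'
#' @param x,y `feature_table` objects with disjoint feature names.
#' @return A `feature_table` with the union of features.
#' @export
bind_features <- function(x, y) {
  stopifnot(inherits(x, "feature_table"), inherits(y, "feature_table"))
  overlap <- intersect(feature_names(x), feature_names(y))
  if (length(overlap))
    stop("duplicate feature names: ", paste(overlap, collapse = ", "), call. = FALSE)
  ids <- feature_ids(x)
  add <- matrix(NA_real_, length(ids), ncol(y$values),
                dimnames = list(ids, feature_names(y)))
  common <- intersect(ids, feature_ids(y))
  add[common, ] <- y$values[common, , drop = FALSE]
  n_miss <- length(ids) - length(common)
  if (n_miss > 0)
    message(n_miss, " row(s) without a match carry missing values")
  feature_table(cbind(x$values, add), c(x$provenance, y$provenance))
}
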