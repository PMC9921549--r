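#' Standardize a feature table
#'
#' Centers each feature to mean 0 and scales to population (denominator n)
#' standard deviation 1, computed over all rows of the table. A zero-variance
#' column is an error naming the column. Applying the operation twice equals
#' applying it once.
#'
#' @param table A `feature_table` (or numeric matrix).
#' @return The standardized object of the same type.
#' @export
standardize <- function(table) {
  values <- if (inherits(table, "feature_table")) table$values else table
  stopifnot(is.matrix(values), is.numeric(values))
  mu <- colMeans(values, na.rm = TRUE)
  sig <- apply(values, 2, function(x) sd_pop(x[!is.na(x)]))
  zero <- names(sig)[!is.finite(sig) | sig == 0]
  if (length(zero))
    stop("zero-variance feature(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  out <- sweep(sweep(values, 2, mu, "-"), 2, sig, "/")
  if (inherits(table, "feature_table"))
    feature_table(out, table$provenance)
  else out
}

#' Embedding configuration
#'
#' @param n_neighbors Neighborhood size for the graph construction,
#'   integer >= 2; default 15.
#' @param min_dist Minimum spacing of points in the embedding, >= 0;
#'   default 0.1.
#' @param seed Integer seed making the layout reproducible; default 42.
#' @param method Currently only `"umap"`.
#' @return A list of class `embedding_config` (logged verbatim into the
#'   result metadata).
#' @export
embedding_config <- function(n_neighbors = 15, min_dist = 0.1, seed = 42,
                             method = c("umap")) {
  method <- match.arg(method)
  stopifnot(n_neighbors >= 2, min_dist >= 0)
  structure(list(n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist, seed = as.integer(seed),
                 method = method),
            class = "embedding_config")
}

#' Joint 2-D embedding of several datasets
#'
#' Concatenates the rows of all tables (targets play no role: only features
#' enter), standardizes the features jointly over the combined matrix, and
#' runs UMAP down to two coordinates. Rows are canonically ordered by
#' (dataset, id) before the embedding and restored afterwards, so permuting
#' the input row order permutes the output rows but never changes any
#' compound's coordinates; with a fixed seed the result is deterministic.
#'
#' @param tables Named list of `feature_table` objects sharing the same
#'   feature set (order may differ; it is aligned to the first table).
#' @param config An [embedding_config()].
#' @return An object of class `embedding_result`: data.frame `coords` with
#'   columns `id`, `dataset`, `dim1`, `dim2`, plus the `config` snapshot.
#' @export
embed_2d <- function(tables, config = embedding_config()) {
  stopifnot(is.list(tables), length(tables) >= 1L,
            inherits(config, "embedding_config"))
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("`tables` must be a named list", call. = FALSE)
  ref <- feature_names(tables[[1L]])
  for (nm in names(tables)) {
    f <- feature_names(tables[[nm]])
    if (!setequal(f, ref)) {
      diffs <- c(setdiff(ref, f), setdiff(f, ref))
      stop("feature mismatch in '", nm, "': ",
           paste(unique(diffs), collapse = ", "), call. = FALSE)
    }
  }
  mats <- lapply(names(tables), function(nm)
    tables[[nm]]$values[, ref, drop = FALSE])
  x <- do.call(rbind, mats)
  dataset <- rep(names(tables), vapply(mats, nrow, integer(1)))
  id <- unlist(lapply(mats, rownames), use.names = FALSE)
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    message(sum(!keep), " row(s) with missing features dropped before embedding")
    x <- x[keep, , drop = FALSE]; dataset <- dataset[keep]; id <- id[keep]
  }
  n <- nrow(x)
  if (n <= config$n_neighbors)
    stop("need more rows than n_neighbors", call. = FALSE)
  x <- standardize(x)
  ord <- order(dataset, id, method = "radix")
  set.seed(config$seed)
  emb <- uwot::umap(x[ord, , drop = FALSE],
                    n_neighbors = config$n_neighbors,
                    min_dist = config$min_dist,
                    n_components = 2,
                    n_threads = 1, n_sgd_threads = 0,
                    verbose = FALSE)
  coords <- matrix(NA_real_, n, 2)
  coords[ord, ] <- emb
  if (any(!is.finite(coords)))
    stop("embedding produced non-finite coordinates", call. = FALSE)
  structure(list(coords = data.frame(id = id, dataset = dataset,
                                     dim1 = coords[, 1], dim2 = coords[, 2],
                                     stringsAsFactors = FALSE),
                 config = config),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d compounds from %d dataset(s) [%s, n_neighbors=%d, min_dist=%g, seed=%d]\n",
              nrow(x$coords), length(unique(x$coords$dataset)),
              x$config$method, x$config$n_neighbors, x$config$min_dist,
              x$config$seed))
  invisible(x)
}

#' Plot the chemical space
#'
#' Scatter plot of the 2-D embedding, colored by source dataset or by a
#' continuous feature overlay (e.g. TPSA or MolLogP, to read polarity or
#' bulkiness trends off axes that themselves carry no predefined meaning —
#' hence the neutral labels "dim 1" / "dim 2").
#'
#' @param result An [embed_2d()] result.
#' @param color_by `"dataset"` (default) or `"feature"`.
#' @param feature Feature name, required when `color_by = "feature"`.
#' @param feature_table A `feature_table` (or named list of them) supplying
#'   the overlay values, matched by compound id.
#' @param out Optional file path; when given the plot is saved there
#'   (format from the extension) and the path returned invisibly.
#' @param width,height Device size in inches for saving.
#' @return The ggplot object (invisibly when `out` is given).
#' @export
plot_chemspace <- function(result, color_by = c("dataset", "feature"),
                           feature = NULL, feature_table = NULL, out = NULL,
                           width = 7, height = 5) {
  color_by <- match.arg(color_by)
  stopifnot(inherits(result, "embedding_result"))
  df <- result$coords
  if (!nrow(df)) stop("empty embedding result", call. = FALSE)
  if (color_by == "dataset") {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          color = .data$dataset)) +
      ggplot2::geom_point(size = 1.2, alpha = 0.8) +
      ggplot2::labs(x = "dim 1", y = "dim 2", color = "dataset")
  } else {
    if (is.null(feature) || is.null(feature_table))
      stop("color_by = 'feature' needs `feature` and `feature_table`",
           call. = FALSE)
    tabs <- if (inherits(feature_table, "feature_table"))
      list(feature_table) else feature_table
    vals <- unlist(lapply(tabs, function(t) {
      if (!feature %in% feature_names(t))
        stop("unknown feature: ", feature, call. = FALSE)
      stats::setNames(t$values[, feature], feature_ids(t))
    }))
    df$overlay <- vals[df$id]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          color = .data$overlay)) +
      ggplot2::geom_point(size = 1.2, alpha = 0.8) +
      ggplot2::scale_color_viridis_c() +
      ggplot2::labs(x = "dim 1", y = "dim 2", color = feature)
  }
  p <- p + ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = width, height = height)
    return(invisible(p))
  }
  p
}
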