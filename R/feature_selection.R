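#' Configuration for the filter-cascade feature selection
#'
#' The cascade runs, per dataset: constant drop, pairwise correlation filter
#' (|r| threshold 0.95), local-descriptor exclusion by name prefix, and a
#' partial-correlation screen built from the inverse covariance matrix. The
#' per-dataset survivors are then intersected into the common feature set.
#'
#' @param corr_threshold Absolute Pearson correlation at or above which one
#'   member of a pair is dropped; in (0, 1], default 0.95.
#' @param partial_corr_threshold Same rule on absolute partial correlations;
#'   default 0.7 (the end state "no dependency between features" is declared
#'   at this cut-off).
#' @param constant_tol Variance at or below which a feature counts as
#'   constant; default 1e-12.
#' @param exclusion_prefixes Local-descriptor name prefixes, see
#'   [is_local_descriptor()].
#' @param tie_break `"max_mean_abs_corr"` (default): of a violating pair,
#'   drop the member with the larger mean |r| to all other remaining
#'   features, exact ties resolved toward the lexicographically later name;
#'   or `"lexicographic"`: always drop the later name.
#' @param stages Named logical vector switching individual stages off for
#'   ablation; names among `constant`, `correlation`, `local`, `partial`.
#' @param regularize Whether to ridge-regularize a (near-)singular covariance
#'   before inversion in the partial-correlation stage; see
#'   [partial_correlation_matrix()].
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(corr_threshold = 0.95,
                             partial_corr_threshold = 0.7,
                             constant_tol = 1e-12,
                             exclusion_prefixes = default_exclusion_prefixes(),
                             tie_break = c("max_mean_abs_corr", "lexicographic"),
                             stages = c(constant = TRUE, correlation = TRUE,
                                        local = TRUE, partial = TRUE),
                             regularize = TRUE) {
  tie_break <- match.arg(tie_break)
  stopifnot(corr_threshold > 0, corr_threshold <= 1,
            partial_corr_threshold > 0, partial_corr_threshold <= 1,
            constant_tol >= 0)
  st <- c(constant = TRUE, correlation = TRUE, local = TRUE, partial = TRUE)
  st[names(stages)] <- stages
  structure(list(corr_threshold = corr_threshold,
                 partial_corr_threshold = partial_corr_threshold,
                 constant_tol = constant_tol,
                 exclusion_prefixes = exclusion_prefixes,
                 tie_break = tie_break, stages = st,
                 regularize = regularize),
            class = "selection_config")
}

empty_drop_log <- function() {
  data.frame(feature = character(), reason = character(),
             partner = character(), r = numeric(), stringsAsFactors = FALSE)
}

set_stage_log <- function(table, stage, features_in, dropped) {
  attr(table, "stage_log") <- list(stage = stage,
                                   features_in = features_in,
                                   features_out = feature_names(table),
                                   dropped = dropped)
  table
}

#' Drop constant features
#'
#' Removes features whose sample variance is at or below `tol` (missing
#' values ignored). Dropping everything is an error: nothing would be left
#' to select from.
#'
#' @param table A `feature_table`.
#' @param tol Variance tolerance, default 1e-12.
#' @return The filtered `feature_table`; the drops are recorded in the
#'   `stage_log` attribute.
#' @export
drop_constant <- function(table, tol = 1e-12) {
  stopifnot(inherits(table, "feature_table"), tol >= 0)
  if (!ncol(table$values)) stop("empty feature table", call. = FALSE)
  v <- apply(table$values, 2, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0  # all-missing or single-value columns count as constant
  drop <- names(v)[v <= tol]
  if (length(drop) == ncol(table$values))
    stop("all features are constant; nothing to select", call. = FALSE)
  keep <- setdiff(feature_names(table), drop)
  out <- select_features(table, keep)
  dropped <- empty_drop_log()
  if (length(drop))
    dropped <- data.frame(feature = drop, reason = "constant",
                          partner = NA_character_, r = NA_real_,
                          stringsAsFactors = FALSE)
  set_stage_log(out, "drop_constant", feature_names(table), dropped)
}

# Greedy pair elimination shared by the marginal and partial screens.
# cor_fun(values) must return a symmetric correlation-like matrix for the
# current set of columns; it is re-evaluated after every drop (only the
# partial screen actually changes under deletion, but re-evaluating both
# keeps the rule identical).
greedy_pair_filter <- function(values, cor_fun, threshold, tie_break,
                               reason) {
  dropped <- empty_drop_log()
  repeat {
    if (ncol(values) < 2L) break
    cm <- cor_fun(values)
    a <- abs(cm)
    diag(a) <- 0
    a[is.na(a)] <- 0
    mx <- max(a)
    if (mx < threshold) break
    hit <- which(a == mx, arr.ind = TRUE)
    # deterministic pair choice under exact ties: first in column order
    hit <- hit[order(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2])), ,
               drop = FALSE]
    i <- min(hit[1, ]); j <- max(hit[1, ])
    ni <- colnames(values)[i]; nj <- colnames(values)[j]
    if (tie_break == "lexicographic") {
      loser <- if (ni > nj) ni else nj
    } else {
      mean_i <- mean(a[i, -i]); mean_j <- mean(a[j, -j])
      loser <- if (mean_i > mean_j) ni
        else if (mean_j > mean_i) nj
        else if (ni > nj) ni else nj
    }
    partner <- if (loser == ni) nj else ni
    dropped <- rbind(dropped,
                     data.frame(feature = loser, reason = reason,
                                partner = partner, r = cm[i, j],
                                stringsAsFactors = FALSE))
    values <- values[, setdiff(colnames(values), loser), drop = FALSE]
  }
  list(values = values, dropped = dropped)
}

#' Pairwise correlation filter
#'
#' Greedy multicollinearity removal: repeatedly locate the feature pair with
#' the largest |Pearson r| at or above `threshold` and drop one member (see
#' `tie_break` in [selection_config()]) until no pair violates. Guarantees
#' the post-condition that no surviving pair has |r| >= `threshold`.
#'
#' @param table A `feature_table` with at least two features.
#' @param threshold Absolute correlation threshold in (0, 1], default 0.95.
#' @param tie_break `"max_mean_abs_corr"` or `"lexicographic"`.
#' @return Filtered `feature_table` with a `stage_log` attribute recording
#'   each drop, its partner and the correlation.
#' @export
correlation_filter <- function(table, threshold = 0.95,
                               tie_break = c("max_mean_abs_corr",
                                             "lexicographic")) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(table, "feature_table"),
            threshold > 0, threshold <= 1)
  if (ncol(table$values) < 2L)
    stop("correlation filter needs at least two features", call. = FALSE)
  res <- greedy_pair_filter(table$values,
                            function(v) suppressWarnings(
                              stats::cor(v, use = "pairwise.complete.obs")),
                            threshold, tie_break, "correlation")
  out <- select_features(table, colnames(res$values))
  set_stage_log(out, "correlation_filter", feature_names(table), res$dropped)
}

#' Exclude local (binned surface-area) descriptors
#'
#' @param table A `feature_table`.
#' @param exclusion_prefixes See [is_local_descriptor()].
#' @return Filtered `feature_table` with a `stage_log` attribute.
#' @export
exclude_local_descriptors <- function(table,
                                      exclusion_prefixes =
                                        default_exclusion_prefixes()) {
  stopifnot(inherits(table, "feature_table"))
  local <- is_local_descriptor(feature_names(table), exclusion_prefixes)
  drop <- feature_names(table)[local]
  out <- select_features(table, feature_names(table)[!local])
  dropped <- empty_drop_log()
  if (length(drop))
    dropped <- data.frame(feature = drop, reason = "local_descriptor",
                          partner = NA_character_, r = NA_real_,
                          stringsAsFactors = FALSE)
  set_stage_log(out, "exclude_local", feature_names(table), dropped)
}

#' Partial-correlation matrix from the precision matrix
#'
#' The partial correlation of features i and j given all others is obtained
#' from the inverse Omega of the variance-covariance matrix:
#' `P[i,j] = -Omega[i,j] / sqrt(Omega[i,i] * Omega[j,j])`, diagonal 1. Each
#' entry equals the correlation between the residuals of i and j after
#' regressing both on all remaining features.
#'
#' When the covariance is singular or badly conditioned (condition number
#' above 1e12, e.g. fewer rows than features) and `regularize = TRUE`, a
#' ridge `lambda * I` with `lambda = 1e-6 * trace(S)/ncol(S)` is added before
#' inversion (reported via a message). With regularization disabled this is
#' an error naming the linearly dependent features.
#'
#' @param table A `feature_table` (or bare numeric matrix); rows with missing
#'   values are dropped for the covariance.
#' @param regularize Logical, default `TRUE`.
#' @return Symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_correlation_matrix <- function(table, regularize = TRUE) {
  values <- if (inherits(table, "feature_table")) table$values else table
  stopifnot(is.matrix(values), is.numeric(values))
  values <- values[stats::complete.cases(values), , drop = FALSE]
  if (nrow(values) < 3L)
    stop("need at least 3 complete rows", call. = FALSE)
  s <- stats::cov(values)
  kappa_s <- tryCatch(kappa(s, exact = TRUE), error = function(e) Inf)
  if (nrow(values) <= ncol(values) || !is.finite(kappa_s) ||
      kappa_s > 1e12) {
    if (!regularize) {
      ev <- eigen(s, symmetric = TRUE)
      null_dir <- abs(ev$vectors[, ncol(s)])
      offenders <- colnames(s)[null_dir > 0.1]
      stop("singular covariance (features involved: ",
           paste(offenders, collapse = ", "),
           "); enable regularization or drop features", call. = FALSE)
    }
    lambda <- 1e-6 * sum(diag(s)) / ncol(s)
    s <- s + diag(lambda, ncol(s))
    message("covariance regularized with lambda = ", format(lambda))
  }
  omega <- solve(s)
  d <- 1 / sqrt(diag(omega))
  p <- -omega * tcrossprod(d)
  diag(p) <- 1
  p <- (p + t(p)) / 2
  dimnames(p) <- dimnames(s)
  p
}

#' Partial-correlation screen
#'
#' Same greedy elimination rule as [correlation_filter()], applied to
#' absolute partial correlations; the matrix is recomputed after every drop
#' (removing a feature changes the conditioning set). Terminates when the
#' largest off-diagonal |partial r| is below `threshold`, i.e. when no
#' conditional dependency remains at the configured cut-off.
#'
#' @param table A `feature_table`.
#' @param threshold Absolute partial-correlation threshold in (0, 1],
#'   default 0.7.
#' @param tie_break `"max_mean_abs_corr"` or `"lexicographic"` (applied to
#'   mean |partial r|).
#' @param regularize See [partial_correlation_matrix()].
#' @return Filtered `feature_table` with a `stage_log` attribute.
#' @export
partial_corr_screen <- function(table, threshold = 0.7,
                                tie_break = c("max_mean_abs_corr",
                                              "lexicographic"),
                                regularize = TRUE) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(table, "feature_table"),
            threshold > 0, threshold <= 1)
  res <- greedy_pair_filter(table$values,
                            function(v) partial_correlation_matrix(
                              v, regularize = regularize),
                            threshold, tie_break, "partial_correlation")
  out <- select_features(table, colnames(res$values))
  set_stage_log(out, "partial_corr_screen", feature_names(table), res$dropped)
}

#' Run the filter cascade across datasets and intersect survivors
#'
#' Applies the stage sequence (constant drop, correlation filter,
#' local-descriptor exclusion, partial-correlation screen) independently to
#' each dataset's feature table, then intersects the per-dataset survivors
#' into the common feature set, ordered by the candidate-pool order of the
#' first table. The full per-stage drop log is retained per dataset.
#'
#' @param tables Named list of `feature_table` objects sharing a candidate
#'   feature namespace.
#' @param config A [selection_config()].
#' @return An object of class `selection_report`: list with `datasets` (per
#'   dataset, the ordered stage logs and survivors), `common_features`, and
#'   `config`.
#' @export
select_common_features <- function(tables, config = selection_config()) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("`tables` must be a named list", call. = FALSE)
  stopifnot(inherits(config, "selection_config"))
  per_dataset <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    stopifnot(inherits(tab, "feature_table"))
    stages <- list()
    if (config$stages[["constant"]]) {
      tab <- drop_constant(tab, config$constant_tol)
      stages$drop_constant <- attr(tab, "stage_log")
    }
    if (config$stages[["correlation"]]) {
      tab <- correlation_filter(tab, config$corr_threshold, config$tie_break)
      stages$correlation_filter <- attr(tab, "stage_log")
    }
    if (config$stages[["local"]]) {
      tab <- exclude_local_descriptors(tab, config$exclusion_prefixes)
      stages$exclude_local <- attr(tab, "stage_log")
    }
    if (config$stages[["partial"]]) {
      tab <- partial_corr_screen(tab, config$partial_corr_threshold,
                                 config$tie_break, config$regularize)
      stages$partial_corr_screen <- attr(tab, "stage_log")
    }
    list(name = nm, stages = stages, survivors = feature_names(tab))
  })
  names(per_dataset) <- names(tables)
  common <- Reduce(intersect, lapply(per_dataset, `[[`, "survivors"))
  pool_order <- feature_names(tables[[1L]])
  common <- pool_order[pool_order %in% common]
  if (!length(common))
    stop("no feature survives in every dataset; consider relaxing ",
         "corr_threshold or partial_corr_threshold", call. = FALSE)
  structure(list(datasets = per_dataset, common_features = common,
                 config = config),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  for (d in x$datasets) {
    path <- vapply(d$stages, function(s)
      sprintf("%s %d->%d", s$stage, length(s$features_in),
              length(s$features_out)), character(1))
    cat("  ", d$name, ": ", paste(path, collapse = "; "), "\n", sep = "")
  }
  cat(sprintf("  common features (%d): %s\n", length(x$common_features),
              paste(x$common_features, collapse = ", ")))
  invisible(x)
}

#' Write a selection report to JSON
#'
#' @param report A `selection_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  out <- list(
    common_features = report$common_features,
    datasets = lapply(report$datasets, function(d)
      list(survivors = d$survivors,
           stages = lapply(d$stages, function(s)
             list(stage = s$stage, n_in = length(s$features_in),
                  n_out = length(s$features_out), dropped = s$dropped)))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
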