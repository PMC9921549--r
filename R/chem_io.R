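#' Column-name schema for compound tables
#'
#' Maps the logical fields of a compound record to the column names used in a
#' particular CSV file. Enthalpy columns hold heats of formation in kcal/mol
#' for the four species that enter the mechanism enthalpies: the neutral
#' phenol ArOH, the hydrogen-withdrawn radical ArO·, the radical cation
#' ArOH·+, and the phenoxide anion ArO-.
#'
#' @param id,smiles,target,ic50 Column names for the compound identifier,
#'   SMILES string, continuous assay target, and IC50 (micromolar).
#' @param h_neutral,h_radical,h_radical_cation,h_anion Column names for the
#'   species formation enthalpies.
#' @return A named list of class `compound_schema`.
#' @export
compound_schema <- function(id = "id", smiles = "smiles", target = "target",
                            ic50 = "ic50", h_neutral = "h_neutral",
                            h_radical = "h_radical",
                            h_radical_cation = "h_radical_cation",
                            h_anion = "h_anion") {
  structure(list(id = id, smiles = smiles, target = target, ic50 = ic50,
                 h_neutral = h_neutral, h_radical = h_radical,
                 h_radical_cation = h_radical_cation, h_anion = h_anion),
            class = "compound_schema")
}

new_compound_dataset <- function(name, task, records) {
  structure(list(name = name, task = task, records = records),
            class = "compound_dataset")
}

#' Assemble a compound dataset from a records data.frame
#'
#' @param records data.frame with at least an `id` column; optional columns
#'   `smiles`, `target`, `ic50`, `h_neutral`, `h_radical`, `h_radical_cation`,
#'   `h_anion`. A logical `valid` column is added if absent.
#' @param name Dataset name (e.g. `"ORAC"`, `"DPPH"`, `"background"`).
#' @param task One of `"regression"`, `"classification"`, `"none"`.
#' @return A `compound_dataset`.
#' @export
compound_dataset <- function(records, name, task = c("regression",
                                                     "classification",
                                                     "none")) {
  task <- match.arg(task)
  if (!is.data.frame(records) || !"id" %in% names(records))
    stop("`records` must be a data.frame with an `id` column", call. = FALSE)
  records$id <- as.character(records$id)
  if (any(!nzchar(records$id)) || anyNA(records$id))
    stop("compound ids must be non-empty", call. = FALSE)
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup))
    stop("duplicate compound ids: ", paste(dup, collapse = ", "), call. = FALSE)
  for (col in c("smiles", "target", "ic50", "h_neutral", "h_radical",
                "h_radical_cation", "h_anion"))
    if (!col %in% names(records))
      records[[col]] <- if (col == "smiles") NA_character_ else NA_real_
  if (any(records$ic50 < 0, na.rm = TRUE))
    stop("negative ic50 values are not allowed", call. = FALSE)
  if (!"valid" %in% names(records)) records$valid <- TRUE
  new_compound_dataset(name, task, records)
}

#' @export
print.compound_dataset <- function(x, ...) {
  cat(sprintf("<compound_dataset> %s (%s): %d record(s), %d flagged invalid\n",
              x$name, x$task, nrow(x$records), sum(!x$records$valid)))
  invisible(x)
}

#' Read a compound table from CSV
#'
#' Reads one CSV compound table (comma separator, `.` decimal, UTF-8, empty
#' cell = missing) into a [compound_dataset()]. Rows whose SMILES cannot be
#' parsed by the descriptor provider are flagged invalid, not dropped, so the
#' dataset size stays auditable; the count of flagged rows is reported with a
#' message.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [compound_schema()] mapping logical fields to column names.
#' @param name Dataset name; defaults to the file name without extension.
#' @param task Task type, see [compound_dataset()].
#' @param validate_smiles If `TRUE` (default) SMILES strings are checked with
#'   the OpenBabel parser when available; unparseable rows get `valid = FALSE`.
#' @return A `compound_dataset`.
#' @export
read_compound_table <- function(path, schema = compound_schema(),
                                name = NULL,
                                task = c("regression", "classification",
                                         "none"),
                                validate_smiles = TRUE) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!schema$id %in% names(raw))
    stop("missing mandatory id column '", schema$id, "' in ", path,
         call. = FALSE)
  records <- data.frame(id = as.character(raw[[schema$id]]),
                        stringsAsFactors = FALSE)
  pull_num <- function(col) {
    if (col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  }
  records$smiles <- if (schema$smiles %in% names(raw))
    as.character(raw[[schema$smiles]]) else NA_character_
  records$target <- pull_num(schema$target)
  records$ic50 <- pull_num(schema$ic50)
  records$h_neutral <- pull_num(schema$h_neutral)
  records$h_radical <- pull_num(schema$h_radical)
  records$h_radical_cation <- pull_num(schema$h_radical_cation)
  records$h_anion <- pull_num(schema$h_anion)
  ds <- compound_dataset(records, name = name, task = task)
  if (validate_smiles && any(!is.na(ds$records$smiles))) {
    ok <- smiles_parseable(ds$records$smiles)
    ds$records$valid <- ok
    n_bad <- sum(!ok)
    if (n_bad > 0)
      message(n_bad, " record(s) with unparseable SMILES flagged invalid")
  }
  ds
}

#' Check which SMILES strings parse
#'
#' Uses the OpenBabel parser (via ChemmineR/ChemmineOB) when installed;
#' strings that are `NA` are treated as parseable placeholders so that
#' id-only synthetic tables pass through.
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector, `TRUE` where parseable or missing.
#' @export
smiles_parseable <- function(smiles) {
  out <- rep(TRUE, length(smiles))
  idx <- which(!is.na(smiles) & nzchar(smiles))
  if (!length(idx)) return(out)
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    warning("ChemmineOB not installed; SMILES not validated")
    return(out)
  }
  for (i in idx) {
    out[i] <- !inherits(
      try(suppressWarnings(ChemmineR::smiles2sdf(smiles[i])), silent = TRUE),
      "try-error")
  }
  out
}

#' Write a feature table to CSV
#'
#' Compound ids go in the first column (`id`), features in the remaining
#' columns. Values are written with 15 significant digits so a write/read
#' round trip is lossless well beyond 12 significant digits.
#'
#' @param table A [feature_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table)
  num <- vapply(df[-1], function(x) format(x, digits = 15, trim = TRUE),
                character(nrow(df)))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L,
                                    dimnames = list(NULL, names(df)[-1]))
  out <- cbind(id = df$id, as.data.frame(num, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_feature_table()]. Provenance is re-derived from feature
#' names: the five mechanism enthalpies are tagged `"thermo"`, the four
#' electronic scalars `"electronic"`, everything else `"descriptor"`.
#'
#' @param path CSV file written by [write_feature_table()] (or any CSV whose
#'   first column is the compound id and remaining columns are numeric).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  ft <- as_feature_table(df, id_col = names(df)[1L])
  feats <- feature_names(ft)
  prov <- rep("descriptor", length(feats))
  names(prov) <- feats
  prov[feats %in% thermo_feature_names()] <- "thermo"
  prov[feats %in% electronic_feature_names()] <- "electronic"
  ft$provenance <- prov
  ft
}

#' Binarize DPPH IC50 values
#'
#' Applies the DPPH classification rule: compounds whose IC50 falls strictly
#' below the threshold (default 300 micromolar) are labelled positive, the
#' remainder (including exactly 300) negative.
#'
#' @param x A `compound_dataset` whose records all carry `ic50`, or a numeric
#'   vector of IC50 values in micromolar.
#' @param threshold Positive IC50 cut-off in micromolar; default 300.
#' @return A factor with levels `c("positive", "negative")` and an attribute
#'   `counts` (named integer vector of class sizes).
#' @examples
#' binarize_dpph(c(100, 500, 299.9))
#' @export
binarize_dpph <- function(x, threshold = 300) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a single positive number", call. = FALSE)
  if (inherits(x, "compound_dataset")) {
    ic50 <- x$records$ic50
    if (anyNA(ic50))
      stop("records without ic50: ",
           paste(x$records$id[is.na(ic50)], collapse = ", "), call. = FALSE)
  } else {
    ic50 <- as.numeric(x)
    if (anyNA(ic50))
      stop("ic50 values must all be present (positions ",
           paste(which(is.na(ic50)), collapse = ", "), ")", call. = FALSE)
  }
  if (any(ic50 < 0))
    stop("ic50 values must be non-negative", call. = FALSE)
  lab <- factor(ifelse(ic50 < threshold, "positive", "negative"),
                levels = c("positive", "negative"))
  attr(lab, "counts") <- c(positive = sum(lab == "positive"),
                           negative = sum(lab == "negative"))
  lab
}
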