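#' Default planted informative feature names
#'
#' Eighteen continuous features spanning the four chemical groups a common
#' antioxidant feature set covers: the five mechanism enthalpies, polarity
#' and electronic-state scalars, bond/complexity indices, and steric
#' descriptors.
#'
#' @return Character vector of 18 names.
#' @export
default_informative_features <- function() c(
  "BDE", "IP", "PDE", "PA", "ETE",
  "TPSA", "MolLogP", "HOMO_LUMO_gap", "DipoleMoment", "NumHBD",
  "BalabanJ", "BertzCT", "Chi0v", "Kappa2", "NumRotatableBonds",
  "LabuteASA", "FractionCSP3", "RingCount")

#' Specification for the synthetic compound generator
#'
#' Describes one synthetic feature table: planted informative features,
#' redundant copies anchored to them, constant columns, and local-descriptor
#' decoys carrying excluded name prefixes. Features are realized as exact
#' linear combinations of an in-sample orthonormal Gaussian basis, so every
#' empirical correlation equals its designed value exactly (see the methods
#' vignette); this makes the filter cascade's behavior on the suite fully
#' deterministic and auditable.
#'
#' @param n_rows Number of compounds; must exceed the latent dimension
#'   (informative + copies + local decoys + 1).
#' @param informative Character vector of planted feature names.
#' @param n_copies Number of redundant copies, distributed round-robin over
#'   the informative features; default 30.
#' @param copy_corr Exact correlation between a copy and its anchor feature,
#'   in [0, 1); default 0.97.
#' @param copy_factor_loading Loading of every copy on a shared redundancy
#'   factor; gives copies a strictly larger mean |r| than their anchor so
#'   the greedy correlation filter always discards the copy. Default 0.2.
#' @param n_constant Number of constant columns; default 5.
#' @param n_local Number of local-descriptor decoys named with
#'   `exclusion_prefixes`; default 10.
#' @param local_factor_loading Loading of local decoys on the shared
#'   redundancy factor; default 0.5.
#' @param exclusion_prefixes Prefixes used to name the local decoys.
#' @param active Named coefficients of the features generating targets.
#' @param noise_sd Regression noise standard deviation; `NULL` (default)
#'   means 0.1 times the standard deviation of the noiseless signal.
#' @param class_separation Latent-score separation for classification
#'   targets; default 2.
#' @param positive_rate Calibrated expected positive fraction for
#'   classification; default 97/198, the DPPH class balance.
#' @param seed Mandatory integer seed.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_rows,
                           informative = default_informative_features(),
                           n_copies = 30, copy_corr = 0.97,
                           copy_factor_loading = 0.2,
                           n_constant = 5, n_local = 10,
                           local_factor_loading = 0.5,
                           exclusion_prefixes = c("PEOE_VSA", "SlogP_VSA"),
                           active = c(TPSA = 3, BDE = -2, MolLogP = 1.5),
                           noise_sd = NULL, class_separation = 2,
                           positive_rate = 97 / 198, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(copy_corr >= 0, copy_corr < 1,
            copy_corr^2 + copy_factor_loading^2 < 1,
            abs(local_factor_loading) < 1,
            n_copies >= 0, n_constant >= 0, n_local >= 0,
            positive_rate > 0, positive_rate < 1, class_separation >= 0)
  if (is.null(names(active)) || !all(names(active) %in% informative))
    stop("`active` must be named after informative features", call. = FALSE)
  latent_dim <- length(informative) + 1L + n_copies + n_local
  if (n_rows <= latent_dim)
    stop("n_rows must exceed the latent dimension (", latent_dim, ")",
         call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), informative = informative,
                 n_copies = as.integer(n_copies), copy_corr = copy_corr,
                 copy_factor_loading = copy_factor_loading,
                 n_constant = as.integer(n_constant),
                 n_local = as.integer(n_local),
                 local_factor_loading = local_factor_loading,
                 exclusion_prefixes = exclusion_prefixes,
                 active = active, noise_sd = noise_sd,
                 class_separation = class_separation,
                 positive_rate = positive_rate, seed = as.integer(seed)),
            class = "generator_spec")
}

# n_rows x k matrix of exactly mean-zero, unit-sample-variance, exactly
# mutually uncorrelated Gaussian-direction columns (QR against the
# intercept), the basis of the exact-correlation construction.
orthonormal_latents <- function(n_rows, k) {
  z <- matrix(stats::rnorm(n_rows * k), n_rows, k)
  q <- qr.Q(qr(cbind(1, z)))[, -1, drop = FALSE]
  q * sqrt(n_rows - 1)
}

#' Generate one synthetic feature table
#'
#' Realizes the structure described by a [generator_spec()]: informative
#' features are mutually exactly uncorrelated; each copy has exactly
#' `copy_corr` correlation with its anchor plus a shared redundancy-factor
#' loading; local decoys load on the same factor; constants are appended
#' last. Deterministic for a fixed seed.
#'
#' @param spec A [generator_spec()].
#' @return A `feature_table` with attribute `ground_truth`: list with
#'   `informative`, `copies` (data.frame name/anchor), `constants`,
#'   `local_decoys`.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n_inf <- length(spec$informative)
  lat <- orthonormal_latents(spec$n_rows,
                             n_inf + 1L + spec$n_copies + spec$n_local)
  parents <- lat[, seq_len(n_inf), drop = FALSE]
  g <- lat[, n_inf + 1L]
  copy_priv <- lat[, n_inf + 1L + seq_len(spec$n_copies), drop = FALSE]
  local_priv <- lat[, n_inf + 1L + spec$n_copies + seq_len(spec$n_local),
                    drop = FALSE]

  cols <- list()
  prov <- character()
  for (i in seq_len(n_inf)) {
    nm <- spec$informative[i]
    cols[[nm]] <- parents[, i]
    prov[nm] <- if (nm %in% thermo_feature_names()) "thermo"
      else if (nm %in% electronic_feature_names()) "electronic"
      else "descriptor"
  }
  gt_copies <- data.frame(name = character(), anchor = character(),
                          stringsAsFactors = FALSE)
  if (spec$n_copies > 0) {
    rho <- spec$copy_corr; gam <- spec$copy_factor_loading
    res <- sqrt(1 - rho^2 - gam^2)
    anchor_idx <- rep_len(seq_len(n_inf), spec$n_copies)
    dup_no <- stats::ave(anchor_idx, anchor_idx, FUN = seq_along)
    for (j in seq_len(spec$n_copies)) {
      anchor <- spec$informative[anchor_idx[j]]
      nm <- sprintf("%s_dup%d", anchor, dup_no[j])
      cols[[nm]] <- rho * parents[, anchor_idx[j]] + gam * g +
        res * copy_priv[, j]
      prov[nm] <- "descriptor"
      gt_copies <- rbind(gt_copies,
                         data.frame(name = nm, anchor = anchor,
                                    stringsAsFactors = FALSE))
    }
  }
  local_names <- character()
  if (spec$n_local > 0) {
    delta <- spec$local_factor_loading
    pre <- rep_len(spec$exclusion_prefixes, spec$n_local)
    idx_in_pre <- stats::ave(seq_along(pre), pre, FUN = seq_along)
    for (j in seq_len(spec$n_local)) {
      nm <- sprintf("%s%d", pre[j], idx_in_pre[j])
      cols[[nm]] <- delta * g + sqrt(1 - delta^2) * local_priv[, j]
      prov[nm] <- "descriptor"
      local_names <- c(local_names, nm)
    }
  }
  const_names <- character()
  if (spec$n_constant > 0) {
    for (j in seq_len(spec$n_constant)) {
      nm <- sprintf("const_%d", j)
      cols[[nm]] <- rep(j, spec$n_rows)
      prov[nm] <- "descriptor"
      const_names <- c(const_names, nm)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- sprintf("cmpd_%03d", seq_len(spec$n_rows))
  ft <- feature_table(m, prov)
  attr(ft, "ground_truth") <- list(informative = spec$informative,
                                   copies = gt_copies,
                                   constants = const_names,
                                   local_decoys = local_names)
  ft
}

#' Generate an exactly equicorrelated feature block
#'
#' All pairwise sample correlations equal `rho` exactly (block-factor
#' construction on the orthonormal latent basis). Useful for checking the
#' closed-form partial correlation of an equicorrelated set,
#' `rho / (1 + (m - 2) * rho)`.
#'
#' @param n_rows Number of rows; must exceed `size + 1`.
#' @param size Number of features in the block.
#' @param rho Common correlation, in [0, 1).
#' @param seed Integer seed.
#' @param names Optional feature names.
#' @return A `feature_table`.
#' @export
generate_equicorrelated <- function(n_rows, size, rho, seed, names = NULL) {
  stopifnot(size >= 2, rho >= 0, rho < 1, n_rows > size + 1)
  set.seed(seed)
  lat <- orthonormal_latents(n_rows, size + 1L)
  f <- lat[, 1L]
  m <- sapply(seq_len(size), function(i)
    sqrt(rho) * f + sqrt(1 - rho) * lat[, i + 1L])
  colnames(m) <- if (is.null(names)) sprintf("X%d", seq_len(size)) else names
  rownames(m) <- sprintf("cmpd_%03d", seq_len(n_rows))
  feature_table(m)
}

#' Regression targets from planted active features
#'
#' `y = sum(coef * feature) + Normal(0, noise_sd)`.
#'
#' @param table A `feature_table`.
#' @param active Named coefficients over features present in the table.
#' @param noise_sd Noise standard deviation; `NULL` means 0.1 times the
#'   population standard deviation of the noiseless signal.
#' @param seed Integer seed.
#' @return Numeric targets with attribute `ground_truth` (active
#'   coefficients and the noise sd used).
#' @export
generate_regression_targets <- function(table, active, noise_sd = NULL,
                                        seed) {
  stopifnot(inherits(table, "feature_table"))
  unknown <- setdiff(names(active), feature_names(table))
  if (length(unknown))
    stop("unknown active features: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  signal <- as.numeric(table$values[, names(active), drop = FALSE] %*% active)
  if (is.null(noise_sd)) noise_sd <- 0.1 * sd_pop(signal)
  y <- signal + stats::rnorm(nrow(table$values), 0, noise_sd)
  attr(y, "ground_truth") <- list(active = active, noise_sd = noise_sd)
  y
}

#' Classification labels and synthetic IC50 values
#'
#' A latent score combines the active features (standardized to unit
#' population variance) scaled by `separation`, plus standard normal noise.
#' The label is positive when the score exceeds a calibrated offset chosen
#' so the expected positive fraction equals `positive_rate`. Synthetic IC50
#' values are mapped monotonically (decreasing) from the score across the
#' `threshold` boundary, so binarizing the IC50s at `threshold` reproduces
#' the planted labels exactly.
#'
#' @param table A `feature_table`.
#' @param active Named coefficients of the active features.
#' @param separation Signal strength (latent-score standard deviations);
#'   0 gives a pure-noise 50/50-ish task. Default 2.
#' @param seed Integer seed.
#' @param positive_rate Calibrated expected positive fraction; default
#'   97/198.
#' @param threshold IC50 boundary in micromolar; default 300.
#' @return List with `labels` (factor positive/negative), `ic50`, `score`,
#'   and `ground_truth`.
#' @export
generate_classification_targets <- function(table, active, separation = 2,
                                            seed, positive_rate = 97 / 198,
                                            threshold = 300) {
  stopifnot(inherits(table, "feature_table"), separation >= 0,
            positive_rate > 0, positive_rate < 1)
  unknown <- setdiff(names(active), feature_names(table))
  if (length(unknown))
    stop("unknown active features: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  signal <- as.numeric(table$values[, names(active), drop = FALSE] %*% active)
  s <- sd_pop(signal)
  lin <- if (s > 0) signal / s else signal * 0
  score <- separation * lin + stats::rnorm(nrow(table$values))
  offset <- stats::qnorm(1 - positive_rate, mean = 0,
                         sd = sqrt(separation^2 + 1))
  labels <- factor(ifelse(score > offset, "positive", "negative"),
                   levels = c("positive", "negative"))
  ic50 <- threshold * exp(-(score - offset))
  list(labels = labels, ic50 = ic50, score = score,
       ground_truth = list(active = active, separation = separation,
                           offset = offset, positive_rate = positive_rate,
                           threshold = threshold))
}

default_suite_sizes <- function()
  c(ORAC = 70L, SOAC = 71L, MTT = 71L, ABTS = 90L, DPPH = 198L,
    phytochemicals = 344L, MEXT = 109L)

#' Generate the full synthetic study suite
#'
#' Builds the seven-dataset layout of the study design: four regression
#' assays (ORAC 70, SOAC 71, MTT 71, ABTS 90), one classification assay
#' (DPPH 198, calibrated to the 97/101 class balance), and two unlabeled
#' background sets (344 and 109 compounds) used only for the chemical-space
#' embedding — 953 compounds in total. Every dataset shares the candidate
#' feature namespace (18 planted informative features, 30 redundant copies,
#' 5 constants, 10 local-descriptor decoys) with independent draws. Compound
#' records additionally carry independent synthetic species enthalpies so
#' the mechanism-enthalpy module can be exercised end to end.
#'
#' @param seed Integer master seed; per-dataset seeds are derived from it.
#' @param sizes Named integer vector of dataset sizes (defaults above).
#' @param dir Optional directory; when given, writes
#'   `<name>_compounds.csv`, `<name>_features.csv` and `ground_truth.json`.
#' @param ... Overrides passed to [generator_spec()] (e.g. `active`,
#'   `class_separation`).
#' @return An object of class `synthetic_suite`: lists `datasets`
#'   (compound_dataset), `tables` (feature_table), `targets`, and
#'   `ground_truth`.
#' @export
generate_suite <- function(seed, sizes = default_suite_sizes(), dir = NULL,
                           ...) {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(sizes) * 3L)
  tasks <- c(ORAC = "regression", SOAC = "regression", MTT = "regression",
             ABTS = "regression", DPPH = "classification")
  datasets <- list(); tables <- list(); targets <- list()
  gt <- NULL
  for (i in seq_along(sizes)) {
    nm <- names(sizes)[i]
    spec <- generator_spec(n_rows = sizes[[i]], seed = sub_seeds[3 * i - 2],
                           ...)
    ft <- generate_feature_table(spec)
    if (is.null(gt)) gt <- attr(ft, "ground_truth")
    task <- if (nm %in% names(tasks)) tasks[[nm]] else "none"
    rec <- data.frame(id = feature_ids(ft), stringsAsFactors = FALSE)
    set.seed(sub_seeds[3 * i - 1])
    rec$h_neutral <- stats::rnorm(nrow(rec), -40, 15)
    rec$h_radical <- rec$h_neutral + stats::rnorm(nrow(rec), 35, 5)
    rec$h_radical_cation <- rec$h_neutral + stats::rnorm(nrow(rec), 170, 10)
    rec$h_anion <- rec$h_neutral + stats::rnorm(nrow(rec), -25, 8)
    tgt <- NULL
    if (task == "regression") {
      y <- generate_regression_targets(ft, spec$active,
                                       noise_sd = spec$noise_sd,
                                       seed = sub_seeds[3 * i])
      rec$target <- as.numeric(y)
      tgt <- y
    } else if (task == "classification") {
      cl <- generate_classification_targets(
        ft, spec$active, separation = spec$class_separation,
        seed = sub_seeds[3 * i], positive_rate = spec$positive_rate)
      rec$ic50 <- cl$ic50
      tgt <- cl
    }
    datasets[[nm]] <- compound_dataset(rec, name = nm, task = task)
    tables[[nm]] <- ft
    targets[[nm]] <- tgt
  }
  spec1 <- generator_spec(n_rows = sizes[[1]], seed = 1, ...)
  gt$active_coefficients <- as.list(spec1$active)
  gt$positive_rate <- spec1$positive_rate
  gt$sizes <- as.list(sizes)
  suite <- structure(list(datasets = datasets, tables = tables,
                          targets = targets, ground_truth = gt,
                          seed = seed),
                     class = "synthetic_suite")
  if (!is.null(dir)) write_suite(suite, dir)
  suite
}

#' @export
print.synthetic_suite <- function(x, ...) {
  sz <- vapply(x$tables, function(t) nrow(t$values), integer(1))
  cat("<synthetic_suite>",
      paste(sprintf("%s=%d", names(sz), sz), collapse = " "),
      sprintf("(total %d)\n", sum(sz)))
  invisible(x)
}

#' Write a synthetic suite to disk
#'
#' @param suite A [generate_suite()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_suite <- function(suite, dir) {
  stopifnot(inherits(suite, "synthetic_suite"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(suite$datasets)) {
    rec <- suite$datasets[[nm]]$records
    drop <- vapply(rec, function(col) all(is.na(col)), logical(1))
    utils::write.csv(rec[!drop], file.path(dir, paste0(nm, "_compounds.csv")),
                     row.names = FALSE)
    write_feature_table(suite$tables[[nm]],
                        file.path(dir, paste0(nm, "_features.csv")))
  }
  jsonlite::write_json(suite$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
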