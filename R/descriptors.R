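#' Descriptor provider contract
#'
#' A descriptor provider decouples the pipeline from any particular
#' cheminformatics toolkit: it is a name, a fixed vector of descriptor names,
#' and a `compute` function mapping one SMILES string to a named numeric
#' vector over exactly those names. The size of the candidate pool is
#' therefore provider metadata, not a pipeline invariant.
#'
#' @param name Provider name.
#' @param descriptor_names Character vector of descriptor names the provider
#'   emits; stable across calls.
#' @param compute `function(smiles)` returning a named numeric vector with
#'   one finite scalar per descriptor (it may throw for unparseable input;
#'   [compute_descriptors()] turns that into a flagged row).
#' @return A list of class `descriptor_provider`.
#' @export
descriptor_provider <- function(name, descriptor_names, compute) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(descriptor_names), length(descriptor_names) >= 1L,
            !anyDuplicated(descriptor_names), is.function(compute))
  structure(list(name = name, descriptor_names = descriptor_names,
                 compute = compute),
            class = "descriptor_provider")
}

ob_descriptor_names <- c(
  "MolWt", "MolLogP", "MolMR", "TPSA", "NumHBA", "NumHBD", "NumF",
  "HeavyAtomCount", "NumC", "NumO", "NumN", "RingCount", "FractionCSP3",
  "NumDoubleBonds")

ob_compute_one <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  mol <- sdf[[1]]
  props <- ChemmineR::propOB(sdf)
  elements <- sub("_.*$", "", rownames(ChemmineR::atomblock(mol)))
  bb <- ChemmineR::bondblock(mol)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) > 0, ncol = length(bb))
  n_atoms <- length(elements)
  n_bonds <- nrow(bb)
  orders <- if (n_bonds > 0) as.numeric(bb[, 3]) else numeric()
  # sp3 carbon: every incident bond is a single bond (kekulized block)
  is_c <- elements == "C"
  has_multi <- rep(FALSE, n_atoms)
  if (n_bonds > 0) {
    multi <- orders > 1
    has_multi[c(bb[multi, 1], bb[multi, 2])] <- TRUE
  }
  frac_csp3 <- if (sum(is_c) == 0) 0 else sum(is_c & !has_multi) / sum(is_c)
  c(MolWt = as.numeric(props$MW),
    MolLogP = as.numeric(props$logP),
    MolMR = as.numeric(props$MR),
    TPSA = as.numeric(props$TPSA),
    NumHBA = as.numeric(props$HBA1),
    NumHBD = as.numeric(props$HBD),
    NumF = as.numeric(props$nF),
    HeavyAtomCount = n_atoms,
    NumC = sum(is_c),
    NumO = sum(elements == "O"),
    NumN = sum(elements == "N"),
    RingCount = n_bonds - n_atoms + 1,      # cyclomatic number (connected)
    FractionCSP3 = frac_csp3,
    NumDoubleBonds = sum(orders == 2))
}

#' OpenBabel-backed descriptor provider
#'
#' Default provider computing a pool of continuous 2-D descriptors with
#' OpenBabel (through ChemmineR/ChemmineOB): molecular weight, Wildman-Crippen
#' logP, molar refractivity, topological polar surface area, hydrogen-bond
#' acceptor/donor counts, halogen and heteroatom counts, ring count
#' (cyclomatic number), fraction of sp3 carbons, and double-bond count.
#'
#' @return A [descriptor_provider()].
#' @export
openbabel_provider <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("the OpenBabel provider needs the ChemmineOB package", call. = FALSE)
  descriptor_provider("openbabel", ob_descriptor_names, ob_compute_one)
}

#' Compute the descriptor candidate pool for a dataset
#'
#' One row per valid record. A molecule the provider fails on is kept as an
#' all-missing row (the pipeline continues); non-finite descriptor values are
#' replaced by missing. Both situations are counted in messages. If every
#' molecule fails, this is an error.
#'
#' @param dataset A [compound_dataset()] with SMILES.
#' @param provider A [descriptor_provider()]; default [openbabel_provider()].
#' @return A `feature_table` with provenance `"descriptor"`.
#' @export
compute_descriptors <- function(dataset, provider = openbabel_provider()) {
  stopifnot(inherits(dataset, "compound_dataset"),
            inherits(provider, "descriptor_provider"))
  rec <- dataset$records[dataset$records$valid & !is.na(dataset$records$smiles), ,
                         drop = FALSE]
  if (!nrow(rec))
    stop("dataset has no valid records with SMILES", call. = FALSE)
  nm <- provider$descriptor_names
  m <- matrix(NA_real_, nrow(rec), length(nm),
              dimnames = list(rec$id, nm))
  failed <- 0L
  for (i in seq_len(nrow(rec))) {
    v <- try(provider$compute(rec$smiles[i]), silent = TRUE)
    if (inherits(v, "try-error")) { failed <- failed + 1L; next }
    m[i, ] <- as.numeric(v[nm])
  }
  if (failed == nrow(rec))
    stop("descriptor computation failed for every molecule", call. = FALSE)
  if (failed > 0)
    message(failed, " molecule(s) failed descriptor computation; rows flagged missing")
  n_nonfinite <- sum(!is.finite(m) & !is.na(m))
  if (n_nonfinite > 0) {
    m[!is.finite(m)] <- NA_real_
    message(n_nonfinite, " non-finite descriptor value(s) replaced by missing")
  }
  prov <- rep("descriptor", length(nm)); names(prov) <- nm
  feature_table(m, prov)
}

#' Electronic-structure scalars for one molecule
#'
#' Frontier-orbital energies and dipole moment from the optimized neutral
#' structure. The HOMO-LUMO gap is `e_lumo - e_homo`; if supplied it must
#' agree with that identity within 1e-6, and a negative gap (open-shell-like)
#' triggers a warning.
#'
#' @param e_homo,e_lumo Orbital energies, eV.
#' @param dipole_moment Dipole moment, debye.
#' @param homo_lumo_gap Optional gap, eV; computed when `NULL`.
#' @return A list of class `electronic_scalars`.
#' @export
electronic_scalars <- function(e_homo, e_lumo, dipole_moment,
                               homo_lumo_gap = NULL) {
  gap <- e_lumo - e_homo
  if (!is.null(homo_lumo_gap) && abs(homo_lumo_gap - gap) > 1e-6)
    stop("homo_lumo_gap must equal e_lumo - e_homo within 1e-6", call. = FALSE)
  if (gap < 0) warning("negative HOMO-LUMO gap")
  structure(list(e_homo = e_homo, e_lumo = e_lumo, homo_lumo_gap = gap,
                 dipole_moment = dipole_moment),
            class = "electronic_scalars")
}

#' Attach electronic-structure scalars to a feature table
#'
#' Adds four columns (`E_HOMO`, `E_LUMO`, `HOMO_LUMO_gap`, `DipoleMoment`)
#' with provenance `"electronic"`. Rows without scalars carry missing values;
#' the count is reported with a message. The gap column is always recomputed
#' as `E_LUMO - E_HOMO`.
#'
#' @param table A `feature_table`.
#' @param scalars A data.frame with columns `id`, `e_homo`, `e_lumo`,
#'   `dipole_moment` (rows for a subset of the table's compounds), or a named
#'   list of [electronic_scalars()] keyed by id.
#' @return The augmented `feature_table`.
#' @export
attach_electronic_scalars <- function(table, scalars) {
  stopifnot(inherits(table, "feature_table"))
  if (is.list(scalars) && !is.data.frame(scalars)) {
    scalars <- do.call(rbind, lapply(names(scalars), function(id) {
      s <- scalars[[id]]
      data.frame(id = id, e_homo = s$e_homo, e_lumo = s$e_lumo,
                 dipole_moment = s$dipole_moment)
    }))
    if (is.null(scalars))
      scalars <- data.frame(id = character(), e_homo = numeric(),
                            e_lumo = numeric(), dipole_moment = numeric())
  }
  need <- c("id", "e_homo", "e_lumo", "dipole_moment")
  if (!all(need %in% names(scalars)))
    stop("scalars need columns: ", paste(need, collapse = ", "), call. = FALSE)
  ids <- feature_ids(table)
  unknown <- setdiff(as.character(scalars$id), ids)
  if (length(unknown))
    stop("scalar ids not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cols <- electronic_feature_names()
  add <- matrix(NA_real_, length(ids), 4L, dimnames = list(ids, cols))
  if (nrow(scalars)) {
    add[as.character(scalars$id), "E_HOMO"] <- scalars$e_homo
    add[as.character(scalars$id), "E_LUMO"] <- scalars$e_lumo
    add[as.character(scalars$id), "DipoleMoment"] <- scalars$dipole_moment
    add[, "HOMO_LUMO_gap"] <- add[, "E_LUMO"] - add[, "E_HOMO"]
  }
  n_missing <- length(ids) - length(unique(scalars$id))
  if (n_missing > 0)
    message(n_missing, " row(s) without electronic scalars carry missing values")
  prov <- rep("electronic", 4L); names(prov) <- cols
  feature_table(cbind(table$values, add), c(table$provenance, prov))
}

#' Default local-descriptor name prefixes
#'
#' The binned surface-area descriptor families describe the surface of
#' individual functional groups rather than the whole molecule and behave
#' discretely; they are excluded from the candidate pool. The two families
#' every practitioner names first are `PEOE_VSA` and `SlogP_VSA`; the default
#' extends to all binned-VSA families.
#'
#' @return Character vector of name prefixes.
#' @export
default_exclusion_prefixes <- function()
  c("PEOE_VSA", "SlogP_VSA", "SMR_VSA", "EState_VSA", "VSA_EState")

#' Is a feature a local (binned surface-area) descriptor?
#'
#' @param name Character vector of feature names.
#' @param exclusion_prefixes Prefixes marking local-descriptor families;
#'   default [default_exclusion_prefixes()].
#' @return Logical vector: `TRUE` where the name starts with any prefix.
#' @examples
#' is_local_descriptor(c("PEOE_VSA3", "TPSA", "SlogP_VSA10"))
#' @export
is_local_descriptor <- function(name,
                                exclusion_prefixes = default_exclusion_prefixes()) {
  if (any(!nzchar(name))) stop("feature names must be non-empty", call. = FALSE)
  out <- rep(FALSE, length(name))
  for (p in exclusion_prefixes)
    out <- out | startsWith(name, p)
  out
}
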