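#' Names of the mechanism-enthalpy features
#' @return `c("BDE", "IP", "PDE", "PA", "ETE")`.
#' @export
thermo_feature_names <- function() c("BDE", "IP", "PDE", "PA", "ETE")

#' Names of the electronic-structure features
#' @return `c("E_HOMO", "E_LUMO", "HOMO_LUMO_gap", "DipoleMoment")`.
#' @export
electronic_feature_names <- function()
  c("E_HOMO", "E_LUMO", "HOMO_LUMO_gap", "DipoleMoment")

#' Reference-species enthalpies
#'
#' Formation enthalpies of the hydrogen atom, the proton and the electron,
#' needed to close the thermodynamic cycles of the three radical-scavenging
#' mechanisms. Defaults are the common gas-phase conventions in kcal/mol:
#' H(H·) = 52.103, H(H+) = 365.7, H(e-) = 0. All three are configurable;
#' the cycle identities hold for any choice.
#'
#' @param h_h_atom Enthalpy of the hydrogen atom, kcal/mol.
#' @param h_proton Enthalpy of the proton, kcal/mol.
#' @param h_electron Enthalpy of the electron, kcal/mol.
#' @return A list of class `reference_constants`.
#' @export
reference_constants <- function(h_h_atom = 52.103, h_proton = 365.7,
                                h_electron = 0) {
  vals <- c(h_h_atom = h_h_atom, h_proton = h_proton, h_electron = h_electron)
  if (!all(is.finite(vals)))
    stop("reference constants must be finite", call. = FALSE)
  structure(as.list(vals), class = "reference_constants")
}

#' Formation enthalpies of the four molecular species
#'
#' @param h_neutral H(ArOH), kcal/mol.
#' @param h_radical H(ArO·), kcal/mol.
#' @param h_radical_cation H(ArOH·+), kcal/mol.
#' @param h_anion H(ArO-), kcal/mol.
#' @return A list of class `species_enthalpies`.
#' @export
species_enthalpies <- function(h_neutral, h_radical, h_radical_cation,
                               h_anion) {
  vals <- c(h_neutral = h_neutral, h_radical = h_radical,
            h_radical_cation = h_radical_cation, h_anion = h_anion)
  if (!all(is.finite(vals)))
    stop("species enthalpies must be finite", call. = FALSE)
  structure(as.list(vals), class = "species_enthalpies")
}

KCAL_PER_KJ <- 1 / 4.184

#' Mechanism enthalpies for one molecule
#'
#' Computes the five thermodynamic properties that characterise the three
#' radical-scavenging mechanisms of a phenolic antioxidant ArOH:
#'
#' * `BDE = H(ArO·) + H(H·) - H(ArOH)` — O-H bond dissociation enthalpy,
#'   governing one-step hydrogen-atom transfer (HAT);
#' * `IP = H(ArOH·+) + H(e-) - H(ArOH)` and
#'   `PDE = H(ArO·) + H(H+) - H(ArOH·+)` — ionization potential and proton
#'   dissociation enthalpy of the electron-transfer-first pathway (SET-PT);
#' * `PA = H(ArO-) + H(H+) - H(ArOH)` and
#'   `ETE = H(ArO·) + H(e-) - H(ArO-)` — proton affinity and
#'   electron-transfer enthalpy of the proton-loss-first pathway (SPLET).
#'
#' Both two-step routes end at the same radical, so `IP + PDE = PA + ETE`
#' exactly, and `PA + ETE - BDE = H(H+) + H(e-) - H(H·)` for any input; the
#' constructor asserts both identities.
#'
#' @param species A [species_enthalpies()] (or list with the same fields),
#'   kcal/mol.
#' @param constants A [reference_constants()].
#' @param unit Output unit, `"kcal/mol"` (default) or `"kJ/mol"`.
#' @return A list of class `thermo_profile` with fields `bde`, `ip`, `pde`,
#'   `pa`, `ete`, `unit` and `constants_used`.
#' @examples
#' thermo_profile(species_enthalpies(-50, -10, 130, -80))
#' @export
thermo_profile <- function(species, constants = reference_constants(),
                           unit = c("kcal/mol", "kJ/mol")) {
  unit <- match.arg(unit)
  if (!inherits(species, "species_enthalpies"))
    species <- do.call(species_enthalpies,
                       species[c("h_neutral", "h_radical",
                                 "h_radical_cation", "h_anion")])
  if (!inherits(constants, "reference_constants"))
    constants <- do.call(reference_constants, as.list(constants))
  hn <- species$h_neutral; hr <- species$h_radical
  hc <- species$h_radical_cation; ha <- species$h_anion
  hh <- constants$h_h_atom; hp <- constants$h_proton; he <- constants$h_electron
  prof <- c(bde = hr + hh - hn,
            ip  = hc + he - hn,
            pde = hr + hp - hc,
            pa  = ha + hp - hn,
            ete = hr + he - ha)
  scale_tol <- max(1, max(abs(c(hn, hr, hc, ha, hh, hp, he))))
  stopifnot(abs((prof["ip"] + prof["pde"]) - (prof["pa"] + prof["ete"])) <=
              1e-9 * scale_tol)
  stopifnot(abs((prof["pa"] + prof["ete"] - prof["bde"]) -
                  (hp + he - hh)) <= 1e-9 * scale_tol)
  if (unit == "kJ/mol") prof <- prof / KCAL_PER_KJ
  structure(c(as.list(prof),
              list(unit = unit, constants_used = constants)),
            class = "thermo_profile")
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat(sprintf("<thermo_profile> [%s] BDE=%.3f IP=%.3f PDE=%.3f PA=%.3f ETE=%.3f\n",
              x$unit, x$bde, x$ip, x$pde, x$pa, x$ete))
  invisible(x)
}

#' Trolox-equivalent antioxidant capacity
#'
#' `TEAC = IC50(Trolox) / IC50(sample)`: a sample twice as potent as Trolox
#' (half the IC50) has TEAC 2.
#'
#' @param ic50_trolox IC50 of Trolox, micromolar; strictly positive.
#' @param ic50_sample IC50 of the sample, micromolar; strictly positive.
#' @return Dimensionless capacity ratio (vectorised).
#' @examples
#' teac(10, 5)
#' @export
teac <- function(ic50_trolox, ic50_sample) {
  if (any(!is.finite(ic50_trolox)) || any(!is.finite(ic50_sample)) ||
      any(ic50_trolox <= 0) || any(ic50_sample <= 0))
    stop("IC50 values must be finite and strictly positive", call. = FALSE)
  ic50_trolox / ic50_sample
}

#' Mechanism-enthalpy feature table for a dataset
#'
#' Applies [thermo_profile()] per compound to the species enthalpies carried
#' in the dataset records, producing the five-column `BDE`/`IP`/`PDE`/`PA`/
#' `ETE` block with provenance `"thermo"`, joinable to a descriptor table by
#' id with [bind_features()]. A record missing one species still yields the
#' enthalpies that remain computable (e.g. without `h_anion`, `BDE`, `IP` and
#' `PDE` are present but `PA` and `ETE` are missing); fully or partially
#' missing rows are counted in a message.
#'
#' @param dataset A [compound_dataset()].
#' @param constants A [reference_constants()].
#' @return A `feature_table` with one row per valid record.
#' @export
thermo_features <- function(dataset, constants = reference_constants()) {
  stopifnot(inherits(dataset, "compound_dataset"))
  rec <- dataset$records[dataset$records$valid, , drop = FALSE]
  if (!nrow(rec)) stop("dataset has no valid records", call. = FALSE)
  hn <- rec$h_neutral; hr <- rec$h_radical
  hc <- rec$h_radical_cation; ha <- rec$h_anion
  hh <- constants$h_h_atom; hp <- constants$h_proton; he <- constants$h_electron
  m <- cbind(BDE = hr + hh - hn,
             IP  = hc + he - hn,
             PDE = hr + hp - hc,
             PA  = ha + hp - hn,
             ETE = hr + he - ha)
  rownames(m) <- rec$id
  n_incomplete <- sum(apply(m, 1, anyNA))
  if (n_incomplete > 0)
    message(n_incomplete,
            " record(s) missing species enthalpies carry missing values")
  prov <- rep("thermo", 5L)
  names(prov) <- colnames(m)
  feature_table(m, prov)
}
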