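---
title: "Mechanism-based antioxidant SAR: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-based antioxidant SAR: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(antioxsar)
```

## The scientific problem

Plant phenolics and related antioxidants scavenge reactive oxygen species
(ROS) through three canonical mechanisms, each governed by a different
thermodynamic quantity:

* **HAT** (hydrogen-atom transfer): one-step O–H homolysis,
  ArOH → ArO· + H·, governed by the bond dissociation enthalpy (BDE);
* **SET-PT** (single-electron transfer, then proton transfer):
  ArOH → ArOH·⁺ + e⁻ → ArO· + H⁺, governed by the ionization potential (IP)
  and the proton dissociation enthalpy (PDE);
* **SPLET** (sequential proton loss, electron transfer):
  ArOH → ArO⁻ + H⁺ → ArO· + e⁻, governed by the proton affinity (PA) and the
  electron-transfer enthalpy (ETE).

Because antioxidant capacity is measured by assays that probe different
radicals (peroxyl radicals in ORAC, singlet oxygen in SOAC, the tetrazolium
dye in MTT, the ABTS radical cation, the DPPH radical), a single-assay QSAR
gives a fragmented picture. This package implements a multi-assay workflow:
build one continuous-descriptor candidate pool per compound, augment it with
the five mechanism enthalpies, reduce it to a *common* feature set that
survives a statistical filter cascade in every assay dataset, evaluate that
set with per-assay gradient-boosted models, and embed all compounds jointly
into a 2-D chemical space.

## Mechanism enthalpies

Given formation enthalpies of the four species (neutral ArOH, radical ArO·,
radical cation ArOH·⁺, anion ArO⁻) and reference values for H·, H⁺ and e⁻:

```
BDE = H(ArO·)   + H(H·) − H(ArOH)
IP  = H(ArOH·⁺) + H(e⁻) − H(ArOH)
PDE = H(ArO·)   + H(H⁺) − H(ArOH·⁺)
PA  = H(ArO⁻)   + H(H⁺) − H(ArOH)
ETE = H(ArO·)   + H(e⁻) − H(ArO⁻)
```

Both two-step routes end at the same phenoxyl radical, so `IP + PDE = PA +
ETE` holds as an algebraic identity, and `PA + ETE − BDE = H(H⁺) + H(e⁻) −
H(H·)` for any input. `thermo_profile()` asserts both closures at 1e-9
(relative to the input scale); they are what make the five columns a
consistent thermodynamic cycle rather than five unrelated numbers.

Units are kcal/mol throughout — the native heat-of-formation unit of the
semi-empirical toolchains that typically produce these numbers — with a
kJ/mol output option. The reference constants default to the common
gas-phase conventions H(H·) = 52.103, H(H⁺) = 365.7, H(e⁻) = 0 kcal/mol and
are fully configurable; every identity above holds for any choice, so the
constants affect PDE/PA/ETE offsets but never the cycle closure. Quantum
chemistry itself is out of scope by design: enthalpies enter through CSV
columns or any provider the user wires in, which keeps the package
desk-scale and testable.

```{r}
thermo_profile(species_enthalpies(h_neutral = -50, h_radical = -10,
                                  h_radical_cation = 130, h_anion = -80))
```

One modelling caveat worth stating explicitly: given fixed reference
constants, PDE and ETE are exact linear combinations of BDE, IP and PA
(`PDE = BDE − IP + c`, `ETE = BDE − PA + c` with `c = H(H⁺) + H(e⁻) −
H(H·)`). A five-column block computed from a single consistent species set
therefore has rank 3. In real data the degeneracy is broken by per-species
conformer selection, convergence noise and solvation treatment; the
synthetic suite (below) instead plants the five thermo-named features as
independent draws, because its purpose is to exercise the statistical
pipeline, not to simulate a quantum-chemistry code.

## Assay targets

`teac()` converts IC50 values to Trolox-equivalent antioxidant capacity,
`IC50(Trolox) / IC50(sample)` — dimensionless and scale-invariant. The DPPH
assay is handled as a classification task: `binarize_dpph()` labels a
compound positive when its IC50 is *strictly below* 300 μM. The boundary is
read strictly ("below" means `<`), so exactly 300 μM is negative. IC50
values are taken as reported, in μM, without unit re-derivation.

## The descriptor candidate pool

Descriptors enter through a provider contract (`descriptor_provider()`):
a name, a stable list of descriptor names, and a function mapping one SMILES
to one finite scalar per descriptor. The built-in provider
(`openbabel_provider()`) uses OpenBabel through ChemmineR/ChemmineOB for
logP, TPSA, molar refractivity, molecular weight and hydrogen-bond counts,
plus connection-table scalars (ring count as the cyclomatic number, the
fraction of sp³ carbons, heteroatom and double-bond counts). The contract
deliberately makes the *size* of the candidate pool provider metadata rather
than a pipeline invariant: descriptor sets drift across toolkit releases,
and any provider that emits one continuous value per molecule plugs in
unchanged. Electronic-structure scalars (HOMO/LUMO energies, their gap,
dipole moment) attach as a separate four-column block; the gap column is
always recomputed as `E_LUMO − E_HOMO` so the identity cannot drift.

Molecules the provider cannot parse are *flagged*, not dropped: dataset
sizes are part of a study's provenance and should stay auditable. Rows with
missing values among selected features are excluded only at model time.

## The filter cascade

`select_common_features()` runs four stages per dataset, in a fixed order,
then intersects survivors across datasets:

1. **Constant drop** — variance ≤ 1e-12.
2. **Correlation filter** — greedy multicollinearity removal: repeatedly
   find the pair with the largest |Pearson r| ≥ 0.95 and drop one member.
3. **Local-descriptor exclusion** — name-prefix removal of binned
   surface-area families (`PEOE_VSA`, `SlogP_VSA`, `SMR_VSA`, `EState_VSA`,
   `VSA_EState` by default). These descriptors measure functional-group
   surface patches and behave discretely, while the pipeline wants one
   continuous value per molecule. The default list extends the two families
   usually named first to all binned-VSA families because the convention is
   open-ended; it is configurable.
4. **Partial-correlation screen** — the same greedy rule on absolute
   partial correlations, recomputed after every drop (removing a feature
   changes the conditioning set of all others).

Partial correlations come from the precision matrix: with Ω the inverse of
the covariance matrix, `P[i,j] = −Ω[i,j]/√(Ω[i,i]·Ω[j,j])`. Each entry
equals the correlation of the residuals of features i and j after
regressing both on all remaining features — the property the test suite
checks against an explicit residual-regression oracle at 1e-8.

Design choices that were genuinely open:

* **Partial-correlation threshold 0.7.** The marginal threshold (0.95) is a
  standard published choice, but no comparable convention exists for the
  partial screen. 0.7 is high enough that small-sample partial-correlation
  noise (sd ≈ 1/√(n−p), about 0.14 at n = 70, p = 18) essentially never
  triggers a false drop, and low enough to catch genuine conditional
  dependencies, which in constructed cases sit near 1. It is configurable
  and logged.
* **Greedy largest-pair-first elimination.** Pair elimination needs a
  deterministic, auditable order. The pair with the largest violation is
  resolved first; the dropped member is the one with the larger mean |r| to
  all other remaining features (the more redundant "hub"), with exact ties
  going to the lexicographically later name. A `lexicographic` tie-break
  mode is available for fully name-determined behavior.
* **Ridge regularization of the covariance.** With 70–198 compounds against
  100+ candidates the covariance is singular before the cascade has pruned
  enough features. When rows ≤ features or the condition number exceeds
  1e12, `λ·I` with `λ = 1e-6·trace/dim` is added before inversion and the
  event is reported. With regularization disabled, singularity is an error
  naming the dependent features.
* **Intersection across datasets.** The common set is the plain
  intersection of per-dataset survivors, ordered by the candidate pool —
  the simplest rule consistent with "features that survive everywhere", and
  invariant under dataset permutation. Each stage is a projection
  (idempotent), so re-running the cascade on its own output changes
  nothing.

## Supervised evaluation

`train_eval()` fits an XGBoost model per assay: regression with an
MAE-oriented objective (`reg:absoluteerror`), classification with binary
cross-entropy. Reported metrics are MAE, RMSE and MAE/STD (MAE divided by
the *population* standard deviation of the observed targets, which makes
errors comparable across assays; a best-constant predictor scores ≈ 1), and
for classification BCE (natural log, probabilities clipped at 1e-15) and
accuracy with the full confusion matrix.

The evaluation protocol is an 80/20 train/test split, stratified by class
for classification, with a fixed seed (default 42) — reported for both
partitions since neither split convention can be inferred from assay data
alone. Hyperparameters are fixed, documented defaults (300 rounds, η = 0.1,
depth 4, single thread) rather than an automated search: determinism and
desk-scale runtime matter more here than the last few percent of accuracy,
and the package's claims are about the *feature set*, not about a tuned
model.

Feature importances use tree gain (the common default among the ensemble's
importance variants), min-max scaled so the strongest feature maps exactly
to 1 and the weakest to 0; with all raw importances equal the scaling is
degenerate and everything maps to 0. *Key features* are those with scaled
importance strictly above 0.85.

## Chemical space

`standardize()` centers and scales each feature to population mean 0 and
standard deviation 1; `embed_2d()` concatenates all datasets, standardizes
*jointly* (the compound space is one space, not seven), and runs UMAP to
two dimensions (defaults n_neighbors = 15, min_dist = 0.1, seed = 42; all
parameters are echoed into the result metadata). Axes carry no predefined
meaning — trends such as "polarity increases along dim 1" are post-hoc
readings made by overlaying a feature with
`plot_chemspace(..., color_by = "feature")`.

Two implementation details make the embedding reproducible: the layout runs
single-threaded with a fixed seed, and rows are canonically ordered by
(dataset, id) before the embedding and restored afterwards, so permuting
the input row order can never change any compound's coordinates.

## The synthetic suite

`generate_suite()` emulates the seven-dataset study layout: ORAC (70),
SOAC (71), MTT (71), ABTS (90), DPPH (198), plus two unlabeled background
sets (344 and 109) used only for the embedding — 953 compounds total. Each
dataset carries the same 63-column candidate namespace: 18 planted
informative features (named after real descriptor and mechanism-enthalpy
vocabulary), 30 redundant copies correlated 0.97 with their anchors, 5
constants, and 10 decoys named with excluded prefixes. Regression targets
are sparse linear signals (default three active features, noise sd = 10% of
the signal sd); DPPH labels come from a latent score whose offset is
calibrated so the expected positive fraction is 97/198, with synthetic IC50
values mapped monotonically across the 300 μM boundary so binarization
reproduces the planted labels exactly. Compound records also carry
independent synthetic species enthalpies so the thermo module runs end to
end.

The generator's central numerical choice: features are built as exact
linear combinations of an **in-sample orthonormalized Gaussian basis**
(QR decomposition against the intercept), so every *empirical* correlation
equals its designed value exactly, not merely in expectation. The reason is
statistical, not cosmetic. At n = 70, the sampling noise of a correlation
near 0.97 (≈ 0.007) straddles the 0.95 threshold, and the greedy
tie-break between an anchor and an independently-noised copy would be
decided by sampling fluctuations of order equal to its expected margin — a
coin flip per block per dataset. With the exact construction, copies carry
a shared redundancy-factor loading (plus links to the local decoys) that
gives them a strictly larger mean |r| than their anchor by a fixed,
noise-free margin, so the cascade's behavior on the suite is fully
deterministic: the correlation filter always discards the copy, the
exclusion stage removes exactly the decoys, and the partial screen sees 18
exactly uncorrelated survivors. Sibling copies of the same anchor have
exactly tied profiles and resolve lexicographically.

What the suite does *not* emulate — and therefore what passing tests do not
show about real data: real descriptor marginals (skewed, heavy-tailed,
often integer-valued; the suite's features are Gaussian with exact unit
variance), nonlinear and higher-order dependencies between descriptors,
block structures less tidy than anchor-plus-copies, chemically valid SMILES
matched to feature values, and the rank-3 physical dependency of a
consistent thermo block discussed above. The suite demonstrates that the
machinery is correct and deterministic, not that 18 features suffice for
any particular chemistry.

## Numerical conventions, degenerate inputs, problem sizes

* Strict inequalities at boundaries: IC50 exactly 300 μM is negative;
  scaled importance exactly 0.85 is not a key feature.
* `scale_importance()` on an all-equal vector returns all zeros.
* BCE clips probabilities at 1e-15; TEAC refuses nonpositive IC50s;
  `standardize()` refuses zero-variance columns by name.
* All-constant tables, empty intersections, and fewer than 10 usable
  training rows are hard errors, not silent results.
* Test and acceptance runs use the study-layout sizes (70–344 rows per
  dataset, 953 embedded compounds), 500-row supervised recovery problems,
  10,000 random enthalpy sets for cycle closure and 500 random tables for
  the partial-correlation oracle — sizes chosen so the whole suite is a
  few minutes of single-threaded work while keeping every check
  well-powered.

## Known limitations

* The built-in provider computes a compact OpenBabel pool, not the
  hundred-plus descriptors of larger toolkits; larger pools plug in through
  the provider contract.
* BDE site selection (which O–H bond) is delegated to whatever produced the
  species enthalpies; the package computes one profile per species set.
* The greedy cascade is order-dependent by construction; it is auditable
  (full drop log with partners and values) rather than optimal in any
  global sense.
* UMAP coordinates are reproducible per seed but not comparable across
  seeds or package versions; only neighborhood structure should be
  interpreted.
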