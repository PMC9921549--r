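test_that("generated tables realize the designed correlations exactly", {
  spec <- generator_spec(n_rows = 80, seed = 31)
  ft <- generate_feature_table(spec)
  gt <- attr(ft, "ground_truth")
  expect_equal(ncol(ft$values), 18 + 30 + 10 + 5)
  v <- ft$values[, setdiff(feature_names(ft), gt$constants)]
  cm <- cor(v)
  # anchors vs their copies: exactly copy_corr
  for (k in seq_len(nrow(gt$copies)))
    expect_equal(cm[gt$copies$anchor[k], gt$copies$name[k]], 0.97,
                 tolerance = 1e-10)
  # informative features mutually uncorrelated
  ci <- cm[gt$informative, gt$informative]
  expect_lt(max(abs(ci[upper.tri(ci)])), 1e-10)
  # constants: exactly n_constant zero-variance columns
  vars <- apply(ft$values, 2, var)
  expect_identical(names(vars)[vars == 0], gt$constants)
  # local decoys carry excluded prefixes
  expect_true(all(is_local_descriptor(gt$local_decoys,
                                      c("PEOE_VSA", "SlogP_VSA"))))
  # determinism
  ft2 <- generate_feature_table(spec)
  expect_identical(ft$values, ft2$values)
})

test_that("equicorrelated blocks are exact at any size and rho", {
  for (rho in c(0.3, 0.9)) {
    eq <- generate_equicorrelated(60, 4, rho, seed = 32)
    cm <- cor(eq$values)
    expect_equal(unname(cm[upper.tri(cm)]), rep(rho, 6), tolerance = 1e-10)
  }
})

test_that("continuity proxy: surviving features take many distinct values", {
  spec <- generator_spec(n_rows = 200, seed = 33)
  ft <- generate_feature_table(spec)
  keep <- !is_local_descriptor(feature_names(ft), spec$exclusion_prefixes) &
    !feature_names(ft) %in% attr(ft, "ground_truth")$constants
  counts <- apply(ft$values[, keep], 2, function(x) length(unique(x)))
  expect_true(all(counts > 10))
})

test_that("regression targets are linear in the active features", {
  spec <- generator_spec(n_rows = 50, n_copies = 0, n_constant = 0,
                         n_local = 0, seed = 34)
  ft <- generate_feature_table(spec)
  y0 <- generate_regression_targets(ft, c(TPSA = 2, BDE = -1), noise_sd = 0,
                                    seed = 34)
  expect_equal(as.numeric(y0),
               as.numeric(2 * ft$values[, "TPSA"] - ft$values[, "BDE"]))
  y1 <- generate_regression_targets(ft, c(TPSA = 1), noise_sd = 0, seed = 34)
  expect_equal(cor(as.numeric(y1), ft$values[, "TPSA"]), 1)
  expect_error(generate_regression_targets(ft, c(nope = 1), seed = 1),
               "unknown active")
})

test_that("classification targets calibrate the class balance", {
  spec <- generator_spec(n_rows = 198, n_copies = 0, n_constant = 0,
                         n_local = 0, seed = 35)
  ft <- generate_feature_table(spec)
  # no signal: balance within binomial noise of 50/50
  cl0 <- generate_classification_targets(ft, c(TPSA = 1), separation = 0,
                                         seed = 35, positive_rate = 0.5)
  expect_lt(abs(sum(cl0$labels == "positive") - 99), 3.5 * sqrt(198 * 0.25))
  # binarizing the synthetic IC50 reproduces the planted labels exactly
  cl <- generate_classification_targets(ft, c(TPSA = 3, BDE = -2),
                                        separation = 2, seed = 36)
  expect_identical(as.character(binarize_dpph(cl$ic50)),
                   as.character(cl$labels))
  expect_true(all(cl$ic50 >= 0))
  # calibration: mean positive count over seeds close to 97
  counts <- vapply(1:60, function(s) {
    c2 <- generate_classification_targets(ft, c(TPSA = 3, BDE = -2),
                                          separation = 2, seed = 100 + s)
    sum(c2$labels == "positive")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 97), 3)
})

test_that("the default suite matches the study layout and serializes", {
  suite <- generate_suite(seed = 37)
  sizes <- vapply(suite$tables, function(t) nrow(t$values), integer(1))
  expect_identical(unname(sizes), c(70L, 71L, 71L, 90L, 198L, 344L, 109L))
  expect_identical(sum(sizes), 953L)
  expect_identical(suite$datasets$DPPH$task, "classification")
  expect_identical(suite$datasets$phytochemicals$task, "none")
  # synthetic enthalpies support the full mechanism-enthalpy block
  tf <- thermo_features(suite$datasets$ORAC)
  expect_false(anyNA(tf$values))
  # regeneration with the same seed is byte-identical on disk
  d1 <- file.path(tempdir(), "suite1"); d2 <- file.path(tempdir(), "suite2")
  write_suite(suite, d1)
  write_suite(generate_suite(seed = 37), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_identical(gt$informative, default_informative_features())
  expect_identical(length(gt$informative), 18L)
  # features CSV round-trips into the pipeline
  back <- read_feature_table(file.path(d1, "ORAC_features.csv"))
  expect_equal(back$values, suite$tables$ORAC$values, tolerance = 1e-9)
  expect_identical(unname(back$provenance["BDE"]), "thermo")
})
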