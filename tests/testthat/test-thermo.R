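test_that("mechanism enthalpies follow the defining combinations", {
  # O-H homolysis with only H(H.) nonzero among references
  p <- thermo_profile(species_enthalpies(-50, -10, 0, 0),
                      reference_constants(52.103, 0, 0))
  expect_equal(p$bde, 92.103)
  # all-zero input gives an all-zero profile
  p0 <- thermo_profile(species_enthalpies(0, 0, 0, 0),
                       reference_constants(0, 0, 0))
  expect_equal(unlist(p0[c("bde", "ip", "pde", "pa", "ete")]),
               c(bde = 0, ip = 0, pde = 0, pa = 0, ete = 0))
  # direct substitution of all five definitions
  sp <- species_enthalpies(-42.5, -3.1, 138.2, -71.9)
  cst <- reference_constants()
  pr <- thermo_profile(sp, cst)
  expect_equal(pr$ip, sp$h_radical_cation + cst$h_electron - sp$h_neutral)
  expect_equal(pr$pde, sp$h_radical + cst$h_proton - sp$h_radical_cation)
  expect_equal(pr$pa, sp$h_anion + cst$h_proton - sp$h_neutral)
  expect_equal(pr$ete, sp$h_radical + cst$h_electron - sp$h_anion)
  expect_error(thermo_profile(list(h_neutral = NaN, h_radical = 0,
                                   h_radical_cation = 0, h_anion = 0)))
})

test_that("both two-step mechanisms close the same thermodynamic cycle", {
  set.seed(11)
  for (k in 1:200) {
    sp <- species_enthalpies(sample(-100:100, 1), sample(-100:100, 1),
                             sample(-100:100, 1), sample(-100:100, 1))
    cst <- reference_constants(runif(1, 0, 100), runif(1, 0, 400),
                               runif(1, -5, 5))
    p <- thermo_profile(sp, cst)
    expect_lt(abs((p$ip + p$pde) - (p$pa + p$ete)), 1e-9)
    expect_lt(abs((p$pa + p$ete - p$bde) -
                    (cst$h_proton + cst$h_electron - cst$h_h_atom)), 1e-9)
  }
})

test_that("shifting all species enthalpies shifts the profile predictably", {
  sp <- list(h_neutral = -30, h_radical = 5, h_radical_cation = 150,
             h_anion = -60)
  cst <- reference_constants()
  base <- thermo_profile(species_enthalpies(-30, 5, 150, -60), cst)
  c0 <- 17.25
  shifted <- thermo_profile(
    species_enthalpies(-30 + c0, 5 + c0, 150 + c0, -60 + c0), cst)
  # each enthalpy is (one species) - (one species) + constants: shifts cancel
  for (f in c("bde", "ip", "pde", "pa", "ete"))
    expect_equal(shifted[[f]], base[[f]])
})

test_that("TEAC is the Trolox/sample IC50 ratio and scale-invariant", {
  expect_equal(teac(10, 10), 1)
  expect_equal(teac(10, 5), 2)
  expect_error(teac(10, 0), "positive")
  expect_error(teac(-1, 5), "positive")
  set.seed(2)
  a <- runif(20, 0.1, 50); b <- runif(20, 0.1, 50); k <- runif(20, 0.1, 9)
  expect_equal(teac(k * a, k * b), teac(a, b))
})

test_that("thermo_features matches per-row profiles and handles gaps", {
  rec <- data.frame(id = c("m1", "m2", "m3"),
                    h_neutral = c(-50, -42.5, -30),
                    h_radical = c(-10, -3.1, 6),
                    h_radical_cation = c(130, 138.2, 151),
                    h_anion = c(-80, -71.9, NA))
  ds <- compound_dataset(rec, "mini", "none")
  ft <- suppressMessages(thermo_features(ds))
  expect_identical(feature_names(ft), c("BDE", "IP", "PDE", "PA", "ETE"))
  expect_identical(unique(unname(ft$provenance)), "thermo")
  for (i in 1:2) {
    pr <- thermo_profile(species_enthalpies(rec$h_neutral[i], rec$h_radical[i],
                                            rec$h_radical_cation[i],
                                            rec$h_anion[i]))
    expect_equal(unname(ft$values[i, ]),
                 unlist(pr[c("bde", "ip", "pde", "pa", "ete")],
                        use.names = FALSE))
  }
  # missing anion: PA/ETE missing, BDE/IP/PDE present
  expect_true(all(is.na(ft$values["m3", c("PA", "ETE")])))
  expect_false(anyNA(ft$values["m3", c("BDE", "IP", "PDE")]))
})
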