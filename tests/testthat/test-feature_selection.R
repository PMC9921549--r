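test_that("constant features are dropped at the tolerance", {
  m <- cbind(flat = rep(5, 6), near = c(1, 1, 1, 1, 1, 1 + 1e-15),
             keep = c(0, 1, 0, 1, 0, 1))
  rownames(m) <- sprintf("c%d", 1:6)
  ft <- feature_table(m)
  out <- drop_constant(ft, tol = 1e-12)
  expect_identical(feature_names(out), "keep")
  log <- attr(out, "stage_log")
  expect_setequal(log$dropped$feature, c("flat", "near"))
  # everything constant is a hard error
  allc <- feature_table(matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 4, 2,
                               dimnames = list(sprintf("r%d", 1:4),
                                               c("a", "b"))))
  expect_error(drop_constant(allc), "all features are constant")
  # projection: applying twice equals applying once
  out2 <- drop_constant(out)
  expect_identical(out2$values, out$values)
})

test_that("correlation filter enforces the pairwise threshold greedily", {
  set.seed(4)
  base <- rnorm(40)
  m <- cbind(A = base, B = base, C = rnorm(40))
  rownames(m) <- sprintf("c%d", 1:40)
  ft <- feature_table(m)
  out <- correlation_filter(ft, threshold = 0.95)
  # exactly one of the duplicated pair dropped
  expect_length(intersect(feature_names(out), c("A", "B")), 1L)
  expect_true("C" %in% feature_names(out))

  # pair straddling the threshold: r = 0.96 dropped, r = 0.94 kept
  n <- 4000
  set.seed(5)
  x <- rnorm(n)
  make_pair <- function(r) x * r + rnorm(n) * sqrt(1 - r^2)
  m2 <- cbind(X = x, hi = make_pair(0.995), lo = rnorm(n))
  r_hi <- cor(m2[, "X"], m2[, "hi"])
  expect_gt(r_hi, 0.95)
  rownames(m2) <- sprintf("c%d", 1:n)
  out2 <- correlation_filter(feature_table(m2), 0.95)
  expect_length(intersect(feature_names(out2), c("X", "hi")), 1L)
  expect_true("lo" %in% feature_names(out2))

  # three mutually collinear features leave exactly one survivor, and no
  # surviving pair violates the threshold (brute-force check)
  set.seed(6)
  z <- rnorm(500)
  m3 <- sapply(1:3, function(i) z + rnorm(500, sd = 0.02))
  colnames(m3) <- c("p1", "p2", "p3"); rownames(m3) <- sprintf("c%d", 1:500)
  m3 <- cbind(m3, other = rnorm(500))
  out3 <- correlation_filter(feature_table(m3), 0.95)
  expect_length(intersect(feature_names(out3), c("p1", "p2", "p3")), 1L)
  cm <- abs(cor(out3$values)); diag(cm) <- 0
  expect_lt(max(cm), 0.95)
  # drop log records partner and correlation
  log <- attr(out3, "stage_log")$dropped
  expect_true(all(abs(log$r) >= 0.95))
  expect_true(all(log$partner %in% colnames(m3)))
})

test_that("partial correlations from the precision matrix match the oracle", {
  # two features: partial equals marginal
  ft <- tiny_feature_table(n = 30, features = c("a", "b"), seed = 7)
  pm <- partial_correlation_matrix(ft)
  expect_equal(pm["a", "b"], cor(ft$values)[1, 2])
  # residual-regression equivalence on random small tables
  set.seed(8)
  for (k in 1:25) {
    p <- sample(3:8, 1); n <- p + sample(3:40, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("r%d", 1:n), sprintf("f%d", 1:p)))
    pmk <- partial_correlation_matrix(x, regularize = FALSE)
    expect_equal(pmk, t(pmk), tolerance = 1e-10)
    for (i in 1:(p - 1)) for (j in (i + 1):p)
      expect_equal(pmk[i, j], residual_partial_cor(x, i, j),
                   tolerance = 1e-8)
  }
  # equicorrelated closed form: rho / (1 + rho) for three features
  eq <- generate_equicorrelated(100, 3, 0.5, seed = 9)
  pe <- partial_correlation_matrix(eq)
  expect_equal(unname(pe[upper.tri(pe)]), rep(1 / 3, 3), tolerance = 1e-10)
  # near-independence at large n
  set.seed(10)
  big <- matrix(rnorm(10000 * 5), 10000, 5,
                dimnames = list(NULL, paste0("g", 1:5)))
  rownames(big) <- sprintf("r%d", 1:10000)
  pb <- partial_correlation_matrix(big)
  expect_lt(max(abs(pb[upper.tri(pb)])), 0.05)
})

test_that("singular covariance errors without regularization, works with it", {
  set.seed(11)
  a <- rnorm(50); b <- rnorm(50)
  x <- cbind(A = a, B = b, C = a + b)  # exact linear dependence
  rownames(x) <- sprintf("r%d", 1:50)
  expect_error(partial_correlation_matrix(x, regularize = FALSE), "singular")
  pm <- suppressMessages(partial_correlation_matrix(x, regularize = TRUE))
  expect_true(all(is.finite(pm)))
})

test_that("partial-correlation screen removes conditionally dependent features", {
  # exact construction: X3 is the sum of X1 and X2 plus tiny noise, so the
  # only conditional dependencies are within the triplet and the greedy
  # screen must discard exactly the derived feature
  set.seed(12)
  n <- 200
  lat <- antioxsar:::orthonormal_latents(n, 4)
  m <- cbind(X1 = lat[, 1], X2 = lat[, 2],
             X3 = lat[, 1] + lat[, 2] + 0.05 * lat[, 3],
             X4 = lat[, 4])
  rownames(m) <- sprintf("r%d", 1:n)
  pm0 <- partial_correlation_matrix(m)
  expect_gt(abs(pm0["X3", "X1"]), 0.99)
  expect_gt(abs(pm0["X3", "X2"]), 0.99)
  out <- partial_corr_screen(feature_table(m), threshold = 0.7)
  expect_identical(feature_names(out), c("X1", "X2", "X4"))
  pm <- partial_correlation_matrix(out)
  expect_lt(max(abs(pm[upper.tri(pm)])), 0.7)
  # already-screened table is a fixed point
  out2 <- partial_corr_screen(out, threshold = 0.7)
  expect_identical(feature_names(out2), feature_names(out))
  # vacuous threshold drops nothing
  keepall <- partial_corr_screen(feature_table(m), threshold = 1)
  expect_identical(feature_names(keepall), colnames(m))
})

test_that("the cascade intersects survivors across datasets in pool order", {
  suite <- generate_suite(seed = 21)
  tabs <- task_tables(suite)
  rep <- select_common_features(tabs)
  expect_s3_class(rep, "selection_report")
  expect_identical(rep$common_features, default_informative_features())
  # stage order is fixed
  expect_identical(names(rep$datasets$ORAC$stages),
                   c("drop_constant", "correlation_filter", "exclude_local",
                     "partial_corr_screen"))
  # dropped + survivors partition the input at every stage
  for (st in rep$datasets$ORAC$stages)
    expect_setequal(c(st$features_out, st$dropped$feature), st$features_in)
  # order-invariance under dataset permutation
  rep2 <- select_common_features(tabs[c(3, 1, 5, 2, 4)])
  expect_setequal(rep2$common_features, rep$common_features)
  # identical tables for all datasets reduce to single-table survivors
  solo <- select_common_features(tabs["ORAC"])
  expect_identical(rep$common_features, solo$common_features)
  # explicit intersection semantics
  expect_identical(Reduce(intersect,
                          lapply(rep$datasets, `[[`, "survivors")),
                   rep$common_features)
})

test_that("selection report serializes to JSON", {
  suite <- generate_suite(seed = 22, sizes = c(ORAC = 70L, ABTS = 90L))
  rep <- select_common_features(suite$tables)
  path <- tempfile(fileext = ".json")
  write_selection_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$common_features, rep$common_features)
  expect_identical(back$datasets$ORAC$stages$drop_constant$n_out, 58L)
})
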