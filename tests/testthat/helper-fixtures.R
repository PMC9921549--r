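# Small fixtures shared across test files; everything is built in code.

tiny_feature_table <- function(n = 6, features = c("TPSA", "MolLogP", "BDE"),
                               seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * length(features)), n, length(features),
              dimnames = list(sprintf("c%02d", seq_len(n)), features))
  feature_table(m)
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# brute-force partial correlation of columns i, j via residual regressions
residual_partial_cor <- function(x, i, j) {
  others <- x[, -c(i, j), drop = FALSE]
  if (ncol(others) == 0) return(stats::cor(x[, i], x[, j]))
  ri <- stats::resid(stats::lm(x[, i] ~ others))
  rj <- stats::resid(stats::lm(x[, j] ~ others))
  stats::cor(ri, rj)
}

# default suite restricted to the five task datasets
task_tables <- function(suite)
  suite$tables[c("ORAC", "SOAC", "MTT", "ABTS", "DPPH")]
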