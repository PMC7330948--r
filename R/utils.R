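# Internal helpers shared across modules.

# Fold a vector of integer components into a seed in [1, 2^31 - 2].
# Modular multiply-accumulate (FNV-style) keeps everything inside double
# precision: all intermediates stay below 2^52.
derive_seed <- function(...) {
  xs <- c(...)
  h <- 216613626
  for (x in xs) {
    h <- (h * 16777 + as.numeric(x) + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

# Column means/variances without matrixStats.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows to compute a variance")
  m <- colMeans(x)
  (colSums(x^2) - n * m^2) / (n - 1)
}

# Vectorized Welch two-sample t-test over the columns of two matrices
# (cases and controls share columns). Returns p-values and the linear-scale
# fold change case/control.
welch_columns <- function(case, control) {
  n1 <- nrow(case)
  n2 <- nrow(control)
  m1 <- colMeans(case)
  m2 <- colMeans(control)
  v1 <- col_vars(case)
  v2 <- col_vars(control)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1 # both groups constant: no evidence either way
  list(p_value = unname(p), fold_change = unname(m1 / m2),
       mean_case = unname(m1), mean_control = unname(m2))
}

# Rolling polynomial hash of a character string, reported as hex; used to
# stamp pipeline outputs with a provenance fingerprint of their configuration.
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 1779033703
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
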