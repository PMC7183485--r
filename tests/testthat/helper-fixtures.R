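# Small construction helpers shared across test files.

# Normalized-stage matrix straight from a numeric matrix (Pearson is
# affine-invariant, so tests need not z-score first).
norm_cm <- function(v) {
  conc_matrix(v, stage = "normalized")
}

# Two-group Gaussian test data with an optional correlated pair (1,2) in
# the case group only.
two_group_data <- function(n_case, n_control, m, r_case = 0, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  v <- matrix(rnorm(n * m), n, m)
  if (r_case != 0) {
    idx <- seq_len(n_case)
    v[idx, 2] <- r_case * v[idx, 1] + sqrt(1 - r_case^2) * v[idx, 2]
  }
  list(x = norm_cm(v), is_case = rep(c(TRUE, FALSE), c(n_case, n_control)))
}

# Raw-stage matrix from explicit values and an optional lod/missing mask.
raw_cm <- function(v, lod = NULL, missing = NULL) {
  status <- matrix("observed", nrow(v), ncol(v))
  if (!is.null(lod)) status[lod] <- "lod"
  if (!is.null(missing)) status[missing] <- "missing"
  v[status != "observed"] <- NA_real_
  conc_matrix(v, status, stage = "raw")
}
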