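test_that("LOD boundary: exactly 10% below LOD is retained, more is dropped", {
  v <- matrix(rexp(30) + 1, 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  lod <- rbind(c(1, 1),          # A: 1/10 = 10% -> retained
               c(2, 2), c(3, 2)) # B: 2/10 = 20% -> dropped
  out <- filter_lod(raw_cm(v, lod = lod), max_below_lod_fraction = 0.10)
  expect_identical(metabolite_ids(out$matrix), c("A", "C"))
  expect_identical(out$report$excluded_metabolites$metabolite, "B")
  expect_equal(out$report$excluded_metabolites$below_lod_fraction, 0.2)
  expect_identical(out$report$retained_metabolites, 2L)
})

test_that("LOD filter is a no-op without below-LOD values and errors when all fail", {
  v <- matrix(rexp(20) + 1, 5, 4)
  out <- filter_lod(raw_cm(v))
  expect_equal(out$matrix$values, raw_cm(v)$values)
  expect_identical(nrow(out$report$excluded_metabolites), 0L)
  all_lod <- which(matrix(TRUE, 5, 4), arr.ind = TRUE)
  expect_error(filter_lod(raw_cm(v, lod = all_lod)), "all metabolites")
})

test_that("mean imputation fills unavailable cells and leaves observed data alone", {
  v <- matrix(c(2, 4, NA, 10, 20, 30), 3, 2, dimnames = list(NULL, c("A", "B")))
  x <- raw_cm(v, missing = cbind(3, 1))
  out <- impute_mean(x)
  expect_equal(out$matrix$values[3, 1], 3)           # mean of {2, 4}
  expect_equal(unname(out$matrix$values[, 2]), c(10, 20, 30))
  expect_identical(out$matrix$status[3, 1], "imputed")
  expect_identical(out$report$imputed_count, 1L)
  expect_identical(out$matrix$stage, "imputed")

  noop <- impute_mean(raw_cm(matrix(1:6 + 0.5, 3, 2)))
  expect_identical(noop$report$imputed_count, 0L)

  empty <- raw_cm(matrix(c(NA, NA, NA, 1, 2, 3), 3, 2),
                  missing = cbind(1:3, 1))
  expect_error(impute_mean(empty), "zero observed values")
})

test_that("log/Z-score normalization matches the hand-computed example", {
  v <- matrix(c(exp(1), exp(1), exp(2)), 3, 1, dimnames = list(NULL, "A"))
  x <- conc_matrix(v, stage = "raw")
  z <- log_zscore(impute_mean(x)$matrix)
  # ln -> {1, 1, 2}; sample SD (n-1) = 0.57735
  expect_equal(as.numeric(z$values),
               c(-0.5773503, -0.5773503, 1.1547005), tolerance = 1e-6)
  expect_identical(z$stage, "normalized")
})

test_that("Z-scores are invariant to multiplicative rescaling of raw values", {
  set.seed(42)
  v <- matrix(rexp(40) + 0.5, 10, 4)
  z1 <- log_zscore(impute_mean(conc_matrix(v, stage = "raw"))$matrix)
  z2 <- log_zscore(impute_mean(conc_matrix(v * 7.3, stage = "raw"))$matrix)
  expect_equal(z1$values, z2$values, tolerance = 1e-12)
})

test_that("normalized columns have mean 0 and SD 1, and bad input errors name the cell", {
  set.seed(7)
  v <- matrix(rexp(200) + 0.1, 20, 10)
  z <- log_zscore(impute_mean(conc_matrix(v, stage = "raw"))$matrix)
  expect_lt(max(abs(colMeans(z$values))), 1e-9)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-9)

  bad <- v; bad[3, 2] <- -1
  bad <- conc_matrix(bad, stage = "raw")
  expect_error(log_zscore(impute_mean(bad)$matrix),
               "non-positive concentration at sample S3, metabolite M2")
  const <- conc_matrix(cbind(M1 = rep(2, 5), M2 = 1:5 + 0.0), stage = "raw")
  expect_error(log_zscore(impute_mean(const)$matrix), "zero-variance")
})

test_that("outlier masking is strict beyond k and idempotent", {
  v <- matrix(c(0.1, -0.5, 3.5, 3.0, -3.0, 1.0), 3, 2,
              dimnames = list(NULL, c("A", "B")))
  x <- conc_matrix(v, stage = "normalized")
  out <- mask_outliers(x, k = 3)
  expect_true(is.na(out$matrix$values[3, 1]))       # 3.5 masked
  expect_identical(out$matrix$status[3, 1], "outlier")
  expect_equal(out$matrix$values[1, 2], 3.0)        # exactly k retained
  expect_equal(out$matrix$values[2, 2], -3.0)
  expect_identical(out$report$outlier_count, 1L)

  again <- mask_outliers(out$matrix, k = 3)
  expect_identical(again$report$outlier_count, 0L)
  expect_equal(again$matrix$values, out$matrix$values)
})

test_that("the composed pipeline preserves rows, only drops columns, and reports counts", {
  spec <- cohort_spec(n_case = 10, n_control = 30, n_metabolites = 8,
                      lod_fraction = c(0.3, rep(0.02, 7)),
                      missing_fraction = 0.05, outlier_fraction = 0,
                      seed = 5)
  coh <- generate_cohort(spec)
  out <- preprocess(coh$concentrations)
  expect_identical(nrow(out$matrix$values), 40L)
  expect_identical(out$report$retained_metabolites, 7L)
  expect_identical(out$report$excluded_metabolites$metabolite, "M001")
  # imputed count = masked cells of the generator truth on retained columns
  keep <- metabolite_ids(out$matrix)
  truth_masked <- coh$truth$missing_mask[, keep] | coh$truth$lod_mask[, keep]
  expect_identical(out$report$imputed_count, as.integer(sum(truth_masked)))
})
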