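test_that("default cohort has the study shape and both groups", {
  coh <- generate_cohort(cohort_spec(seed = 2))
  expect_identical(dim(coh$concentrations$values), c(445L, 131L))
  expect_identical(sum(coh$labels == "case"), 67L)
  expect_identical(sum(coh$labels == "control"), 378L)
  expect_identical(dim(coh$truth$lod_mask), dim(coh$concentrations$values))
  expect_identical(dim(coh$truth$outlier_mask), dim(coh$concentrations$values))
  expect_true(all(coh$concentrations$values > 0, na.rm = TRUE))
})

test_that("a fixed seed reproduces the cohort exactly", {
  s <- cohort_spec(n_case = 10, n_control = 20, n_metabolites = 6, seed = 123)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$concentrations$values, b$concentrations$values)
  expect_identical(a$concentrations$status, b$concentrations$status)
  expect_identical(a$outcomes, b$outcomes)
})

test_that("zero censoring/missing/outlier fractions leave every cell observed", {
  s <- cohort_spec(n_case = 8, n_control = 12, n_metabolites = 5,
                   lod_fraction = 0, missing_fraction = 0,
                   outlier_fraction = 0, seed = 4)
  coh <- generate_cohort(s)
  expect_true(all(coh$concentrations$status == "observed"))
  expect_false(any(coh$truth$lod_mask | coh$truth$missing_mask |
                     coh$truth$outlier_mask))
})

test_that("planted correlations are recovered by sample correlation at large n", {
  s <- cohort_spec(n_case = 500, n_control = 500, n_metabolites = 8,
                   planted_edges = data.frame(i = 1, j = 2,
                                              r_case = 0.8, r_control = 0),
                   background_r = 0, lod_fraction = 0, missing_fraction = 0,
                   outlier_fraction = 0, seed = 6)
  coh <- generate_cohort(s)
  lv <- log(coh$concentrations$values)
  r_case <- cor(lv[coh$labels == "case", 1], lv[coh$labels == "case", 2])
  r_ctrl <- cor(lv[coh$labels == "control", 1], lv[coh$labels == "control", 2])
  expect_lt(abs(r_case - 0.8), 0.05)
  se0 <- 1 / sqrt(500 - 3)
  expect_lt(abs(atanh(r_ctrl)), 3 * se0)
})

test_that("without planted structure, between-group correlation differences are noise", {
  s <- cohort_spec(n_case = 300, n_control = 300, n_metabolites = 6,
                   background_r = 0.3, lod_fraction = 0, missing_fraction = 0,
                   outlier_fraction = 0, seed = 14)
  coh <- generate_cohort(s)
  x <- preprocess(coh$concentrations, outlier_k = 100)$matrix
  ed <- diff_edges(x, coh$labels == "case")
  expect_true(all(abs(ed$r_diff) < 4))  # standard-normal scale, 15 pairs
})

test_that("an unplantable correlation target is rejected with the edges named", {
  s <- cohort_spec(n_case = 10, n_control = 10, n_metabolites = 3,
                   planted_edges = data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                                              r_case = c(0.9, 0.9, -0.9),
                                              r_control = 0),
                   background_r = 0)
  expect_error(generate_cohort(s), "not positive definite.*\\(1,2\\)")
  expect_error(cohort_spec(planted_edges = data.frame(i = 1, j = 1,
                                                      r_case = 0.5,
                                                      r_control = 0)),
               "distinct")
  expect_error(cohort_spec(n_case = 3), "at least 4")
  expect_error(cohort_spec(background_r = 1), "background_r")
})

test_that("masked fractions land near their expectations", {
  s <- cohort_spec(n_case = 100, n_control = 300, n_metabolites = 20,
                   lod_fraction = 0.10, missing_fraction = 0.05,
                   outlier_fraction = 0, seed = 16)
  coh <- generate_cohort(s)
  expect_equal(mean(coh$truth$lod_mask), 0.10, tolerance = 0.1)
  expect_equal(mean(coh$truth$missing_mask), 0.05, tolerance = 0.2)
})

test_that("synthetic WOMAC scores respect ranges and the responder contract", {
  coh <- generate_cohort(cohort_spec(n_case = 50, n_control = 150, seed = 18,
                                     n_metabolites = 5))
  oc <- coh$outcomes
  expect_true(all(oc$baseline_pain %in% 0:20, oc$followup_pain %in% 0:20))
  expect_true(all(oc$baseline_function %in% 0:68, oc$followup_function %in% 0:68))
  lab <- classify_responders(oc)
  expect_identical(lab$pain == "non-responder", coh$labels == "case")
  expect_identical(lab$`function.` == "non-responder", coh$labels == "case")
  expect_false(any(lab$pain == "excluded"))
})
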