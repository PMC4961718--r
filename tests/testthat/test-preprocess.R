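test_that("net hope is the hope/fear difference with range validation", {
  expect_equal(net_hope(2.0, 2.0), 0.0)
  expect_equal(net_hope(3.0, 0.0), 3.0)
  expect_equal(net_hope(1.5, 2.25), -0.75)
  expect_error(net_hope(3.5, 1.0), "range")
  expect_error(net_hope(1.0, -0.1), "range")
})

test_that("best_attempt picks by orientation and propagates missing", {
  expect_equal(best_attempt(c(10.9, 10.71), "lower"), 10.71)
  expect_equal(best_attempt(c(28, 30), "higher"), 30)
  expect_true(is.na(best_attempt(c(NA_real_, NA_real_), "lower")))
  expect_equal(best_attempt(c(NA, 9.8), "lower"), 9.8)
  m <- rbind(c(1, 3), c(NA, 2), c(NA, NA))
  expect_equal(best_attempt(m, "higher"), c(3, 2, NA))
})

test_that("zscore_column standardizes (sample sd) and aligns orientation", {
  expect_equal(zscore_column(c(1, 2, 3), "higher"), c(-1, 0, 1))
  expect_equal(zscore_column(c(1, 2, 3), "lower"), c(1, 0, -1))
  expect_error(zscore_column(c(5, 5, 5)), "variance")
  # idempotence
  x <- rnorm(50)
  expect_equal(zscore_column(zscore_column(x)), zscore_column(x),
               tolerance = 1e-12)
})

test_that("composite is the element-wise mean", {
  expect_equal(composite(c(1, -1), c(0, 0)), c(0.5, -0.5))
  x <- rnorm(10)
  expect_equal(composite(x, x, x), x)
  expect_equal(composite(c(1, 2), c(-2, 0), c(1, -2)), c(0, 0))
  expect_error(composite(1:3, 1:4), "length")
})

test_that("percent_adult_height computes the maturity proxy", {
  expect_equal(percent_adult_height(150, 178.57), 84.0, tolerance = 1e-3)
  expect_equal(percent_adult_height(170, 170), 100)
  expect_error(percent_adult_height(150, 0), "positive")
  expect_warning(percent_adult_height(181, 180), "exceeds")
})

test_that("generated cohorts land in the observed maturity band", {
  sim <- generate_panel(generator_config(seed = 11, raw_mode = TRUE,
                                         missing_rate = 0, n_outliers = 0))
  d <- sim$panel$data
  m <- tapply(d$pct_adult_height, d$timepoint, mean)
  expect_gt(m[["1"]], 83.63)
  expect_lt(m[["3"]], 94.94)
  expect_true(all(diff(m) > 0))
})

test_that("build_factor_panel yields standardized factors and logs imputation", {
  sim <- generate_panel(generator_config(seed = 5, raw_mode = TRUE))
  fp <- suppressWarnings(build_factor_panel(sim$panel))
  m <- as.matrix(as.data.frame(fp)[, c("net_hope", "technical_skills",
                                       "physical_fitness",
                                       "biological_maturity")])
  expect_false(anyNA(m))
  for (tp in 1:3) {
    mt <- m[fp$timepoint == tp, ]
    expect_lt(max(abs(colMeans(mt))), 1e-9)
    expect_equal(unname(apply(mt, 2, sd)), rep(1, 4), tolerance = 1e-9)
  }
  # the imputed share reflects the masked measure cells
  expect_equal(attr(fp, "imputed_fraction"), 0.18, tolerance = 0.035)
  expect_s3_class(attr(fp, "mcar"), "mcar_test")
})

test_that("factor scores recover the planted profile structure from raw scores", {
  sim <- generate_panel(generator_config(seed = 21, raw_mode = TRUE,
                                         missing_rate = 0, n_outliers = 0))
  fp <- build_factor_panel(sim$panel)
  m <- factor_matrix(fp, 1)
  truth_t1 <- sim$truth$cluster_path[rownames(m), 1]
  # within-cluster factor means should echo the planted centroids
  cent <- sim$truth$config$centroids[[1]]
  rec <- sapply(1:4, function(j) tapply(m[, j], truth_t1, mean))
  expect_gt(cor(as.vector(rec), as.vector(cent)), 0.9)
})

test_that("a single-timepoint raw panel builds a valid one-timepoint factor panel", {
  sim <- generate_panel(generator_config(seed = 9, n_timepoints = 1,
                                         raw_mode = TRUE,
                                         missing_rate = 0.1))
  fp <- suppressWarnings(build_factor_panel(sim$panel))
  expect_equal(unique(fp$timepoint), 1L)
  expect_false(anyNA(as.data.frame(fp)[, "net_hope"]))
})
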