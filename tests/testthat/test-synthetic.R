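test_that("generator defaults produce the emulated panel shape", {
  sim <- generate_panel(generator_config(seed = 1))
  d <- as.data.frame(sim$panel)
  expect_equal(length(unique(d$person_id)), 120)
  expect_equal(sort(unique(d$timepoint)), 1:3)
  mm <- as.matrix(d[, c("net_hope", "technical_skills",
                        "physical_fitness", "biological_maturity")])
  expect_equal(mean(is.na(mm)), 0.18, tolerance = 0.03)
  expect_length(sim$truth$outlier_ids, 4)
  expect_true(all(sim$truth$outcome %in% 0:2))
})

test_that("the noiseless limit emits exact centroids", {
  cfg <- generator_config(missing_rate = 0, n_outliers = 0, within_sd = 0,
                          seed = 2)
  sim <- generate_panel(cfg)
  d <- as.data.frame(sim$panel)
  for (tp in 1:3) {
    m <- as.matrix(d[d$timepoint == tp, c("net_hope", "technical_skills",
                                          "physical_fitness",
                                          "biological_maturity")])
    want <- cfg$centroids[[tp]][sim$truth$cluster_path[, tp], ]
    expect_equal(unname(m), unname(want))
  }
})

test_that("generation is deterministic under a fixed seed, distinct across seeds", {
  s1 <- generate_panel(generator_config(seed = 42))
  s2 <- generate_panel(generator_config(seed = 42))
  expect_identical(s1, s2)
  s3 <- generate_panel(generator_config(seed = 43))
  expect_false(identical(s1$truth$cluster_path, s3$truth$cluster_path))
})

test_that("describe reports exact bookkeeping on the noiseless panel", {
  cfg <- generator_config(missing_rate = 0, n_outliers = 0, within_sd = 0,
                          seed = 3)
  sim <- generate_panel(cfg)
  ds <- describe_panel(sim$panel, sim$truth)
  expect_equal(ds$missing_fraction, 0)
  expect_equal(colSums(ds$cluster_sizes), rep(120, 3))
  path <- sim$truth$cluster_path
  want12 <- unclass(table(path[, 1], path[, 2]))
  expect_equal(unname(unclass(ds$transition_counts[[1]])), unname(want12))
  # mismatched pair errors
  other <- generate_panel(generator_config(n_persons = 50, seed = 4))
  expect_error(describe_panel(other$panel, sim$truth), "match")
})

test_that("chain marginals converge to the realized cluster frequencies", {
  cfg <- generator_config(n_persons = 10000, n_timepoints = 2,
                          missing_rate = 0, n_outliers = 0, seed = 5)
  sim <- generate_panel(cfg)
  # t2 marginal of the uniform-start chain is uniform for the default
  # symmetric transition matrix
  marg <- tabulate(sim$truth$cluster_path[, 2], 4) / 10000
  expect_equal(marg, rep(0.25, 4), tolerance = 0.02)
})

test_that("planted outliers are flagged as residues at default settings", {
  hits <- vapply(1:40, function(seed) {
    sim <- generate_panel(generator_config(seed = seed, missing_rate = 0))
    rep <- suppressWarnings(
      find_residues(factor_matrix(sim$panel, 1), residue_config()))
    all(sim$truth$outlier_ids %in% rep$residue_ids)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("raw mode anchors test-score means at the published scales", {
  sim <- generate_panel(generator_config(seed = 6, raw_mode = TRUE,
                                         missing_rate = 0, n_outliers = 0))
  d <- sim$panel$data
  t1 <- d[d$timepoint == 1, ]
  sprint_best <- pmin(t1$sprint_40m_1, t1$sprint_40m_2)
  se <- sd(sprint_best) / sqrt(nrow(t1))
  expect_lt(abs(mean(sprint_best) - 6.64), 3 * se + 0.05)
  expect_true(all(t1$hs >= 0 & t1$hs <= 3))
  expect_true(all(t1$ff >= 0 & t1$ff <= 3))
  # hs/ff pairs are not collinear (shared-shift construction)
  expect_lt(abs(cor(t1$hs, t1$hs + t1$ff)), 0.999)
})
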