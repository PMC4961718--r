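test_that("ward_tree merges duplicates first and matches the ESS oracle", {
  x <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(9, 9, 9, 9), c(9, 9, 9, 9))
  tr <- ward_tree(x)
  expect_equal(tr$increments[1:2], c(0, 0))
  expect_gt(tr$increments[3], 100)

  set.seed(10)
  for (r in 1:20) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 4), n)
    tr <- ward_tree(x)
    o <- oracle_ward(x)
    expect_identical(tree_merge_sets(tr), o$merges)
    expect_equal(tr$increments, o$increments, tolerance = 1e-8)
  }
})

test_that("Ward fusion increments are non-decreasing", {
  set.seed(11)
  for (r in 1:50) {
    x <- matrix(rnorm(30 * 4), 30)
    expect_true(all(diff(ward_tree(x)$increments) > -1e-10))
  }
})

test_that("mojena flags the outstanding fusion and guards degenerate series", {
  # standardized value of 10 in [1,1,1,1,10] is ~1.79 sample-sd units
  res <- mojena_suggest(c(1, 1, 1, 1, 10), c = 1.5)
  expect_equal(res$stage, 5L)
  expect_equal(res$k, 2L)
  expect_true(is.na(mojena_suggest(c(2, 2, 2, 2, 2), c = 1.5)$k))
  # raising the threshold beyond the outlier's z removes the suggestion
  expect_true(is.na(mojena_suggest(c(1, 1, 1, 1, 10), c = 2.75)$k))
})

test_that("eess matches a direct variance decomposition and its limits", {
  set.seed(12)
  x <- matrix(rnorm(40 * 4), 40)
  expect_equal(eess(x, seq_len(40)), 100)         # singletons
  expect_equal(eess(x, rep(1L, 40)), 0)           # one cluster
  cl <- sample(1:3, 40, replace = TRUE)
  # R^2 of a one-way decomposition as the oracle
  gm <- colMeans(x)
  ssb <- sum(sapply(split(seq_len(40), cl), function(i)
    length(i) * (colMeans(x[i, , drop = FALSE]) - gm)^2))
  sst <- sum(sweep(x, 2, gm)^2)
  expect_equal(eess(x, cl), 100 * ssb / sst, tolerance = 1e-10)
})

test_that("homogeneity count behaves at the extremes", {
  set.seed(13)
  tight <- rbind(matrix(rnorm(40, sd = 0.05), 10),
                 matrix(rnorm(40, sd = 0.05) + 10, 10))
  hf <- homogeneity_f_count(tight, rep(1:2, each = 10))
  expect_equal(hf$count, 0)
  # singletons have zero within-variance cells
  x <- matrix(rnorm(20), 5)
  expect_equal(homogeneity_f_count(x, 1:5)$count, 0)
  # random split of homogeneous data: ratios near 1, some above
  x <- matrix(rnorm(200 * 4), 200)
  hf <- homogeneity_f_count(x, rep(1:2, 100))
  expect_true(all(hf$table > 0.7 & hf$table < 1.3))
})

test_that("relocation is a descent method with a fixed point", {
  set.seed(14)
  d <- make_planted(14)
  tr <- ward_tree(d$x)
  for (k in c(2, 4, 6)) {
    init <- cut_ward(tr, k)
    ssw0 <- sum(sapply(split(seq_len(nrow(d$x)), init), function(i) {
      xi <- d$x[i, , drop = FALSE]
      sum(sweep(xi, 2, colMeans(xi))^2)
    }))
    sol <- relocate(d$x, init, timepoint = 1L)
    expect_lte(sol$ss_within, ssw0 + 1e-10)
    # re-relocating a fixed point changes nothing
    sol2 <- relocate(d$x, sol$assignments)
    expect_equal(unname(sol2$assignments), unname(sol$assignments))
  }
})

test_that("centroids equal within-cluster means and every person is assigned", {
  set.seed(15)
  d <- make_planted(15, n = 60)
  sol <- relocate(d$x, cut_ward(ward_tree(d$x), 4))
  expect_length(sol$assignments, 60)
  for (cl in 1:4) {
    i <- names(sol$assignments)[sol$assignments == cl]
    expect_equal(unname(sol$centroids[cl, ]),
                 unname(colMeans(d$x[i, , drop = FALSE])))
  }
  expect_equal(sum(sol$sizes), 60)
})

test_that("select_solution recovers planted structure and reports diagnostics", {
  d <- make_planted(16, separation = 6)   # well-separated clusters
  sel <- select_solution(d$x, k_candidates = 2:8)
  expect_named(sel$diagnostics,
               c("k", "eess_percent", "f_count", "mojena_flagged",
                 "elbow_drop"))
  expect_equal(sel$pick, 4L)
  sol <- sel$solutions[["4"]]
  expect_gt(oracle_ari(sol$assignments[rownames(d$x)], d$z), 0.9)
  # EESS grows weakly with k along cuts of one Ward tree
  tr <- ward_tree(d$x)
  ee <- vapply(2:8, function(k) eess(d$x, cut_ward(tr, k)), numeric(1))
  expect_true(all(diff(ee) > -1e-10))
})

test_that("structureless data yields a low-confidence fallback pick", {
  set.seed(17)
  x <- matrix(rnorm(80 * 4), 80)
  sel <- select_solution(x, k_candidates = 3:5)
  expect_true(sel$pick %in% 3:5)
  expect_true(sel$low_confidence || !is.na(sel$mojena$k))
})
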