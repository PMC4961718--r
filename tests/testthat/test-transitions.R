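test_that("transition_table counts over the inner join with conserved margins", {
  a <- setNames(c(1, 1, 1), c("A", "B", "C"))
  b <- setNames(c(1, 1, 1, 2), c("A", "B", "C", "D"))
  tab <- transition_table(a, b)
  expect_equal(tab["1", "1"], 3L)
  expect_equal(sum(tab), 3L)            # D dropped by the join
  expect_error(transition_table(setNames(1, "A"), setNames(1, "B")),
               "no persons")
  set.seed(30)
  ids <- sprintf("p%02d", 1:40)
  x <- setNames(sample(1:3, 40, TRUE), ids)
  y <- setNames(sample(1:4, 40, TRUE), ids)
  tab <- transition_table(x, y)
  expect_equal(unname(rowSums(tab)), unname(as.vector(table(x))))
  expect_equal(unname(colSums(tab)), unname(as.vector(table(y))))
})

test_that("collapse_2x2 rebuilds margins and conserves N", {
  tab <- rbind(c(10, 5), c(5, 10))
  expect_equal(collapse_2x2(tab, 1, 1), c(10, 5, 5, 10))
  set.seed(31)
  tab <- matrix(rpois(12, 5), 3, 4)
  for (i in 1:3) for (j in 1:4) {
    cell <- collapse_2x2(tab, i, j)
    expect_equal(sum(cell), sum(tab))
    expect_equal(cell[1], tab[i, j])
  }
  tab0 <- rbind(c(0, 3), c(4, 2))
  expect_equal(collapse_2x2(tab0, 1, 1)[1], 0L)
})

test_that("exact_cell_test matches closed forms and conventions", {
  ct <- exact_cell_test(3, 0, 0, 3)
  expect_equal(ct$p_type, 1 / choose(6, 3))       # = 0.05 exactly
  expect_identical(ct$odds_ratio, Inf)
  expect_equal(ct$classification, "none")         # strict p < alpha
  expect_false(is.na(ct$odds_ratio_haldane))

  ct2 <- exact_cell_test(10, 5, 5, 10)
  expect_equal(ct2$odds_ratio, 4.0)
  expect_true(is.na(ct2$odds_ratio_haldane))
  expect_error(exact_cell_test(0, 0, 0, 0), "all-zero")
})

test_that("p values are invariant under row/column swaps, OR maps to its inverse", {
  set.seed(32)
  for (r in 1:20) {
    cell <- rpois(4, 4)
    if (sum(cell) == 0) next
    a <- cell[1]; b <- cell[2]; c <- cell[3]; d <- cell[4]
    t1 <- exact_cell_test(a, b, c, d)
    t2 <- exact_cell_test(d, c, b, a)        # swap both rows and columns
    expect_equal(t1$p_type, t2$p_type, tolerance = 1e-12)
    expect_equal(t1$p_antitype, t2$p_antitype, tolerance = 1e-12)
    t3 <- exact_cell_test(b, a, d, c)        # swap columns only
    if (is.finite(t1$odds_ratio) && t1$odds_ratio > 0)
      expect_equal(t3$odds_ratio, 1 / t1$odds_ratio)
  }
})

test_that("both one-sided p values exceed one when summed (shared point mass)", {
  set.seed(33)
  for (r in 1:20) {
    cell <- rpois(4, 3)
    if (sum(cell) == 0) next
    ct <- exact_cell_test(cell[1], cell[2], cell[3], cell[4])
    expect_gte(ct$p_type + ct$p_antitype, 1 - 1e-12)
  }
})

test_that("an exactly independent table classifies nothing", {
  tab <- outer(c(20, 40), c(30, 30)) / 60   # rank-1, N = 60
  rep <- scan_types(tab)
  expect_equal(rep$cells$observed, as.vector(sapply(1:2, function(j) tab[, j])))
  expect_equal(rep$cells$expected, rep$cells$observed)
  expect_true(all(rep$cells$classification == "none"))
})

test_that("scan_types finds diagonal types when everyone stays", {
  ids <- sprintf("p%03d", 1:120)
  stay <- setNames(rep(1:4, each = 30), ids)
  rep <- scan_types(transition_table(stay, stay))
  diag_cells <- rep$cells$from == rep$cells$to
  expect_true(all(rep$cells$classification[diag_cells] == "type"))
  expect_true(all(rep$cells$classification[!diag_cells] == "antitype"))
  expect_equal(nrow(rep$zero_paths), 12)
})

test_that("multiplicity corrections only prune classifications", {
  set.seed(34)
  ids <- sprintf("p%03d", 1:120)
  a <- setNames(sample(1:4, 120, TRUE), ids)
  b <- setNames(ifelse(runif(120) < 0.5, a, sample(1:4, 120, TRUE)), ids)
  tab <- transition_table(a, b)
  plain <- scan_types(tab, correction = "none")
  holm <- scan_types(tab, correction = "holm")
  bonf <- scan_types(tab, correction = "bonferroni")
  sig <- function(r) which(r$cells$classification != "none")
  expect_true(all(sig(holm) %in% sig(plain)))
  expect_true(all(sig(bonf) %in% sig(holm)))
})
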