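#' Cross-tabulate memberships across adjacent occasions
#'
#' Counts persons over the inner join of the two assignment vectors
#' (persons present at both occasions); margins equal cluster sizes among
#' the joined persons. The column mapping may be the next timepoint's
#' clusters or a developmental outcome.
#'
#' @param assign_from named vector (person -> cluster) at the earlier
#'   occasion.
#' @param assign_to named vector (person -> cluster or outcome level).
#' @param levels_from,levels_to category sets used to pad the table
#'   (default: sorted unique values of each full vector).
#' @return integer matrix of counts with category dimnames.
#' @export
transition_table <- function(assign_from, assign_to,
                             levels_from = NULL, levels_to = NULL) {
  if (is.null(names(assign_from)) || is.null(names(assign_to)))
    stop("assignment vectors must be named by person id")
  common <- intersect(names(assign_from), names(assign_to))
  if (!length(common)) stop("no persons present at both occasions")
  if (is.null(levels_from)) levels_from <- sort(unique(assign_from))
  if (is.null(levels_to)) levels_to <- sort(unique(assign_to))
  tab <- table(factor(assign_from[common], levels = levels_from),
               factor(assign_to[common], levels = levels_to))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c("from", "to")
  m
}

#' Collapse one cell of a transition table to a 2x2 table
#'
#' For cell (i, j): `a` = count in the cell, `b` = rest of row i, `c` =
#' rest of column j, `d` = everything else; a + b + c + d = N.
#'
#' @param tab counts matrix from [transition_table()].
#' @param i,j row and column index of the cell.
#' @return integer vector `c(a, b, c, d)`.
#' @export
collapse_2x2 <- function(tab, i, j) {
  stopifnot(is.matrix(tab), i >= 1, i <= nrow(tab), j >= 1, j <= ncol(tab))
  a <- tab[i, j]
  b <- sum(tab[i, ]) - a
  cc <- sum(tab[, j]) - a
  d <- sum(tab) - a - b - cc
  as.integer(c(a = a, b = b, c = cc, d = d))
}

#' Exact hypergeometric test of one transition cell
#'
#' With all margins of the collapsed 2x2 table fixed, the cell count
#' follows the hypergeometric law
#' P(X = x) = C(a+b, x) C(c+d, (a+c) - x) / C(N, a+c).
#' The upper tail P(X >= a) supports a developmental type (the path is
#' followed more often than independence predicts), the lower tail
#' P(X <= a) an antitype; both are one-sided and share the observed
#' point mass. The odds ratio ad/bc quantifies how strongly the path is
#' enriched or depleted; zero cells give exact 0 or +Inf, with a
#' Haldane-Anscombe (+0.5) estimate reported alongside in that case.
#'
#' @param a,b,c,d nonnegative integer cells of the collapsed table.
#' @param alpha per-cell significance level (strict `p < alpha`).
#' @return An object of class `cell_test`: `observed`, `expected`,
#'   `p_type`, `p_antitype`, `odds_ratio`, `odds_ratio_haldane` (`NA`
#'   unless a zero cell made the plain OR degenerate), `classification`
#'   (`"type"`, `"antitype"` or `"none"`).
#' @export
exact_cell_test <- function(a, b, c, d, alpha = 0.05) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  n <- sum(cells)
  if (n == 0) stop("all-zero table")
  expected <- (a + b) * (a + c) / n
  p_type <- phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  p_antitype <- phyper(a, a + b, c + d, a + c)
  or <- if (b * c > 0) (a * d) / (b * c)
        else if (a * d > 0) Inf
        else NaN
  or_h <- if (b * c == 0 || a * d == 0)
    (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)) else NA_real_
  classification <- if (p_type < alpha && a > expected) "type"
    else if (p_antitype < alpha && a < expected) "antitype"
    else "none"
  structure(list(observed = as.integer(a), expected = expected,
                 p_type = p_type, p_antitype = p_antitype,
                 odds_ratio = or, odds_ratio_haldane = or_h,
                 classification = classification, alpha = alpha,
                 table = setNames(as.integer(cells), c("a", "b", "c", "d"))),
            class = "cell_test")
}

#' Scan a transition table for developmental types and antitypes
#'
#' Tests every cell of the k x m table with the exact hypergeometric
#' test. By default each cell is judged at the nominal level with no
#' multiplicity correction; Holm or Bonferroni adjustment (applied to the
#' upper-tail p values across cells for type calls and to the lower-tail
#' p values for antitype calls) is available. Paths with zero observed
#' transitions are surfaced explicitly.
#'
#' @param tab counts matrix from [transition_table()].
#' @param alpha per-cell significance level.
#' @param correction `"none"`, `"holm"` or `"bonferroni"`.
#' @return An object of class `transition_report`: `table`, `cells`
#'   (data frame with from, to, observed, expected, p values, odds
#'   ratios, classification), `zero_paths`, `alpha`, `correction`, `n`.
#' @export
scan_types <- function(tab, alpha = 0.05,
                       correction = c("none", "holm", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(is.matrix(tab))
  idx <- expand.grid(i = seq_len(nrow(tab)), j = seq_len(ncol(tab)))
  tests <- lapply(seq_len(nrow(idx)), function(r) {
    cell <- collapse_2x2(tab, idx$i[r], idx$j[r])
    exact_cell_test(cell[1L], cell[2L], cell[3L], cell[4L], alpha = alpha)
  })
  p_type <- p.adjust(vapply(tests, `[[`, numeric(1), "p_type"),
                     method = correction)
  p_anti <- p.adjust(vapply(tests, `[[`, numeric(1), "p_antitype"),
                     method = correction)
  expected <- vapply(tests, `[[`, numeric(1), "expected")
  observed <- vapply(tests, `[[`, integer(1), "observed")
  classification <- ifelse(p_type < alpha & observed > expected, "type",
                    ifelse(p_anti < alpha & observed < expected,
                           "antitype", "none"))
  from_lab <- rownames(tab) %||% as.character(seq_len(nrow(tab)))
  to_lab <- colnames(tab) %||% as.character(seq_len(ncol(tab)))
  cells <- data.frame(
    from = from_lab[idx$i], to = to_lab[idx$j],
    observed = observed, expected = expected,
    p_type = p_type, p_antitype = p_anti,
    odds_ratio = vapply(tests, `[[`, numeric(1), "odds_ratio"),
    odds_ratio_haldane = vapply(tests, `[[`, numeric(1),
                                "odds_ratio_haldane"),
    classification = classification,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, cells = cells,
                 zero_paths = cells[cells$observed == 0L,
                                    c("from", "to"), drop = FALSE],
                 alpha = alpha, correction = correction, n = sum(tab)),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("transition report: N = %d, alpha = %g, correction = %s\n",
              x$n, x$alpha, x$correction))
  sig <- x$cells[x$cells$classification != "none", , drop = FALSE]
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig)))
      cat(sprintf("  %s: %s -> %s, obs %d vs exp %.1f, OR = %.2g\n",
                  sig$classification[r], sig$from[r], sig$to[r],
                  sig$observed[r], sig$expected[r], sig$odds_ratio[r]))
  } else cat("  no types or antitypes\n")
  if (nrow(x$zero_paths))
    cat("  zero-transition paths:",
        paste(x$zero_paths$from, x$zero_paths$to, sep = "->",
              collapse = ", "), "\n")
  invisible(x)
}
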