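# Independent oracles used to cross-check the package implementations.
# They are deliberately naive (brute force / closed form) and share no
# code with the functions they check.

# greedy minimal-ESS-increment agglomeration by exhaustive pair scan
oracle_ward <- function(x) {
  n <- nrow(x)
  members <- as.list(seq_len(n))
  cent <- x
  size <- rep(1L, n)
  active <- seq_len(n)
  merges <- list()
  inc <- numeric(0)
  while (length(active) > 1L) {
    best <- NULL; bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1L)) {
      a <- active[jj]; b <- active[ii]
      d <- size[a] * size[b] / (size[a] + size[b]) *
        sum((cent[a, ] - cent[b, ])^2)
      if (d < bestd - 1e-12) { bestd <- d; best <- c(a, b) }
    }
    a <- best[1L]; b <- best[2L]
    merges[[length(merges) + 1L]] <- sort(c(members[[a]], members[[b]]))
    inc <- c(inc, bestd)
    cent[a, ] <- (size[a] * cent[a, ] + size[b] * cent[b, ]) /
      (size[a] + size[b])
    members[[a]] <- c(members[[a]], members[[b]])
    size[a] <- size[a] + size[b]
    active <- setdiff(active, b)
  }
  list(merges = merges, increments = inc)
}

# member sets merged at each stage of a ward_tree (hclust merge matrix)
tree_merge_sets <- function(tree) {
  out <- list()
  for (s in seq_len(tree$n_leaves - 1L)) {
    get <- function(v) if (v < 0) -v else out[[v]]
    out[[s]] <- sort(c(get(tree$merge[s, 1L]), get(tree$merge[s, 2L])))
  }
  out
}

# exhaustive hypergeometric tail by direct enumeration with choose()
oracle_tail_p <- function(a, b, c, d, upper = TRUE) {
  n <- a + b + c + d
  r1 <- a + b
  k <- a + c
  lo <- max(0L, k - (c + d))
  hi <- min(r1, k)
  xs <- if (upper) a:hi else lo:a
  sum(exp(lchoose(r1, xs) + lchoose(n - r1, k - xs) - lchoose(n, k)))
}

# brute-force residue flags by a double loop over persons
oracle_residues <- function(x, T_dist, K) {
  n <- nrow(x)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      if (mean((x[i, ] - x[j, ])^2) <= T_dist) cnt <- cnt + 1L
    }
    flagged[i] <- cnt < K
  }
  flagged
}

# adjusted Rand index between two labelings (contingency closed form)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  tot <- choose(length(a), 2)
  exp_idx <- si * sj / tot
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# planted 4-cluster benchmark: equidistant centroids at a given averaged
# squared Euclidean separation, unit within-cluster sd
make_planted <- function(seed, n = 120, k = 4, p = 4, separation = 2,
                         within_sd = 1) {
  set.seed(seed)
  cent <- planted_centroids(k, p, separation)
  z <- sample(rep(seq_len(k), length.out = n))
  x <- cent[z, , drop = FALSE] +
    matrix(rnorm(n * p, sd = within_sd), n, p)
  rownames(x) <- sprintf("P%03d", seq_len(n))
  list(x = x, z = z, centroids = cent)
}
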