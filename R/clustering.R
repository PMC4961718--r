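#' Ward agglomeration of person profiles
#'
#' Hierarchical clustering by Ward's minimum-variance method on squared
#' Euclidean distances: at every stage the pair of clusters whose fusion
#' least increases the total within-cluster error sum of squares (ESS) is
#' merged. Fusion coefficients are reported both as per-merge ESS
#' increments and as the cumulative total ESS after each merge; Ward
#' guarantees the increment series is non-decreasing.
#'
#' @param x numeric matrix (persons x factors), no missing values.
#' @return An object of class `ward_tree`: `merge` (hclust convention),
#'   `increments` (ESS increase per merge), `coefficients` (total ESS
#'   after each merge), `n_leaves`, `labels`, and the underlying `hclust`
#'   object.
#' @export
ward_tree <- function(x) {
  stopifnot(is.matrix(x), !anyNA(x))
  if (nrow(x) < 2L) stop("need at least 2 persons")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  hc <- hclust(dist(x)^2, method = "ward.D")
  inc <- hc$height / 2          # ward.D heights are twice the ESS increment
  structure(list(merge = hc$merge, increments = inc,
                 coefficients = cumsum(inc), n_leaves = nrow(x),
                 labels = rownames(x), hclust = hc),
            class = "ward_tree")
}

#' Cut a Ward tree into k clusters
#'
#' @param tree a [ward_tree()].
#' @param k number of clusters.
#' @return named integer vector of cluster labels (1..k) per person.
#' @export
cut_ward <- function(tree, k) {
  stopifnot(inherits(tree, "ward_tree"), k >= 1, k <= tree$n_leaves)
  cutree(tree$hclust, k = k)
}

#' Mojena stopping rule
#'
#' Standardizes the fusion-coefficient series of an agglomerative
#' clustering and flags the first merge (in merge order, i.e. scanning
#' from many clusters towards few) whose standardized value exceeds
#' `mean + c * sd`; the suggested solution is the number of clusters
#' present just before that merge. The default series is the per-merge
#' ESS increment (the dendrogram fusion heights); `series =
#' "cumulative"` standardizes the running total ESS instead.
#'
#' @param tree a [ward_tree()], or a raw numeric fusion series.
#' @param c threshold in standard deviations (default 2.75).
#' @param series `"increment"` or `"cumulative"`.
#' @return list with `k` (suggested clusters, `NA` if no stage is
#'   flagged), `stage` (index of the flagged merge), `z` (standardized
#'   series) and `flagged` (logical per stage).
#' @export
mojena_suggest <- function(tree, c = 2.75,
                           series = c("increment", "cumulative")) {
  series <- match.arg(series)
  s <- if (inherits(tree, "ward_tree")) {
    if (series == "increment") tree$increments else tree$coefficients
  } else as.numeric(tree)
  if (length(s) < 3L) stop("need at least 3 fusion stages")
  sdev <- sd(s)
  if (!is.finite(sdev) || sdev == 0)
    return(list(k = NA_integer_, stage = NA_integer_,
                z = rep(0, length(s)), flagged = rep(FALSE, length(s))))
  z <- (s - mean(s)) / sdev
  flagged <- z > c
  stage <- which(flagged)[1L]
  n <- length(s) + 1L
  k <- if (is.na(stage)) NA_integer_ else n - stage + 1L
  list(k = k, stage = stage, z = z, flagged = flagged)
}

#' Explained error sum of squares of a partition
#'
#' 100 * (1 - SS_within / SS_total), the share of the total squared
#' deviation about the grand centroid that the cluster solution accounts
#' for. Singleton-only partitions reach 100; the one-cluster partition
#' scores 0.
#'
#' @param x numeric matrix (persons x factors).
#' @param assignments integer cluster labels per row.
#' @return percentage in `[0, 100]`.
#' @export
eess <- function(x, assignments) {
  stopifnot(is.matrix(x), length(assignments) == nrow(x))
  if (length(unique(assignments)) < 1L) stop("empty partition")
  ss_total <- sum(sweep(x, 2L, colMeans(x))^2)
  if (ss_total == 0) return(100)
  100 * (1 - ss_within(x, assignments) / ss_total)
}

ss_within <- function(x, assignments) {
  sum(vapply(split(seq_len(nrow(x)), assignments), function(i) {
    xi <- x[i, , drop = FALSE]
    sum(sweep(xi, 2L, colMeans(xi))^2)
  }, numeric(1)))
}

cluster_centroids <- function(x, assignments, k = max(assignments)) {
  cent <- matrix(NA_real_, k, ncol(x),
                 dimnames = list(NULL, colnames(x)))
  for (cl in seq_len(k)) {
    i <- which(assignments == cl)
    if (length(i)) cent[cl, ] <- colMeans(x[i, , drop = FALSE])
  }
  cent
}

#' Within-cluster homogeneity table
#'
#' For every cluster x factor cell, the ratio of the within-cluster
#' variance of that factor to its total variance. Homogeneous solutions
#' have few cells above 1; solutions with the smallest count of ratios
#' > 1 are favored. Singleton clusters have ratio 0.
#'
#' @param x numeric matrix (persons x factors).
#' @param assignments integer cluster labels per row.
#' @return list with `count` (cells with ratio > 1) and `table`
#'   (clusters x factors ratio matrix).
#' @export
homogeneity_f_count <- function(x, assignments) {
  stopifnot(is.matrix(x), length(assignments) == nrow(x))
  tot <- apply(x, 2L, var)
  k <- max(assignments)
  tab <- matrix(0, k, ncol(x),
                dimnames = list(paste0("cluster", seq_len(k)), colnames(x)))
  for (cl in seq_len(k)) {
    i <- which(assignments == cl)
    if (length(i) > 1L)
      tab[cl, ] <- apply(x[i, , drop = FALSE], 2L, var) / tot
  }
  list(count = sum(tab > 1), table = tab)
}

#' k-means relocation of a cluster solution
#'
#' Iteratively reassigns every person to the nearest cluster centroid
#' (squared Euclidean distance) and recomputes the centroids, starting
#' from an initial partition (typically a Ward cut), until no person
#' moves. The within-cluster sum of squares never increases. A cluster
#' emptied by reassignment is re-seeded with the person farthest from
#' their current centroid.
#'
#' @param x numeric matrix (persons x factors) with person ids as row
#'   names.
#' @param assignments initial integer cluster labels per row.
#' @param timepoint timepoint label carried into the solution.
#' @param max_iter iteration cap.
#' @param name_threshold |z| threshold for descriptive cluster names.
#' @return A `cluster_solution`: `timepoint`, `k`, `assignments` (named),
#'   `centroids`, `sizes`, `eess_percent`, `f_count`, `f_table`, `names`,
#'   `ss_within`, `iterations`.
#' @export
relocate <- function(x, assignments, timepoint = NA_integer_,
                     max_iter = 100L, name_threshold = 0.5) {
  stopifnot(is.matrix(x), length(assignments) == nrow(x))
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  k <- max(assignments)
  assign <- as.integer(assignments)
  for (it in seq_len(max_iter)) {
    cent <- cluster_centroids(x, assign, k)
    # squared distance of every person to every centroid
    d2 <- outer(rowSums(x^2), rowSums(cent^2, na.rm = TRUE), "+") -
      2 * tcrossprod(x, cent)
    d2[, is.na(cent[, 1L])] <- Inf
    new_assign <- max.col(-d2, ties.method = "first")
    # re-seed emptied clusters with the worst-fitted person
    for (cl in which(tabulate(new_assign, k) == 0L)) {
      fit <- d2[cbind(seq_len(nrow(x)), new_assign)]
      new_assign[which.max(fit)] <- cl
      d2[which.max(fit), ] <- -Inf   # freeze this person for this sweep
    }
    if (all(new_assign == assign)) break
    assign <- new_assign
    if (it == max_iter)
      stop("relocation did not converge in ", max_iter, " iterations")
  }
  cluster_solution(x, assign, timepoint = timepoint,
                   name_threshold = name_threshold, iterations = it)
}

#' Assemble a cluster solution from data and assignments
#'
#' @inheritParams relocate
#' @param iterations bookkeeping from the relocation loop.
#' @return A `cluster_solution` (see [relocate()]).
#' @export
cluster_solution <- function(x, assignments, timepoint = NA_integer_,
                             name_threshold = 0.5, iterations = 0L) {
  k <- max(assignments)
  cent <- cluster_centroids(x, assignments, k)
  hf <- homogeneity_f_count(x, assignments)
  nms <- lapply(seq_len(k), function(cl)
    name_cluster(cent[cl, ], threshold = name_threshold))
  structure(list(timepoint = timepoint, k = k,
                 assignments = setNames(as.integer(assignments), rownames(x)),
                 centroids = cent,
                 sizes = tabulate(assignments, k),
                 eess_percent = eess(x, assignments),
                 f_count = hf$count, f_table = hf$table, names = nms,
                 ss_within = ss_within(x, assignments),
                 iterations = iterations),
            class = "cluster_solution")
}

#' Cluster-solution diagnostics over a range of k
#'
#' Builds one Ward tree, and for every candidate k relocates the Ward cut
#' and reports EESS, the homogeneity count, the Mojena flag and an elbow
#' score (relative drop in within-cluster SS from k - 1 to k). The
#' default pick is the Mojena suggestion; if the rule flags nothing (or
#' suggests a k outside the candidate set) the pick falls back to the
#' smallest homogeneity count, ties broken by the largest EESS, and is
#' marked low-confidence. The pick is a reproducible default, not a
#' substitute for judging interpretability.
#'
#' @param x numeric matrix (persons x factors).
#' @param k_candidates integer vector of candidate cluster numbers.
#' @param c_mojena Mojena threshold.
#' @param timepoint label carried into the solutions.
#' @param name_threshold |z| threshold for cluster names.
#' @return list with `diagnostics` (data frame: k, eess_percent, f_count,
#'   mojena_flagged, elbow_drop), `pick`, `low_confidence`, `solutions`
#'   (list of `cluster_solution` keyed by k), `mojena` and `tree`.
#' @export
select_solution <- function(x, k_candidates = 2:8, c_mojena = 2.75,
                            timepoint = NA_integer_, name_threshold = 0.5) {
  stopifnot(length(k_candidates) >= 1)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  tree <- ward_tree(x)
  moj <- mojena_suggest(tree, c = c_mojena)
  sols <- lapply(k_candidates, function(k)
    relocate(x, cut_ward(tree, k), timepoint = timepoint,
             name_threshold = name_threshold))
  names(sols) <- as.character(k_candidates)
  ssw <- vapply(sols, `[[`, numeric(1), "ss_within")
  ssw_prev <- vapply(k_candidates - 1L, function(k)
    if (k >= 1L) ss_within(x, cut_ward(tree, k)) else NA_real_, numeric(1))
  diagnostics <- data.frame(
    k = k_candidates,
    eess_percent = vapply(sols, `[[`, numeric(1), "eess_percent"),
    f_count = vapply(sols, `[[`, numeric(1), "f_count"),
    mojena_flagged = k_candidates == (moj$k %||% -1L),
    elbow_drop = (ssw_prev - ssw) / ssw_prev,
    row.names = NULL
  )
  low_confidence <- FALSE
  if (!is.na(moj$k) && moj$k %in% k_candidates) {
    pick <- moj$k
  } else {
    ord <- order(diagnostics$f_count, -diagnostics$eess_percent)
    pick <- k_candidates[ord[1L]]
    low_confidence <- TRUE
  }
  list(diagnostics = diagnostics, pick = pick,
       low_confidence = low_confidence, solutions = sols, mojena = moj,
       tree = tree)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution (t%s): k = %d, EESS = %.1f%%, F>1 cells = %d\n",
              x$timepoint, x$k, x$eess_percent, x$f_count))
  for (cl in seq_len(x$k)) {
    nm <- x$names[[cl]]
    lab <- if (nrow(nm)) paste(sprintf("%s %s", nm$factor, nm$direction),
                               collapse = ", ") else "(no salient factor)"
    cat(sprintf("  %d (n=%d): %s\n", cl, x$sizes[cl], lab))
  }
  invisible(x)
}
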