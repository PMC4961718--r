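#' Centroid distances between two cluster solutions
#'
#' Entry (i, j) is the averaged squared Euclidean distance between
#' centroid i of the first solution and centroid j of the second, on the
#' same scale as the residue threshold.
#'
#' @param sol_a,sol_b `cluster_solution` objects (or bare centroid
#'   matrices) over the same factor space.
#' @return k_a x k_b numeric matrix.
#' @export
centroid_distances <- function(sol_a, sol_b) {
  ca <- if (inherits(sol_a, "cluster_solution")) sol_a$centroids else sol_a
  cb <- if (inherits(sol_b, "cluster_solution")) sol_b$centroids else sol_b
  if (ncol(ca) != ncol(cb)) stop("centroid dimensions differ")
  d <- matrix(NA_real_, nrow(ca), nrow(cb),
              dimnames = list(paste0("a", seq_len(nrow(ca))),
                              paste0("b", seq_len(nrow(cb)))))
  for (i in seq_len(nrow(ca)))
    for (j in seq_len(nrow(cb)))
      d[i, j] <- profile_distance(ca[i, ], cb[j, ])
  d
}

# all injections of the smaller index set into the larger (for the
# exhaustive assignment cross-check)
all_pairings <- function(nr, nc) {
  small <- min(nr, nc); large <- max(nr, nc)
  perms <- function(v, m) {
    if (m == 0L) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i], m - 1L))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  perms(seq_len(large), small)
}

#' Pair clusters across timepoints by increasing centroid distance
#'
#' Greedy matching that mirrors arranging the clusters in pairs by
#' increasing value: the globally smallest remaining distance whose row
#' and column are both unused is taken repeatedly. Leftover clusters
#' (when the solutions differ in k, i.e. a profile emerged or vanished)
#' are listed as unmatched. For up to 6 clusters per side the greedy
#' pairing is cross-checked against the exhaustive minimum-total-distance
#' assignment, and a discrepancy is reported via `optimal_differs` --
#' never silently.
#'
#' @param d distance matrix from [centroid_distances()].
#' @param check_optimal run the exhaustive cross-check (default `TRUE`
#'   when feasible).
#' @return An object of class `stability_match`: `pairing` (data frame
#'   `cluster_a`, `cluster_b`, `distance`, sorted ascending),
#'   `unmatched_a`, `unmatched_b`, `optimal_differs`, `distance_matrix`.
#' @export
pair_by_distance <- function(d, check_optimal = TRUE) {
  stopifnot(is.matrix(d), nrow(d) >= 1, ncol(d) >= 1)
  dd <- d
  pairs <- data.frame(cluster_a = integer(0), cluster_b = integer(0),
                      distance = numeric(0))
  while (any(is.finite(dd))) {
    ij <- arrayInd(which.min(dd), dim(dd))
    pairs <- rbind(pairs, data.frame(cluster_a = ij[1L], cluster_b = ij[2L],
                                     distance = d[ij[1L], ij[2L]]))
    dd[ij[1L], ] <- Inf
    dd[, ij[2L]] <- Inf
  }
  optimal_differs <- FALSE
  if (check_optimal && max(dim(d)) <= 6L) {
    byrow <- nrow(d) <= ncol(d)
    small <- min(dim(d))
    best <- Inf; best_inj <- NULL
    for (inj in all_pairings(nrow(d), ncol(d))) {
      tot <- sum(if (byrow) d[cbind(seq_len(small), inj)]
                 else d[cbind(inj, seq_len(small))])
      if (tot < best) { best <- tot; best_inj <- inj }
    }
    greedy_tot <- sum(pairs$distance)
    if (greedy_tot > best + 1e-12) {
      opt <- if (byrow)
        data.frame(cluster_a = seq_len(small), cluster_b = best_inj)
      else
        data.frame(cluster_a = best_inj, cluster_b = seq_len(small))
      optimal_differs <- !all(paste(pairs$cluster_a, pairs$cluster_b) %in%
                              paste(opt$cluster_a, opt$cluster_b))
    }
  }
  structure(list(pairing = pairs,
                 unmatched_a = setdiff(seq_len(nrow(d)), pairs$cluster_a),
                 unmatched_b = setdiff(seq_len(ncol(d)), pairs$cluster_b),
                 optimal_differs = optimal_differs,
                 distance_matrix = d),
            class = "stability_match")
}

#' Descriptive name of a cluster from its centroid
#'
#' Only operating factors with |z| strictly greater than the threshold
#' take part in naming; they are reported with their direction (above or
#' below the sample average) in order of decreasing salience.
#'
#' @param centroid numeric vector of factor z-scores (named, or taken in
#'   the canonical factor order).
#' @param threshold salience cutoff on |z| (default 0.5, strict).
#' @return data frame with columns `factor`, `direction`, `z`, ordered by
#'   decreasing |z|; zero rows when no factor is salient.
#' @export
name_cluster <- function(centroid, threshold = 0.5) {
  nms <- names(centroid)
  if (is.null(nms)) nms <- FACTOR_NAMES[seq_along(centroid)]
  sel <- which(abs(centroid) > threshold)
  sel <- sel[order(-abs(centroid[sel]))]
  data.frame(factor = nms[sel],
             direction = ifelse(centroid[sel] > 0, "above", "below"),
             z = as.numeric(centroid[sel]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.stability_match <- function(x, ...) {
  cat("structural stability pairing (ascending centroid distance):\n")
  print(x$pairing, row.names = FALSE)
  if (length(x$unmatched_a))
    cat("  unmatched in first solution:",
        paste(x$unmatched_a, collapse = ", "), "\n")
  if (length(x$unmatched_b))
    cat("  unmatched in second solution:",
        paste(x$unmatched_b, collapse = ", "), "\n")
  if (x$optimal_differs)
    cat("  note: greedy pairing differs from the optimal assignment\n")
  invisible(x)
}
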