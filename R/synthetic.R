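# Table-style anchors (mean, sd) per raw measure and timepoint used by
# raw mode to map planted factor z-scores back to test-score scales.
RAW_ANCHORS <- list(
  net_hope         = cbind(mean = c(1.86, 1.81, 1.94),
                           sd   = c(0.81, 0.83, 0.72)),
  dribbling        = cbind(mean = c(10.71, 10.14, 10.20),
                           sd   = c(0.87, 0.87, 0.68)),
  ball_control     = cbind(mean = c(19.66, 17.87, 15.78),
                           sd   = c(3.54, 3.56, 1.44)),
  juggling         = cbind(mean = c(2.75, 5.28, 8.04),
                           sd   = c(3.20, 6.46, 6.98)),
  sprint_40m       = cbind(mean = c(6.64, 6.43, 6.21),
                           sd   = c(0.33, 0.30, 0.44)),
  yoyo_ir1         = cbind(mean = c(865.67, 1087.57, 1330.33),
                           sd   = c(284.81, 387.43, 456.79)),
  cmj              = cbind(mean = c(28.83, 30.60, 30.56),
                           sd   = c(3.73, 3.76, 3.80)),
  pct_adult_height = cbind(mean = c(84.34, 87.54, 92.48),
                           sd   = c(1.69, 2.48, 3.03))
)

# default centroid profiles (clusters x factors), magnitudes on the scale
# of published z-score cluster profiles
default_centroids <- function() {
  m <- rbind(
    c(-1.5, -0.6,  0.2,  0.3),   # failure-fearing
    c( 1.0, -0.5, -1.2, -0.7),   # unfit but success-oriented
    c( 0.8,  1.2,  0.4, -0.8),   # highly skilled, late developer
    c( 0.2, -0.4,  1.2,  1.3))   # fit, early matured
  colnames(m) <- FACTOR_NAMES
  m
}

#' Regular-simplex centroids at a given separation
#'
#' Builds `k` cluster centroids in `p` dimensions that are pairwise
#' equidistant, scaled so that every pairwise averaged squared Euclidean
#' distance equals `separation` (the same units as the residue threshold
#' and the structural-stability distances).
#'
#' @param k number of clusters (k - 1 <= p).
#' @param p number of factors.
#' @param separation pairwise averaged squared Euclidean distance.
#' @return k x p centroid matrix, centered at the origin.
#' @export
planted_centroids <- function(k = 4L, p = 4L, separation = 2) {
  stopifnot(k >= 2, p >= k - 1, separation > 0)
  cent <- diag(k)
  cent <- cent - matrix(colMeans(cent), k, k, byrow = TRUE)
  # unit vectors pairwise distance sqrt(2); scale to Euclidean sqrt(sep * p)
  cent <- cent / sqrt(2) * sqrt(separation * p)
  out <- cbind(cent, matrix(0, k, max(0L, p - k)))[, seq_len(p), drop = FALSE]
  colnames(out) <- if (p == length(FACTOR_NAMES)) FACTOR_NAMES else
    paste0("factor", seq_len(p))
  out
}

#' Synthetic-panel generator configuration
#'
#' Defaults emulate the study conditions the analysis assumes: 120
#' persons followed over 3 annual timepoints, 4 latent profile clusters
#' with diagonal-dominant year-to-year transitions, an ordinal outcome
#' (0/1/2) whose distribution depends on the final-timepoint cluster,
#' 18% cell-wise MCAR missingness, and 4 extreme-profile outliers placed
#' at magnitude 3 on two factors each.
#'
#' @param n_persons,n_timepoints,n_clusters panel dimensions.
#' @param centroids k x 4 matrix, or list of one matrix per timepoint.
#' @param within_sd within-cluster factor standard deviation.
#' @param transition_matrix k x k row-stochastic matrix (or list per
#'   adjacent pair of timepoints).
#' @param init_probs length-k initial cluster distribution (default
#'   uniform).
#' @param outcome_probs k x L row-stochastic matrix: final-timepoint
#'   cluster -> outcome level probabilities.
#' @param missing_rate cell-wise MCAR probability, in `[0, 0.5)`.
#' @param n_outliers persons overwritten with extreme profiles.
#' @param outlier_magnitude |z| at which two factors of each outlier are
#'   planted (below average).
#' @param seed integer RNG seed.
#' @param raw_mode emit raw test scores (a [raw_panel()]) instead of
#'   factor scores.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_persons = 120L, n_timepoints = 3L,
                             n_clusters = 4L, centroids = NULL,
                             within_sd = 1.0, transition_matrix = NULL,
                             init_probs = NULL, outcome_probs = NULL,
                             missing_rate = 0.18, n_outliers = 4L,
                             outlier_magnitude = 3.0, seed = 1L,
                             raw_mode = FALSE) {
  k <- as.integer(n_clusters)
  if (k > n_persons) stop("more clusters than persons")
  if (is.null(centroids)) centroids <- default_centroids()[seq_len(min(k, 4L)), , drop = FALSE]
  if (!is.list(centroids)) centroids <- rep(list(centroids), n_timepoints)
  if (length(centroids) != n_timepoints)
    stop("need one centroid matrix per timepoint")
  if (any(vapply(centroids, nrow, integer(1)) != k))
    stop("centroid matrices must have n_clusters rows")
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(0.45 / max(1L, k - 1L), k, k)
    diag(transition_matrix) <- if (k > 1L) 0.55 else 1
  }
  if (is.null(init_probs)) init_probs <- rep(1 / k, k)
  if (is.null(outcome_probs)) {
    outcome_probs <- if (k == 4L) rbind(
      c(0.80, 0.18, 0.02),    # failure-fearing: mostly no card
      c(0.75, 0.23, 0.02),    # unfit success-oriented
      c(0.35, 0.35, 0.30),    # highly skilled: enriched top level
      c(0.45, 0.45, 0.10))    # fit early matured: enriched middle level
    else matrix(1 / 3, k, 3)
  }
  stopifnot(abs(sum(init_probs) - 1) < 1e-12,
            all(abs(rowSums(transition_matrix) - 1) < 1e-12),
            all(abs(rowSums(outcome_probs) - 1) < 1e-12),
            missing_rate >= 0, missing_rate < 0.5,
            within_sd >= 0, n_outliers >= 0, outlier_magnitude >= 0)
  structure(list(n_persons = as.integer(n_persons),
                 n_timepoints = as.integer(n_timepoints),
                 n_clusters = k, centroids = centroids,
                 within_sd = within_sd,
                 transition_matrix = transition_matrix,
                 init_probs = init_probs, outcome_probs = outcome_probs,
                 missing_rate = missing_rate,
                 n_outliers = as.integer(n_outliers),
                 outlier_magnitude = outlier_magnitude,
                 seed = as.integer(seed), raw_mode = isTRUE(raw_mode)),
            class = "generator_config")
}

#' Generate a synthetic longitudinal panel with ground truth
#'
#' Persons draw an initial cluster from `init_probs`, evolve by the
#' transition matrix, and emit factor vectors equal to their cluster
#' centroid plus spherical Gaussian noise. The outcome is drawn from the
#' final-timepoint cluster's row of `outcome_probs`. Outlier persons are
#' overwritten at every timepoint with a discordant extreme profile: a
#' distinct factor pair per outlier at `-outlier_magnitude`, the
#' remaining factors at `+outlier_magnitude`, so the profile is unlike
#' any cluster by construction. The MCAR mask is
#' applied cell-wise to the factor cells (factor mode) or per measure --
#' a missed test loses all its attempts -- so the share of missing
#' analysis cells matches `missing_rate` in both modes. In raw mode the
#' factors are mapped back to test
#' scales through published mean/sd anchors, with two attempts emitted
#' for the twice-administered tests so that preprocessing exercises the
#' best-attempt logic; hope/fear scale means reproduce net hope exactly
#' (hs - ff = NH) around a bounded shared shift so the pair is not
#' collinear.
#'
#' @param cfg a [generator_config()].
#' @return list with `panel` (a [factor_panel()] or [raw_panel()]) and
#'   `truth` (class `synthetic_truth`: `cluster_path` matrix persons x
#'   timepoints, `outcome`, `outlier_ids`, `config`).
#' @export
generate_panel <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_persons; tt <- cfg$n_timepoints; k <- cfg$n_clusters
  ids <- sprintf("P%03d", seq_len(n))

  path <- matrix(NA_integer_, n, tt, dimnames = list(ids, NULL))
  path[, 1L] <- sample.int(k, n, replace = TRUE, prob = cfg$init_probs)
  if (tt > 1L) for (t in 2L:tt)
    path[, t] <- vapply(path[, t - 1L], function(cl)
      sample.int(k, 1L, prob = cfg$transition_matrix[cl, ]), integer(1))

  factors <- array(NA_real_, c(n, 4L, tt))
  for (t in seq_len(tt))
    factors[, , t] <- cfg$centroids[[t]][path[, t], , drop = FALSE] +
      matrix(rnorm(n * 4L, sd = cfg$within_sd), n, 4L)

  outcome <- vapply(path[, tt], function(cl)
    sample.int(ncol(cfg$outcome_probs), 1L,
               prob = cfg$outcome_probs[cl, ]) - 1L, integer(1))

  outlier_ids <- character(0)
  if (cfg$n_outliers > 0L) {
    pick <- sample.int(n, cfg$n_outliers)
    outlier_ids <- ids[pick]
    pair_pool <- combn(4L, 2L)
    pairs <- pair_pool[, rep_len(sample.int(ncol(pair_pool)),
                                 cfg$n_outliers), drop = FALSE]
    for (o in seq_len(cfg$n_outliers)) {
      v <- rep(cfg$outlier_magnitude, 4L)   # discordant extreme profile
      v[pairs[, o]] <- -cfg$outlier_magnitude
      for (t in seq_len(tt)) factors[pick[o], , t] <- v
    }
  }

  truth <- structure(list(cluster_path = path, outcome = outcome,
                          outlier_ids = outlier_ids, config = cfg),
                     class = "synthetic_truth")

  if (!cfg$raw_mode) {
    long <- do.call(rbind, lapply(seq_len(tt), function(t) {
      d <- data.frame(person_id = ids, timepoint = t)
      d[FACTOR_NAMES] <- factors[, , t]
      d
    }))
    if (cfg$missing_rate > 0) {
      cells <- as.matrix(long[, FACTOR_NAMES])
      mask <- matrix(stats::runif(length(cells)) < cfg$missing_rate,
                     nrow(cells))
      cells[mask] <- NA_real_
      long[, FACTOR_NAMES] <- cells
    }
    long$outcome <- outcome[match(long$person_id, ids)]
    return(list(panel = factor_panel(long), truth = truth))
  }

  # raw mode: factor z -> test scores via anchors, with attempt pairs
  schema <- default_schema()
  test_noise <- 0.5
  long <- do.call(rbind, lapply(seq_len(tt), function(t) {
    ai <- min(t, 3L)
    z <- factors[, , t]
    d <- data.frame(person_id = ids, timepoint = t)
    raw_of <- function(measure, zlat, lower) {
      a <- RAW_ANCHORS[[measure]]
      zt <- zlat + rnorm(n, sd = test_noise)
      a[ai, "mean"] + a[ai, "sd"] * (if (lower) -zt else zt)
    }
    attempts_of <- function(best, lower, sdv) {
      worse <- best + (if (lower) 1 else -1) * abs(rnorm(n, sd = sdv))
      flip <- stats::runif(n) < 0.5
      cbind(ifelse(flip, worse, best), ifelse(flip, best, worse))
    }
    nh <- pmin(pmax(RAW_ANCHORS$net_hope[ai, "mean"] +
                    RAW_ANCHORS$net_hope[ai, "sd"] * z[, 1L], -3), 3)
    hs0 <- (3 + nh) / 2
    ff0 <- (3 - nh) / 2
    # shared shift keeps hs - ff = NH exact while breaking the hs/ff
    # collinearity; bounded so both scale means stay in [0, 3]
    u <- rnorm(n, sd = 0.25)
    u <- pmin(pmax(u, -pmin(hs0, ff0)), pmin(3 - hs0, 3 - ff0))
    d$hs <- hs0 + u
    d$ff <- ff0 + u
    two <- function(measure, zlat, lower) {
      best <- raw_of(measure, zlat, lower)
      at <- attempts_of(best, lower, 0.3 * RAW_ANCHORS[[measure]][ai, "sd"])
      at
    }
    at <- two("dribbling", z[, 2L], TRUE)
    d$dribbling_1 <- at[, 1L]; d$dribbling_2 <- at[, 2L]
    at <- two("ball_control", z[, 2L], TRUE)
    d$ball_control_1 <- at[, 1L]; d$ball_control_2 <- at[, 2L]
    at <- two("juggling", z[, 2L], FALSE)
    d$juggling_1 <- pmax(at[, 1L], 0); d$juggling_2 <- pmax(at[, 2L], 0)
    at <- two("sprint_40m", z[, 3L], TRUE)
    d$sprint_40m_1 <- at[, 1L]; d$sprint_40m_2 <- at[, 2L]
    d$yoyo_ir1 <- pmax(raw_of("yoyo_ir1", z[, 3L], FALSE), 0)
    at <- two("cmj", z[, 3L], FALSE)
    d$cmj_1 <- at[, 1L]; d$cmj_2 <- at[, 2L]
    d$pct_adult_height <- raw_of("pct_adult_height", z[, 4L], FALSE)
    d
  }))
  # MCAR at the measure level: a missed test loses all its attempts, so
  # the analysis-cell missing share matches missing_rate
  if (cfg$missing_rate > 0) {
    for (nm in names(schema$variables)) {
      a <- schema$variables[[nm]]$attempts
      cols <- if (a == 1L) nm else paste(nm, seq_len(a), sep = "_")
      mask <- stats::runif(nrow(long)) < cfg$missing_rate
      long[mask, cols] <- NA_real_
    }
  }
  long$outcome <- outcome[match(long$person_id, ids)]
  list(panel = raw_panel(long, schema), truth = truth)
}

#' Summarize a generated panel against its ground truth
#'
#' @param panel the panel returned by [generate_panel()].
#' @param truth the matching `synthetic_truth`.
#' @return list with `cluster_sizes` (clusters x timepoints), realized
#'   `transition_counts` (per adjacent pair), `missing_fraction`,
#'   `outcome_table`.
#' @export
describe_panel <- function(panel, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  d <- if (inherits(panel, "raw_panel")) panel$data else panel
  ids <- rownames(truth$cluster_path)
  if (!setequal(unique(d$person_id), ids) ||
      max(d$timepoint) != ncol(truth$cluster_path))
    stop("panel and truth do not match")
  k <- truth$config$n_clusters
  tt <- ncol(truth$cluster_path)
  sizes <- vapply(seq_len(tt), function(t)
    tabulate(truth$cluster_path[, t], k), integer(k))
  trans <- if (tt > 1L) lapply(seq_len(tt - 1L), function(t)
    transition_table(setNames(truth$cluster_path[, t], ids),
                     setNames(truth$cluster_path[, t + 1L], ids),
                     levels_from = seq_len(k), levels_to = seq_len(k)))
    else list()
  value_cols <- setdiff(names(d), c(ID_COLS, "outcome"))
  list(cluster_sizes = sizes,
       transition_counts = trans,
       missing_fraction = mean(is.na(as.matrix(d[, value_cols]))),
       outcome_table = table(truth$outcome))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d persons x %d timepoints, k = %d, %d outliers\n",
              nrow(x$cluster_path), ncol(x$cluster_path),
              x$config$n_clusters, length(x$outlier_ids)))
  invisible(x)
}
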