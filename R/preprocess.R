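#' Net hope: achievement-motive balance
#'
#' Net hope is the difference between the two achievement-motive
#' components, hope for success and fear of failure (NH = HS - FF), both
#' measured as scale means on a 0--3 response scale. Positive values mean
#' that hope for success dominates.
#'
#' @param hs hope-for-success scale mean(s), in `[0, 3]`.
#' @param ff fear-of-failure scale mean(s), in `[0, 3]`.
#' @return `hs - ff`, in `[-3, 3]`. `NA` propagates.
#' @export
net_hope <- function(hs, ff) {
  chk <- function(x, nm) {
    if (any(x < 0 | x > 3, na.rm = TRUE))
      stop(nm, " outside the 0-3 scale range")
  }
  chk(hs, "hs"); chk(ff, "ff")
  hs - ff
}

#' Best of several test attempts
#'
#' Selects each person's best score across attempts: the maximum for
#' higher-is-better measures, the minimum for lower-is-better ones (times).
#' Missing attempts are ignored; if all attempts are missing the result is
#' missing.
#'
#' @param attempts numeric vector (one person) or matrix (persons x
#'   attempts).
#' @param orientation `"higher"` or `"lower"`.
#' @return best score per person (`NA` where all attempts missing).
#' @export
best_attempt <- function(attempts, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  f <- if (orientation == "higher") max else min
  pick <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else f(v)
  }
  if (is.matrix(attempts)) apply(attempts, 1L, pick) else pick(attempts)
}

#' z-standardize a column, aligned so positive = above average
#'
#' Centers and scales by the sample standard deviation (n - 1); for
#' lower-is-better measures the sign is then flipped so that positive
#' z-scores always stand for above-average performance.
#'
#' @param values numeric vector without missing values.
#' @param orientation `"higher"` or `"lower"`.
#' @return z-scored vector with mean 0 and sd 1.
#' @export
zscore_column <- function(values, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  if (anyNA(values)) stop("zscore_column requires complete data")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("zero-variance column cannot be z-scored")
  z <- (values - mean(values)) / s
  if (orientation == "lower") -z else z
}

#' Element-wise mean of aligned z-columns
#'
#' Combines two or more aligned (positive = better) z-columns into a
#' composite score by the per-person arithmetic mean.
#'
#' @param ... numeric vectors of equal length, or a single list/matrix.
#' @return numeric vector of per-person means.
#' @export
composite <- function(...) {
  cols <- list(...)
  if (length(cols) == 1L && is.list(cols[[1]])) cols <- cols[[1]]
  if (length(cols) == 1L && is.matrix(cols[[1]]))
    return(rowMeans(cols[[1]]))
  n <- unique(vapply(cols, length, integer(1)))
  if (length(n) != 1L) stop("columns differ in length")
  rowMeans(do.call(cbind, cols))
}

#' Percentage of predicted adult height
#'
#' The current stature as a percentage of the predicted adult stature; a
#' non-invasive proxy for biological maturity (early-maturing individuals
#' are closer to their adult height than late-maturing peers of the same
#' chronological age).
#'
#' @param current_height current standing height, cm.
#' @param predicted_adult_height predicted adult height, cm.
#' @return percentage (100 * current / predicted). Values above 100 are
#'   returned with a warning (measurement after the estimate's horizon).
#' @export
percent_adult_height <- function(current_height, predicted_adult_height) {
  if (any(predicted_adult_height <= 0, na.rm = TRUE))
    stop("predicted adult height must be positive")
  if (any(current_height <= 0, na.rm = TRUE))
    stop("current height must be positive")
  over <- current_height > predicted_adult_height
  if (any(over, na.rm = TRUE))
    warning("current height exceeds predicted adult height for ",
            sum(over, na.rm = TRUE), " value(s)")
  100 * current_height / predicted_adult_height
}

#' Standardize a factor panel within timepoints
#'
#' Re-expresses each factor column as within-timepoint z-scores (sample
#' sd). All four factors are higher-is-better by construction.
#'
#' @param panel a [factor_panel()] without missing values.
#' @return the standardized `factor_panel`.
#' @export
standardize_factor_panel <- function(panel) {
  stopifnot(inherits(panel, "factor_panel"))
  for (tp in sort(unique(panel$timepoint))) {
    i <- panel$timepoint == tp
    for (f in FACTOR_NAMES)
      panel[[f]][i] <- zscore_column(panel[[f]][i], "higher")
  }
  panel
}

#' Build the four-factor panel from raw measures
#'
#' Per timepoint the pipeline is: best attempt per test; joint EM
#' imputation of all analysis variables of all timepoints on the person x
#' (variable x timepoint) matrix (so persons missing a whole measuring
#' point borrow cross-timepoint information); net hope = HS - FF; each
#' test z-scored with lower-is-better signs flipped; technical skills =
#' mean of the dribbling, ball-control and juggling z-scores; physical
#' fitness = mean of the sprint, endurance and jump z-scores; the four
#' factors finally z-scored within timepoint. Factor order is fixed:
#' net_hope, technical_skills, physical_fitness, biological_maturity.
#'
#' @param raw a [raw_panel()] using the [default_schema()] variables.
#' @param em an [em_config()] for the imputation step. The default uses a
#'   small ridge because the joint all-timepoint covariance (27
#'   variables) is large relative to typical cohort sizes.
#' @return A [factor_panel()] with attributes `mcar` (Little's test
#'   result), `imputed_fraction` (share of analysis cells imputed) and
#'   `em` (iterations, final log-likelihood).
#' @export
build_factor_panel <- function(raw, em = em_config(max_iter = 1000L,
                                                   ridge = 1e-3)) {
  stopifnot(inherits(raw, "raw_panel"))
  d <- raw$data
  sch <- raw$schema$variables
  need <- c("hs", "ff", "dribbling", "ball_control", "juggling",
            "sprint_40m", "yoyo_ir1", "cmj", "pct_adult_height")
  if (!all(need %in% names(sch)))
    stop("schema lacks required analysis variables: ",
         paste(setdiff(need, names(sch)), collapse = ", "))

  # collapse attempts -> one column per analysis variable
  vals <- lapply(need, function(nm) {
    a <- sch[[nm]]$attempts
    cols <- if (a == 1L) nm else paste(nm, seq_len(a), sep = "_")
    best_attempt(as.matrix(d[, cols, drop = FALSE]), sch[[nm]]$orientation)
  })
  names(vals) <- need

  # person x (variable.timepoint) wide matrix for joint imputation
  persons <- sort(unique(d$person_id))
  tps <- sort(unique(d$timepoint))
  wide <- matrix(NA_real_, length(persons), length(need) * length(tps),
                 dimnames = list(persons, paste(rep(need, length(tps)),
                                 rep(tps, each = length(need)), sep = ".")))
  for (ti in seq_along(tps)) {
    i <- d$timepoint == tps[ti]
    rows <- match(d$person_id[i], persons)
    for (vi in seq_along(need))
      wide[rows, (ti - 1L) * length(need) + vi] <- vals[[need[vi]]][i]
  }

  n_missing <- sum(is.na(wide))
  mcar <- little_mcar(wide, cfg = em)
  completed <- if (n_missing > 0) em_impute(wide, em) else wide

  # long factor panel
  out <- do.call(rbind, lapply(seq_along(tps), function(ti) {
    block <- completed[, (ti - 1L) * length(need) + seq_along(need),
                       drop = FALSE]
    colnames(block) <- need
    z <- function(nm) zscore_column(block[, nm], sch[[nm]]$orientation)
    data.frame(
      person_id = persons,
      timepoint = tps[ti],
      net_hope = net_hope(pmin(pmax(block[, "hs"], 0), 3),
                          pmin(pmax(block[, "ff"], 0), 3)),
      technical_skills = composite(z("dribbling"), z("ball_control"),
                                   z("juggling")),
      physical_fitness = composite(z("sprint_40m"), z("yoyo_ir1"),
                                   z("cmj")),
      biological_maturity = block[, "pct_adult_height"]
    )
  }))
  if ("outcome" %in% names(d)) {
    oc <- panel_outcomes(raw)
    out$outcome <- oc[out$person_id]
  }
  fp <- standardize_factor_panel(factor_panel(out))
  attr(fp, "mcar") <- mcar
  attr(fp, "imputed_fraction") <- n_missing / length(wide)
  attr(fp, "em") <- if (n_missing > 0)
    list(iterations = attr(completed, "iterations"),
         loglik = tail_loglik(completed)) else NULL
  fp
}

tail_loglik <- function(completed) {
  ll <- attr(completed, "loglik")
  if (is.null(ll)) NA_real_ else ll[length(ll)]
}
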