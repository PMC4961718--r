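#' Residue-screening configuration
#'
#' A person is a residue at a timepoint when fewer than `K` other persons
#' have a profile within averaged squared Euclidean distance `T_dist` of
#' theirs. The 3% guideline is advisory: exceeding it raises a warning,
#' never silent removal.
#'
#' @param T_dist distance threshold on z-scored profiles (default 0.8).
#' @param K minimum number of similar cases (default 1: only persons with
#'   a unique profile are removed).
#' @param max_fraction advisory ceiling on the residue share.
#' @return An object of class `residue_config`.
#' @export
residue_config <- function(T_dist = 0.8, K = 1L, max_fraction = 0.03) {
  stopifnot(T_dist > 0, K >= 1, max_fraction > 0, max_fraction < 1)
  structure(list(T_dist = T_dist, K = as.integer(K),
                 max_fraction = max_fraction), class = "residue_config")
}

#' Distance between two person profiles
#'
#' The averaged squared Euclidean distance sum((a - b)^2) / p, the scale
#' on which the residue threshold (0.8 on z-scored factors) and the
#' structural-stability distances are expressed. Set `average = FALSE`
#' for the raw (summed) squared distance.
#'
#' @param a,b numeric profile vectors of equal length.
#' @param average divide by the number of variables (default `TRUE`).
#' @return nonnegative scalar distance.
#' @export
profile_distance <- function(a, b, average = TRUE) {
  if (length(a) != length(b)) stop("profiles differ in length")
  if (anyNA(a) || anyNA(b)) stop("profiles must be complete")
  d <- sum((a - b)^2)
  if (average) d / length(a) else d
}

# all pairwise averaged squared distances of a profile matrix
asd_matrix <- function(x, average = TRUE) {
  d <- as.matrix(dist(x))^2
  if (average) d / ncol(x) else d
}

#' Identify residues at one timepoint
#'
#' @param x numeric matrix (persons x factors) with person ids as row
#'   names; z-scored profiles of one timepoint.
#' @param cfg a [residue_config()].
#' @param timepoint timepoint label carried into the report.
#' @return An object of class `residue_report`: `timepoint`,
#'   `residue_ids`, `fraction`, `exceeded_guideline`, `n`.
#' @export
find_residues <- function(x, cfg = residue_config(), timepoint = NA_integer_) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (n < cfg$K + 1L)
    stop("need at least K + 1 = ", cfg$K + 1L, " persons")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(n))
  d <- asd_matrix(x)
  neighbours <- rowSums(d <= cfg$T_dist) - 1L   # self excluded
  ids <- rownames(x)[neighbours < cfg$K]
  fraction <- length(ids) / n
  if (fraction > cfg$max_fraction)
    warning(sprintf("residue fraction %.1f%% exceeds the %.0f%% guideline",
                    100 * fraction, 100 * cfg$max_fraction))
  structure(list(timepoint = timepoint, residue_ids = ids,
                 fraction = fraction,
                 exceeded_guideline = fraction > cfg$max_fraction, n = n),
            class = "residue_report")
}

#' Remove residues from the whole longitudinal sample
#'
#' Persons flagged as a residue at any timepoint are removed from all
#' timepoints, reproducing the construction of a final analysis sample
#' from which the outliers of every phase have been dropped.
#'
#' @param panel a [factor_panel()].
#' @param reports list of [find_residues()] reports (one per timepoint).
#' @return list with `panel` (the reduced `factor_panel`) and
#'   `removed_ids` (character vector, union over timepoints).
#' @export
remove_residues <- function(panel, reports) {
  stopifnot(inherits(panel, "factor_panel"))
  if (inherits(reports, "residue_report")) reports <- list(reports)
  removed <- sort(unique(unlist(lapply(reports, `[[`, "residue_ids"))))
  kept <- panel[!panel$person_id %in% removed, , drop = FALSE]
  list(panel = factor_panel(as.data.frame(kept)), removed_ids = removed)
}

#' Screen every timepoint of a panel for residues
#'
#' @param panel a [factor_panel()] without missing values.
#' @param cfg a [residue_config()].
#' @return list of `residue_report`, one per timepoint.
#' @export
screen_residues <- function(panel, cfg = residue_config()) {
  stopifnot(inherits(panel, "factor_panel"))
  lapply(sort(unique(panel$timepoint)), function(tp)
    find_residues(factor_matrix(panel, tp), cfg, timepoint = tp))
}

#' @export
print.residue_report <- function(x, ...) {
  cat(sprintf("residues at t%s: %d of %d (%.1f%%)%s\n",
              x$timepoint, length(x$residue_ids), x$n, 100 * x$fraction,
              if (x$exceeded_guideline) " [guideline exceeded]" else ""))
  if (length(x$residue_ids))
    cat("  ids:", paste(x$residue_ids, collapse = ", "), "\n")
  invisible(x)
}
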