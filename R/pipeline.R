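#' Pipeline configuration
#'
#' One object governs an end-to-end run: data source (a generator config
#' for synthetic panels, or paths to a panel CSV and schema JSON),
#' residue screening, cluster-solution selection, and transition testing.
#' Serializable to and from JSON; unknown keys are rejected.
#'
#' @param generator a [generator_config()], or `NULL` when reading from
#'   files.
#' @param panel_path,schema_path input CSV and schema JSON (schema `NULL`
#'   for a factor-panel CSV).
#' @param residues a [residue_config()].
#' @param k_candidates candidate cluster numbers per timepoint.
#' @param c_mojena Mojena threshold.
#' @param name_threshold |z| cutoff for cluster naming.
#' @param alpha per-cell significance level for transition tests.
#' @param correction multiplicity correction (`"none"`, `"holm"`,
#'   `"bonferroni"`).
#' @param em an [em_config()].
#' @param seed integer seed for every stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            panel_path = NULL, schema_path = NULL,
                            residues = residue_config(),
                            k_candidates = 2:8, c_mojena = 2.75,
                            name_threshold = 0.5, alpha = 0.05,
                            correction = "none",
                            em = em_config(max_iter = 1000L, ridge = 1e-3),
                            seed = 1L) {
  stopifnot(is.null(generator) || inherits(generator, "generator_config"),
            inherits(residues, "residue_config"),
            inherits(em, "em_config"),
            correction %in% c("none", "holm", "bonferroni"))
  if (is.null(generator) && is.null(panel_path))
    stop("either a generator config or a panel path is required")
  structure(list(generator = generator, panel_path = panel_path,
                 schema_path = schema_path, residues = residues,
                 k_candidates = as.integer(k_candidates),
                 c_mojena = c_mojena, name_threshold = name_threshold,
                 alpha = alpha, correction = correction, em = em,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("generator", "panel_path", "schema_path", "residues",
             "k_candidates", "c_mojena", "name_threshold", "alpha",
             "correction", "em", "seed")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  as_matrix_list <- function(v) {
    if (is.array(v) && length(dim(v)) == 3L)
      lapply(seq_len(dim(v)[1L]), function(i) v[i, , ])
    else if (is.list(v) && !is.data.frame(v)) lapply(v, as.matrix)
    else as.matrix(v)
  }
  drop_empty <- function(l) l[vapply(l, length, integer(1)) > 0L]
  gen <- if (!is.null(x$generator)) {
    g <- drop_empty(x$generator)
    if (!is.null(g$centroids)) g$centroids <- as_matrix_list(g$centroids)
    if (!is.null(g$transition_matrix))
      g$transition_matrix <- as.matrix(g$transition_matrix)
    if (!is.null(g$outcome_probs))
      g$outcome_probs <- as.matrix(g$outcome_probs)
    if (!is.null(g$init_probs)) g$init_probs <- as.numeric(g$init_probs)
    do.call(generator_config, g)
  }
  pipeline_config(
    generator = gen,
    panel_path = x$panel_path, schema_path = x$schema_path,
    residues = do.call(residue_config, as.list(x$residues %||% list())),
    k_candidates = x$k_candidates %||% 2:8,
    c_mojena = x$c_mojena %||% 2.75,
    name_threshold = x$name_threshold %||% 0.5,
    alpha = x$alpha %||% 0.05,
    correction = x$correction %||% "none",
    em = do.call(em_config, drop_empty(as.list(x$em %||% list()))),
    seed = x$seed %||% 1L)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- lapply(unclass(cfg), function(v)
    if (is.object(v)) unclass(v) else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Run the full person-oriented analysis pipeline
#'
#' Stages: obtain a panel (synthetic or from file); build or complete the
#' factor panel (joint EM imputation over all timepoints, Little's MCAR
#' diagnostic, within-timepoint standardization); screen and remove
#' residues (union over timepoints); per-timepoint Ward clustering with
#' Mojena-guided solution selection and k-means relocation; structural
#' stability pairing of adjacent solutions; exact hypergeometric
#' type/antitype scans for adjacent timepoint pairs and, when an outcome
#' is present, from the final timepoint's clusters to the outcome levels.
#'
#' @param cfg a [pipeline_config()].
#' @return A `licur_bundle`: `config`, `counts` (bookkeeping per stage),
#'   `mcar`, `imputed_fraction`, `residues`, `solutions` (per timepoint),
#'   `selection` (diagnostics per timepoint), `stability`, `transitions`,
#'   `outcome_transitions`, `truth` (when synthetic).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)

  truth <- NULL
  if (!is.null(cfg$generator)) {
    gen <- cfg$generator
    gen$seed <- cfg$seed
    sim <- generate_panel(gen)
    panel <- sim$panel
    truth <- sim$truth
  } else {
    schema <- if (!is.null(cfg$schema_path)) read_schema(cfg$schema_path)
    panel <- read_panel(cfg$panel_path, schema)
  }
  if (inherits(panel, "raw_panel") && nrow(panel$data) == 0L)
    stop("empty input panel")

  mcar <- NULL; imputed_fraction <- 0
  if (inherits(panel, "raw_panel")) {
    fp <- build_factor_panel(panel, em = cfg$em)
    mcar <- attr(fp, "mcar")
    imputed_fraction <- attr(fp, "imputed_fraction")
  } else {
    fp <- panel
    fm <- as.matrix(as.data.frame(fp)[, FACTOR_NAMES])
    if (anyNA(fm)) {
      wide <- factor_wide(fp)
      mcar <- little_mcar(wide, cfg = cfg$em)
      imputed_fraction <- mean(is.na(wide))
      completed <- em_impute(wide, cfg$em)
      fp <- factor_long(completed, fp)
    }
    fp <- standardize_factor_panel(fp)
  }

  tps <- sort(unique(fp$timepoint))
  n_in <- length(unique(fp$person_id))
  reports <- screen_residues(fp, cfg$residues)
  rr <- remove_residues(fp, reports)
  kept <- rr$panel

  selection <- lapply(tps, function(tp)
    select_solution(factor_matrix(kept, tp),
                    k_candidates = cfg$k_candidates,
                    c_mojena = cfg$c_mojena, timepoint = tp,
                    name_threshold = cfg$name_threshold))
  names(selection) <- paste0("t", tps)
  solutions <- lapply(selection, function(s)
    s$solutions[[as.character(s$pick)]])

  stability <- list()
  transitions <- list()
  if (length(tps) > 1L) {
    for (i in seq_len(length(tps) - 1L)) {
      key <- sprintf("t%d_t%d", tps[i], tps[i + 1L])
      stability[[key]] <- pair_by_distance(
        centroid_distances(solutions[[i]], solutions[[i + 1L]]))
      transitions[[key]] <- scan_types(
        transition_table(solutions[[i]]$assignments,
                         solutions[[i + 1L]]$assignments),
        alpha = cfg$alpha, correction = cfg$correction)
    }
  }
  outcome_transitions <- NULL
  has_outcome <- "outcome" %in% names(kept)
  if (has_outcome && !all(is.na(kept$outcome))) {
    oc <- panel_outcomes(kept)
    outcome_transitions <- scan_types(
      transition_table(solutions[[length(tps)]]$assignments, oc),
      alpha = cfg$alpha, correction = cfg$correction)
  }

  structure(list(
    config = cfg,
    counts = list(persons_in = n_in,
                  residues_removed = length(rr$removed_ids),
                  persons_kept = length(unique(kept$person_id)),
                  imputed_fraction = imputed_fraction),
    mcar = mcar, imputed_fraction = imputed_fraction,
    residues = reports, removed_ids = rr$removed_ids,
    factor_panel = kept, selection = selection, solutions = solutions,
    stability = stability, transitions = transitions,
    outcome_transitions = outcome_transitions, truth = truth),
    class = "licur_bundle")
}

# persons x (factor.timepoint) wide matrix of a factor panel
factor_wide <- function(fp) {
  d <- as.data.frame(fp)
  persons <- sort(unique(d$person_id))
  tps <- sort(unique(d$timepoint))
  wide <- matrix(NA_real_, length(persons), 4L * length(tps),
                 dimnames = list(persons,
                   paste(rep(FACTOR_NAMES, length(tps)),
                         rep(tps, each = 4L), sep = ".")))
  for (ti in seq_along(tps)) {
    i <- d$timepoint == tps[ti]
    wide[match(d$person_id[i], persons), (ti - 1L) * 4L + 1:4] <-
      as.matrix(d[i, FACTOR_NAMES])
  }
  wide
}

factor_long <- function(wide, template) {
  d <- as.data.frame(template)
  tps <- sort(unique(d$timepoint))
  for (ti in seq_along(tps)) {
    i <- d$timepoint == tps[ti]
    d[i, FACTOR_NAMES] <-
      wide[match(d$person_id[i], rownames(wide)), (ti - 1L) * 4L + 1:4]
  }
  factor_panel(d)
}

#' Render a pipeline bundle as text and JSON
#'
#' The JSON report is deterministic for a given configuration and seed
#' (stable key order, fixed number formatting): repeated runs are
#' byte-identical. The text report lists per-timepoint cluster centroid
#' tables with their |z|-based names, the structural-stability pairings,
#' and every developmental type, antitype and zero-transition path; if no
#' cell is significant it says so explicitly.
#'
#' @param bundle a `licur_bundle` from [run_pipeline()].
#' @return list with `text` (character vector of report lines) and
#'   `json` (a JSON string).
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "licur_bundle"))
  num <- function(x) round(unname(x), 6)
  lines <- c("person-oriented pattern analysis report",
             sprintf("persons in: %d; residues removed: %d; kept: %d",
                     bundle$counts$persons_in,
                     bundle$counts$residues_removed,
                     bundle$counts$persons_kept),
             sprintf("imputed cells: %.2f%%",
                     100 * bundle$counts$imputed_fraction))
  if (!is.null(bundle$mcar) && bundle$mcar$applicable)
    lines <- c(lines, sprintf("MCAR test: chi2 = %.1f, df = %d, p = %.3f",
                              bundle$mcar$chi2, bundle$mcar$df,
                              bundle$mcar$p_value))

  sol_json <- list()
  for (key in names(bundle$solutions)) {
    sol <- bundle$solutions[[key]]
    lines <- c(lines, sprintf("-- %s: k = %d, EESS = %.1f%%", key, sol$k,
                              sol$eess_percent))
    for (cl in seq_len(sol$k)) {
      nm <- sol$names[[cl]]
      lab <- if (nrow(nm))
        paste(sprintf("%s %s (z=%.2f)", nm$factor, nm$direction, nm$z),
              collapse = ", ")
      else "(no salient factor)"
      lines <- c(lines, sprintf("   cluster %d (n=%d): %s | centroid [%s]",
                                cl, sol$sizes[cl], lab,
                                paste(sprintf("%.2f", sol$centroids[cl, ]),
                                      collapse = ", ")))
    }
    sol_json[[key]] <- list(
      k = sol$k, sizes = sol$sizes,
      eess_percent = num(sol$eess_percent), f_count = sol$f_count,
      centroids = apply(unname(sol$centroids), 1:2, num),
      names = lapply(sol$names, function(nm)
        lapply(seq_len(nrow(nm)), function(r)
          list(factor = nm$factor[r], direction = nm$direction[r],
               z = num(nm$z[r])))))
  }

  stab_json <- list()
  for (key in names(bundle$stability)) {
    m <- bundle$stability[[key]]
    lines <- c(lines, sprintf("-- stability %s:", key),
               sprintf("   %d <-> %d (d = %.3f)", m$pairing$cluster_a,
                       m$pairing$cluster_b, m$pairing$distance))
    if (length(m$unmatched_a) || length(m$unmatched_b))
      lines <- c(lines, sprintf("   unmatched: a[%s] b[%s]",
                                paste(m$unmatched_a, collapse = ","),
                                paste(m$unmatched_b, collapse = ",")))
    stab_json[[key]] <- list(
      pairing = lapply(seq_len(nrow(m$pairing)), function(r)
        list(cluster_a = m$pairing$cluster_a[r],
             cluster_b = m$pairing$cluster_b[r],
             distance = num(m$pairing$distance[r]))),
      unmatched_a = m$unmatched_a, unmatched_b = m$unmatched_b,
      optimal_differs = m$optimal_differs)
  }

  trans_json <- list()
  report_trans <- function(rep, key) {
    sig <- rep$cells[rep$cells$classification != "none", , drop = FALSE]
    out <- character(0)
    if (nrow(sig)) {
      out <- sprintf("   %s: %s -> %s obs %d exp %.1f OR %.2g",
                     sig$classification, sig$from, sig$to, sig$observed,
                     sig$expected, sig$odds_ratio)
    } else out <- "   no types/antitypes"
    if (nrow(rep$zero_paths))
      out <- c(out, sprintf("   zero-transition paths: %s",
                            paste(rep$zero_paths$from, rep$zero_paths$to,
                                  sep = "->", collapse = ", ")))
    c(sprintf("-- transitions %s:", key), out)
  }
  for (key in names(bundle$transitions)) {
    rep <- bundle$transitions[[key]]
    lines <- c(lines, report_trans(rep, key))
    trans_json[[key]] <- transition_report_json(rep, num)
  }
  if (!is.null(bundle$outcome_transitions)) {
    rep <- bundle$outcome_transitions
    lines <- c(lines, report_trans(rep, "final -> outcome"))
    trans_json[["outcome"]] <- transition_report_json(rep, num)
  }

  json <- jsonlite::toJSON(list(
    counts = bundle$counts,
    mcar = if (!is.null(bundle$mcar)) unclass(bundle$mcar),
    residues = lapply(bundle$residues, function(r)
      list(timepoint = r$timepoint, residue_ids = r$residue_ids,
           fraction = num(r$fraction),
           exceeded_guideline = r$exceeded_guideline)),
    solutions = sol_json, stability = stab_json,
    transitions = trans_json),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  list(text = lines, json = as.character(json))
}

transition_report_json <- function(rep, num) {
  list(
    n = rep$n, alpha = rep$alpha, correction = rep$correction,
    table = apply(unname(rep$table), 1:2, as.integer),
    cells = lapply(seq_len(nrow(rep$cells)), function(r) {
      cl <- rep$cells[r, ]
      list(from = cl$from, to = cl$to, observed = cl$observed,
           expected = num(cl$expected), p_type = num(cl$p_type),
           p_antitype = num(cl$p_antitype),
           odds_ratio = if (is.finite(cl$odds_ratio)) num(cl$odds_ratio)
                        else as.character(cl$odds_ratio),
           classification = cl$classification)
    }),
    zero_paths = lapply(seq_len(nrow(rep$zero_paths)), function(r)
      list(from = rep$zero_paths$from[r], to = rep$zero_paths$to[r])))
}

#' @export
print.licur_bundle <- function(x, ...) {
  cat(render_report(x)$text, sep = "\n")
  invisible(x)
}
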