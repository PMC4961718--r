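#' Longitudinal raw-measure panel
#'
#' A `raw_panel` holds one row per person and timepoint with the raw
#' measures declared by a schema, an optional ordinal outcome level per
#' person (constant across timepoints), and missing cells stored as `NA`.
#'
#' @param data data frame with columns `person_id`, `timepoint`, the
#'   measure columns of `schema`, and optionally `outcome`.
#' @param schema a [panel_schema()].
#' @return An object of class `raw_panel`.
#' @export
raw_panel <- function(data, schema) {
  stopifnot(inherits(schema, "licur_schema"), is.data.frame(data))
  cols <- schema_columns(schema)
  miss <- setdiff(c(ID_COLS, cols), names(data))
  if (length(miss))
    stop("panel lacks declared columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(data), c(ID_COLS, cols, "outcome"))
  if (length(extra))
    stop("undeclared variable columns: ", paste(extra, collapse = ", "))
  data$person_id <- as.character(data$person_id)
  data$timepoint <- as.integer(data$timepoint)
  validate_panel_core(data)
  for (cc in cols) {
    if (!is.numeric(data[[cc]]))
      stop("measure column '", cc, "' is not numeric")
  }
  data <- data[order(data$timepoint, data$person_id),
               c(ID_COLS, cols, intersect("outcome", names(data)))]
  rownames(data) <- NULL
  structure(list(data = data, schema = schema), class = "raw_panel")
}

# shared (person, timepoint, outcome) validation
validate_panel_core <- function(data) {
  if (!nrow(data)) stop("panel has no rows")
  key <- paste(data$person_id, data$timepoint, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (person, timepoint) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  tps <- sort(unique(data$timepoint))
  if (!identical(tps, seq_len(max(tps))) || min(tps) != 1L)
    stop("timepoints must be consecutive integers starting at 1")
  if ("outcome" %in% names(data)) {
    byp <- split(data$outcome, data$person_id)
    bad <- vapply(byp, function(v) {
      v <- v[!is.na(v)]
      length(unique(v)) > 1L
    }, logical(1))
    if (any(bad))
      stop("outcome not constant within person: ",
           paste(names(byp)[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Panel of the four z-scored operating factors
#'
#' One row per person and timepoint with the four operating factors
#' (net hope, technical skills, physical fitness, biological maturity).
#' After imputation and standardization each factor column has mean 0 and
#' unit variance within each timepoint.
#'
#' @param data data frame with columns `person_id`, `timepoint`, the four
#'   factor columns, and optionally `outcome`.
#' @return An object of class `factor_panel` (a data frame).
#' @export
factor_panel <- function(data) {
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(ID_COLS, FACTOR_NAMES), names(data))
  if (length(miss))
    stop("factor panel lacks columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(data), c(ID_COLS, FACTOR_NAMES, "outcome"))
  if (length(extra))
    stop("unexpected columns: ", paste(extra, collapse = ", "))
  data$person_id <- as.character(data$person_id)
  data$timepoint <- as.integer(data$timepoint)
  validate_panel_core(data)
  data <- data[order(data$timepoint, data$person_id),
               c(ID_COLS, FACTOR_NAMES, intersect("outcome", names(data)))]
  rownames(data) <- NULL
  class(data) <- c("factor_panel", "data.frame")
  data
}

#' Factor matrix of one timepoint
#'
#' @param panel a `factor_panel`.
#' @param timepoint timepoint to extract.
#' @return numeric matrix (persons x 4) with person ids as row names.
#' @export
factor_matrix <- function(panel, timepoint) {
  stopifnot(inherits(panel, "factor_panel"))
  d <- panel[panel$timepoint == timepoint, , drop = FALSE]
  if (!nrow(d)) stop("no rows at timepoint ", timepoint)
  m <- as.matrix(d[, FACTOR_NAMES])
  rownames(m) <- d$person_id
  m
}

#' Read a longitudinal panel from delimited text
#'
#' Reads an RFC-4180 style CSV (UTF-8, "." decimal separator) with a header
#' naming `person_id`, `timepoint`, the measure columns declared by the
#' schema and optionally `outcome`. Empty fields and the schema's missing
#' token are read as missing; any other non-numeric cell is an error, as
#' are duplicate (person, timepoint) rows and undeclared columns.
#'
#' @param path CSV file path.
#' @param schema a [panel_schema()]; when `NULL` the file is read as a
#'   [factor_panel()] (the four factor columns instead of raw measures).
#' @return A `raw_panel`, or a `factor_panel` when `schema` is `NULL`.
#' @export
read_panel <- function(path, schema = NULL) {
  tok <- if (is.null(schema)) "NA" else schema$missing_token
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(ID_COLS %in% names(raw)))
    stop("file must have 'person_id' and 'timepoint' columns")
  numify <- function(v, col) {
    v[v %in% c("", tok)] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(out)
    if (any(bad))
      stop("non-numeric cell(s) in column '", col, "': ",
           paste(unique(v[bad]), collapse = ", "))
    out
  }
  for (cc in setdiff(names(raw), "person_id"))
    raw[[cc]] <- numify(raw[[cc]], cc)
  if ("outcome" %in% names(raw)) raw$outcome <- as.integer(raw$outcome)
  raw$timepoint <- as.integer(raw$timepoint)
  if (is.null(schema)) factor_panel(raw) else raw_panel(raw, schema)
}

#' Write a panel to delimited text
#'
#' Numeric cells are written with 17 significant digits so that
#' `read_panel()` recovers the panel exactly (values, missingness mask and
#' outcome); missing cells are written as empty fields.
#'
#' @param panel a `raw_panel` or `factor_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  d <- if (inherits(panel, "raw_panel")) panel$data else
       if (inherits(panel, "factor_panel")) as.data.frame(panel) else
       stop("not a panel")
  for (cc in names(d))
    if (is.double(d[[cc]])) {
      v <- sprintf("%.17g", d[[cc]])
      v[is.na(d[[cc]])] <- NA_character_
      d[[cc]] <- v
    }
  write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-person outcome levels of a panel
#'
#' @param panel a `raw_panel` or `factor_panel` carrying an `outcome`
#'   column.
#' @return named integer vector, one level per person.
#' @export
panel_outcomes <- function(panel) {
  d <- if (inherits(panel, "raw_panel")) panel$data else panel
  if (!"outcome" %in% names(d)) stop("panel has no outcome column")
  first <- !duplicated(d$person_id)
  setNames(d$outcome[first], d$person_id[first])
}

#' @export
print.raw_panel <- function(x, ...) {
  d <- x$data
  cat(sprintf("raw_panel: %d persons x %d timepoints, %d measure columns\n",
              length(unique(d$person_id)), max(d$timepoint),
              length(schema_columns(x$schema))))
  mm <- as.matrix(d[, schema_columns(x$schema)])
  cat(sprintf("  missing cells: %.1f%%%s\n", 100 * mean(is.na(mm)),
              if ("outcome" %in% names(d)) "; outcome present" else ""))
  invisible(x)
}

#' @export
print.factor_panel <- function(x, ...) {
  cat(sprintf("factor_panel: %d persons x %d timepoints\n",
              length(unique(x$person_id)), max(x$timepoint)))
  print.data.frame(head(as.data.frame(x), 4))
  invisible(x)
}
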