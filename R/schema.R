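#' Variable schema for raw longitudinal panels
#'
#' A schema declares, for every raw measure, its orientation
#' (`"higher"` = higher values mean better performance, `"lower"` = lower
#' values mean better, as for times) and how many attempts were recorded.
#' Measures with more than one attempt appear in the data file as columns
#' `<name>_1`, `<name>_2`, ...; single-attempt measures as `<name>`.
#'
#' @param variables named list; each element a list with fields
#'   `orientation` (`"higher"` or `"lower"`) and `attempts` (integer >= 1).
#' @param missing_token string accepted as missing on read, in addition to
#'   the empty field. Default `"NA"`.
#' @return An object of class `licur_schema`.
#' @export
panel_schema <- function(variables, missing_token = "NA") {
  stopifnot(is.list(variables), length(variables) >= 1,
            !is.null(names(variables)), all(nzchar(names(variables))))
  variables <- lapply(variables, function(v) {
    if (is.character(v)) v <- list(orientation = v)
    if (is.null(v$orientation) ||
        !v$orientation %in% c("higher", "lower"))
      stop("every variable must declare orientation 'higher' or 'lower'")
    if (is.null(v$attempts)) v$attempts <- 1L
    v$attempts <- as.integer(v$attempts)
    stopifnot(v$attempts >= 1L)
    v[c("orientation", "attempts")]
  })
  structure(list(variables = variables, missing_token = missing_token),
            class = "licur_schema")
}

#' Default schema of the talent-study measure battery
#'
#' Hope for success and fear of failure (0--3 scale means), three technical
#' tests (dribbling, ball control in seconds -- lower is better -- and
#' juggling in points), three fitness tests (40 m sprint in seconds, Yo-yo
#' intermittent endurance distance in meters, countermovement jump in cm)
#' and the percentage of predicted adult height as the maturity proxy.
#' Technical tests, sprint and jump were administered twice; the Yo-yo test
#' once.
#'
#' @return A `licur_schema`.
#' @export
default_schema <- function() {
  panel_schema(list(
    hs               = list(orientation = "higher", attempts = 1L),
    ff               = list(orientation = "lower",  attempts = 1L),
    dribbling        = list(orientation = "lower",  attempts = 2L),
    ball_control     = list(orientation = "lower",  attempts = 2L),
    juggling         = list(orientation = "higher", attempts = 2L),
    sprint_40m       = list(orientation = "lower",  attempts = 2L),
    yoyo_ir1         = list(orientation = "higher", attempts = 1L),
    cmj              = list(orientation = "higher", attempts = 2L),
    pct_adult_height = list(orientation = "higher", attempts = 1L)
  ))
}

# expected measure columns of a schema, in declaration order
schema_columns <- function(schema) {
  unlist(lapply(names(schema$variables), function(nm) {
    a <- schema$variables[[nm]]$attempts
    if (a == 1L) nm else paste(nm, seq_len(a), sep = "_")
  }), use.names = FALSE)
}

#' Read or write a schema as JSON
#'
#' @param path file path.
#' @return `read_schema` returns a `licur_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$variables)) stop("schema JSON lacks a 'variables' field")
  panel_schema(x$variables,
               missing_token = if (is.null(x$missing_token)) "NA"
                               else x$missing_token)
}

#' @rdname read_schema
#' @param schema a `licur_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "licur_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.licur_schema <- function(x, ...) {
  cat("licur schema:", length(x$variables), "variables\n")
  for (nm in names(x$variables)) {
    v <- x$variables[[nm]]
    cat(sprintf("  %-18s %-6s attempts=%d\n", nm, v$orientation, v$attempts))
  }
  invisible(x)
}
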