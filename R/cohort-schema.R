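#' Machine-readable cohort schema
#'
#' The package stores a child-level cohort as a tibble with one row per child
#' and two column blocks: a preschool assessment block (symptom, medication,
#' utilisation, atopy and physician-diagnosis fields recalled over the 12
#' months before the visit, nominally at 3 years of age) and an optional
#' school-entry outcome block (columns prefixed `out5_`, nominally at 5
#' years). The schema — column names, types, allowed ranges and which columns
#' a file must contain — ships as a plain CSV so external tools can validate
#' files without loading R. Question wording is a semantic reconstruction of
#' standard preschool respiratory questionnaires, not a verbatim instrument.
#'
#' Column types are: `character`, `numeric` (with `min`/`max` sanity range),
#' `count` (non-negative integer), `logical` (serialised as 0/1) and
#' `ordinal` (levels listed in the `levels` column, `|`-separated). Empty CSV
#' cells mean "unknown", which is distinct from zero throughout the package.
#'
#' @return A tibble with columns `column`, `type`, `levels`, `min`, `max`,
#'   `block`, `required`.
#' @examples
#' cohort_schema()
#' @export
cohort_schema <- function() {
  path <- system.file("extdata", "cohort_schema.csv", package = "chartscreen")
  readr::read_csv(path, col_types = readr::cols(
    column = "c", type = "c", levels = "c",
    min = "d", max = "d", block = "c", required = "l"
  ))
}

#' @keywords internal
schema_levels <- function(schema_row) {
  strsplit(schema_row$levels, "|", fixed = TRUE)[[1]]
}

# Coerce one raw character column to its schema type. Returns list(values,
# n_invalid): cells that are non-empty but unparseable or out of range become
# NA ("unknown") and are counted, never silently dropped or clamped.
coerce_column <- function(x, row) {
  blank <- is.na(x) | trimws(x) == ""
  raw <- trimws(x)
  out <- switch(row$type,
    character = raw,
    numeric = suppressWarnings(as.numeric(raw)),
    count = suppressWarnings(as.numeric(raw)),
    logical = {
      low <- tolower(raw)
      ifelse(low %in% c("1", "true"), TRUE,
        ifelse(low %in% c("0", "false"), FALSE, NA)
      )
    },
    ordinal = {
      lev <- schema_levels(row)
      factor(ifelse(raw %in% lev, raw, NA_character_), levels = lev)
    },
    stop("unknown schema type: ", row$type)
  )
  if (row$type %in% c("numeric", "count")) {
    bad <- !is.na(out) &
      ((!is.na(row$min) & out < row$min) | (!is.na(row$max) & out > row$max))
    if (row$type == "count") bad <- bad | (!is.na(out) & out != round(out))
    out[bad] <- NA
    if (row$type == "count") out <- as.integer(out)
  }
  n_invalid <- sum(!blank & is.na(out))
  out[blank] <- NA
  list(values = out, n_invalid = n_invalid)
}

#' Validate an in-memory cohort tibble against the schema
#'
#' Checks that all required columns are present, `child_id` values are
#' unique, and every typed column respects its declared type and range.
#' Validation is total: problems are collected and reported together.
#'
#' @param data A cohort tibble (as returned by [read_cohort()] or
#'   [simulate_cohort()]).
#' @param require_outcomes Also require the `out5_` outcome block.
#' @return `data`, invisibly, if valid; otherwise an error of class
#'   `chartscreen_schema_error` or `chartscreen_validation_error`.
#' @export
validate_cohort <- function(data, require_outcomes = FALSE) {
  sch <- cohort_schema()
  needed <- sch$column[sch$required]
  if (require_outcomes) needed <- union(needed, sch$column[sch$block == "outcome5"])
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("missing mandatory columns: ", paste(missing_cols, collapse = ", ")),
      class = "chartscreen_schema_error", columns = missing_cols
    )
  }
  dup <- unique(data$child_id[duplicated(data$child_id)])
  if (length(dup) > 0) {
    rlang::abort(
      paste0("duplicate child_id values: ", paste(dup, collapse = ", ")),
      class = "chartscreen_validation_error", duplicates = dup
    )
  }
  problems <- character()
  for (i in seq_len(nrow(sch))) {
    row <- sch[i, ]
    if (!row$column %in% names(data)) next
    x <- data[[row$column]]
    bad <- switch(row$type,
      character = !is.character(x),
      numeric = !is.numeric(x),
      count = !(is.numeric(x) && all(is.na(x) | (x >= 0 & x == round(x)))),
      logical = !is.logical(x),
      ordinal = !(is.factor(x) && identical(levels(x), schema_levels(row)))
    )
    if (isTRUE(bad)) problems <- c(problems, row$column)
  }
  if (length(problems) > 0) {
    rlang::abort(
      paste0("columns violating schema types/ranges: ", paste(problems, collapse = ", ")),
      class = "chartscreen_validation_error", columns = problems
    )
  }
  invisible(data)
}
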