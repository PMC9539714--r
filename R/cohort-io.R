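#' Read a child-level cohort from CSV
#'
#' Reads a cohort file in the documented dialect (see [cohort_schema()]):
#' comma-separated, UTF-8, lowercase snake_case header, booleans as 0/1,
#' empty cell = unknown. Every cell is parsed against the schema; a cell
#' that is non-empty but unparseable or outside its allowed range (for
#' example a wheeze count of `-1`) is recorded as unknown and counted, with
#' one warning summarising all affected columns. No row is ever silently
#' dropped and row order is preserved.
#'
#' @param path Path to a cohort CSV file.
#' @param schema_version Schema version string; only `"1"` exists.
#' @return A tibble of class `chart_cohort` with typed columns. The
#'   attribute `"parse_summary"` (also via [cohort_issues()]) holds one row
#'   per column with `n_missing` (empty cells) and `n_invalid` (unparseable
#'   or out-of-range cells coerced to unknown).
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, schema_version = "1") {
  stopifnot(identical(schema_version, "1"))
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "chartscreen_io_error")
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  sch <- cohort_schema()
  mandatory <- sch$column[sch$required]
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("missing mandatory columns: ", paste(missing_cols, collapse = ", ")),
      class = "chartscreen_schema_error", columns = missing_cols
    )
  }
  known <- intersect(sch$column, names(raw))
  out <- tibble::tibble(.rows = nrow(raw))
  summary <- vector("list", length(known))
  for (k in seq_along(known)) {
    row <- sch[sch$column == known[k], ]
    coerced <- coerce_column(raw[[known[k]]], row)
    out[[known[k]]] <- coerced$values
    summary[[k]] <- tibble::tibble(
      column = known[k],
      n_missing = sum(is.na(coerced$values)),
      n_invalid = coerced$n_invalid
    )
  }
  summary <- dplyr::bind_rows(summary)
  invalid <- summary[summary$n_invalid > 0, ]
  if (nrow(invalid) > 0) {
    rlang::warn(paste0(
      "cells coerced to unknown (unparseable or out of range): ",
      paste0(invalid$column, " (", invalid$n_invalid, ")", collapse = ", ")
    ), class = "chartscreen_parse_warning")
  }
  dup <- unique(out$child_id[duplicated(out$child_id)])
  if (length(dup) > 0) {
    rlang::abort(
      paste0("duplicate child_id values: ", paste(dup, collapse = ", ")),
      class = "chartscreen_validation_error", duplicates = dup
    )
  }
  structure(out,
    class = c("chart_cohort", class(out)),
    parse_summary = summary, schema_version = schema_version
  )
}

#' Per-column parse summary of a cohort read from disk
#'
#' @param data A `chart_cohort` tibble from [read_cohort()].
#' @return Tibble with `column`, `n_missing`, `n_invalid`.
#' @export
cohort_issues <- function(data) {
  attr(data, "parse_summary")
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: logicals become 0/1, ordinals their level
#' labels, unknowns empty cells. `read_cohort(write_cohort(x))` restores `x`
#' field for field.
#'
#' @param data A cohort tibble; validated with [validate_cohort()] first.
#' @param path Output file path.
#' @return The number of data rows written, invisibly.
#' @export
write_cohort <- function(data, path) {
  validate_cohort(data)
  sch <- cohort_schema()
  cols <- intersect(sch$column, names(data))
  ser <- data[, cols, drop = FALSE]
  for (nm in cols) {
    x <- ser[[nm]]
    if (is.logical(x)) ser[[nm]] <- as.integer(x)
    if (is.factor(x)) ser[[nm]] <- as.character(x)
  }
  readr::write_csv(ser, path, na = "", progress = FALSE)
  invisible(nrow(ser))
}
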