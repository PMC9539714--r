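#' mAPI rule configuration
#'
#' Loads the versioned modified Asthma Predictive Index definition shipped
#' with the package (wheeze-frequency gate of 4 or more episodes per year,
#' major criteria parental asthma / eczema / aeroallergen sensitisation,
#' minor criteria food sensitisation / wheeze apart from colds / blood
#' eosinophils at or above 4 percent; positive when the gate holds together
#' with at least 1 major or 2 minor criteria). Pass a modified list to
#' [classify_mapi()] to evaluate a variant.
#'
#' @param path Optional path to an alternative YAML rules file.
#' @return Named list with elements `version`, `min_wheeze_episodes`,
#'   `min_major`, `min_minor`, `major_criteria`, `minor_criteria`.
#' @export
mapi_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mapi_rules.yaml", package = "chartscreen")
  }
  rules <- yaml::read_yaml(path)
  stopifnot(
    is.numeric(rules$min_wheeze_episodes),
    length(rules$major_criteria) >= rules$min_major,
    length(rules$minor_criteria) >= rules$min_minor
  )
  rules
}

#' Classify children with the modified Asthma Predictive Index
#'
#' The mAPI needs the atopy block (skin-prick and blood-test derived
#' fields); children missing any required field are reported indeterminate
#' rather than assumed negative, mirroring evaluations restricted to
#' children with available test data. Indeterminate and evaluable children
#' always partition the cohort.
#'
#' @param data Cohort tibble carrying the atopy block columns.
#' @param rules Rule configuration, see [mapi_rules()].
#' @return Tibble with `child_id`, `positive` (logical, `NA` when
#'   indeterminate), `wheeze_gate`, `n_major`, `n_minor`, `indeterminate`,
#'   and `missing_fields` (list column).
#' @export
classify_mapi <- function(data, rules = mapi_rules()) {
  fields <- c(
    "wheeze_episodes_last_12mo",
    rules$major_criteria, rules$minor_criteria
  )
  absent <- setdiff(fields, names(data))
  if (length(absent) > 0) {
    rlang::abort(
      paste0("columns required for mAPI absent: ", paste(absent, collapse = ", ")),
      class = "chartscreen_schema_error", columns = absent
    )
  }
  block <- data[, fields, drop = FALSE]
  miss <- is.na(block)
  indeterminate <- rowSums(miss) > 0
  gate <- data$wheeze_episodes_last_12mo >= rules$min_wheeze_episodes
  n_major <- rowSums(block[, rules$major_criteria, drop = FALSE], na.rm = TRUE)
  n_minor <- rowSums(block[, rules$minor_criteria, drop = FALSE], na.rm = TRUE)
  positive <- gate & (n_major >= rules$min_major | n_minor >= rules$min_minor)
  positive[indeterminate] <- NA
  tibble::tibble(
    child_id = data$child_id,
    positive = positive,
    wheeze_gate = gate,
    n_major = n_major,
    n_minor = n_minor,
    indeterminate = indeterminate,
    missing_fields = lapply(
      seq_len(nrow(data)),
      function(i) fields[miss[i, ]]
    )
  )
}

#' Physician asthma-diagnosis labels
#'
#' Turns a recorded physician diagnosis into a binary predictor or outcome
#' under an explicit definition variant. The variant is a required, named
#' part of every downstream report because published accuracy figures can
#' hinge on whether "possible asthma" counts as positive.
#'
#' @param data Cohort tibble.
#' @param definition One of `in_study_definite` (study-physician definite
#'   asthma only), `in_study_definite_or_possible`, or `external_reported`
#'   (parent-reported external physician diagnosis).
#' @param at `"age3"` reads the preschool block (`asthma_dx_in_study`,
#'   `asthma_dx_external`), `"age5"` the outcome block (`out5_` columns).
#' @return Logical vector, `NA` where the label is missing.
#' @export
physician_label <- function(data,
                            definition = c(
                              "in_study_definite",
                              "in_study_definite_or_possible",
                              "external_reported"
                            ),
                            at = c("age3", "age5")) {
  definition <- match.arg(definition)
  at <- match.arg(at)
  pre <- if (at == "age3") "" else "out5_"
  if (definition == "external_reported") {
    return(data[[paste0(pre, "asthma_dx_external")]])
  }
  dx <- data[[paste0(pre, "asthma_dx_in_study")]]
  out <- dx == "definite"
  if (definition == "in_study_definite_or_possible") {
    out <- dx %in% c("definite", "possible")
    out[is.na(dx)] <- NA
  }
  out
}
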