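#' Persistent wheeze at school entry
#'
#' Persistent wheeze is defined as 2 or more wheeze episodes annually at
#' both the preschool (3-year) and school-entry (5-year) assessments, each
#' over its 12-month recall window. The outcome is indeterminate when either
#' count is unknown, except that a known count below 2 at one timepoint
#' already settles the answer as `FALSE`.
#'
#' @param data Cohort tibble with both `wheeze_episodes_last_12mo` and
#'   `out5_wheeze_episodes_last_12mo`.
#' @return Logical vector (`NA` = indeterminate).
#' @export
derive_persistent_wheeze <- function(data) {
  (data$wheeze_episodes_last_12mo >= 2) & (data$out5_wheeze_episodes_last_12mo >= 2)
}

#' Asthma at school entry under a named definition
#'
#' The criterion-standard outcome is the in-study specialist diagnosis at
#' the 5-year visit; the definition variant (definite only, definite or
#' possible, or parent-reported external diagnosis) must be named
#' explicitly and is carried through to every report.
#'
#' @param data Cohort tibble with the outcome block.
#' @param definition See [physician_label()].
#' @return Logical vector (`NA` = indeterminate).
#' @export
derive_asthma <- function(data, definition = c(
                            "in_study_definite",
                            "in_study_definite_or_possible",
                            "external_reported"
                          )) {
  physician_label(data, definition = match.arg(definition), at = "age5")
}

#' Health-care burden components at school entry
#'
#' Burden is use of inhaled or oral corticosteroids or bronchodilators, or
#' an ED visit or hospitalisation for asthma and/or wheeze, over the
#' 12 months before the 5-year assessment. Components are reported
#' separately (they are evaluated separately downstream) along with their
#' disjunction; missing fields propagate by three-valued logic so
#' `any_burden` is `TRUE` as soon as one component is known present.
#'
#' @param data Cohort tibble with the outcome block.
#' @return Tibble with `child_id` and logical columns `ics`,
#'   `ocs_or_bronchodilator`, `ed_or_hospitalization`, `any_burden`.
#' @export
derive_burden <- function(data) {
  ics <- data$out5_ics_use
  ocs_bd <- data$out5_ocs_use | data$out5_bronchodilator_use
  ed <- data$out5_ed_or_hosp_wheeze
  tibble::tibble(
    child_id = data$child_id,
    ics = ics,
    ocs_or_bronchodilator = ocs_bd,
    ed_or_hospitalization = ed,
    any_burden = ics | ocs_bd | ed
  )
}

#' All study outcomes in one table
#'
#' Convenience wrapper deriving persistent wheeze, asthma (under the chosen
#' definition) and the burden components per child. Children indeterminate
#' for one outcome remain evaluable for the others (complete-case per
#' outcome).
#'
#' @inheritParams derive_asthma
#' @return Tibble with `child_id`, `persistent_wheeze`, `asthma`,
#'   `asthma_definition`, and the [derive_burden()] columns.
#' @export
derive_outcomes <- function(data, definition = "in_study_definite") {
  burden <- derive_burden(data)
  tibble::tibble(
    child_id = data$child_id,
    persistent_wheeze = derive_persistent_wheeze(data),
    asthma = derive_asthma(data, definition),
    asthma_definition = definition,
    ics = burden$ics,
    ocs_or_bronchodilator = burden$ocs_or_bronchodilator,
    ed_or_hospitalization = burden$ed_or_hospitalization,
    any_burden = burden$any_burden
  )
}
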