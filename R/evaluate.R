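#' Predictor-by-outcome diagnostic accuracy table
#'
#' Evaluates each requested preschool predictor against each school-entry
#' outcome on the same cohort tibble and returns one tidy row per
#' predictor-outcome-metric combination (sensitivity, specificity, PPV,
#' NPV, AUROC). The CHART predictor is binarised as high risk versus the
#' moderate and low tiers together; children indeterminate for a predictor
#' or outcome are excluded from that pair only (complete-case per pair),
#' and the per-pair evaluable n is reported. Undefined metrics (zero
#' denominator, absent outcome class) appear as explicit `NA` rows rather
#' than being dropped.
#'
#' @param data Cohort tibble with preschool and outcome blocks.
#' @param predictors Subset of `"chart"`, `"mapi"`, `"physician_in_study"`,
#'   `"physician_external"`.
#' @param outcomes Subset of `"persistent_wheeze"`, `"asthma"`, `"ics"`,
#'   `"ocs_or_bronchodilator"`, `"ed_or_hospitalization"`, `"any_burden"`.
#' @param asthma_definition Definition variant for the asthma outcome
#'   (see [derive_asthma()]); named in the output.
#' @param physician_definition Definition variant for the in-study
#'   physician predictor at the preschool assessment.
#' @param conf_level Confidence level for all intervals.
#' @param auroc_ci `"delong"` or `"bootstrap"`.
#' @return Tibble with columns `predictor`, `outcome`, `metric`,
#'   `estimate`, `conf_low`, `conf_high`, `ci_method`, `n_evaluable`,
#'   plus `asthma_definition` and `physician_definition` tags.
#' @export
evaluation_table <- function(data,
                             predictors = c("chart", "mapi", "physician_in_study", "physician_external"),
                             outcomes = c("persistent_wheeze", "asthma", "ics", "ocs_or_bronchodilator", "ed_or_hospitalization", "any_burden"),
                             asthma_definition = "in_study_definite",
                             physician_definition = "in_study_definite",
                             conf_level = 0.95,
                             auroc_ci = c("delong", "bootstrap")) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  auroc_ci <- match.arg(auroc_ci)

  pred_vectors <- list()
  for (p in predictors) {
    pred_vectors[[p]] <- switch(p,
      chart = {
        cat <- chart_classify(data)$category
        out <- cat == "high"
        out
      },
      mapi = classify_mapi(data)$positive,
      physician_in_study = physician_label(data,
        definition = physician_definition, at = "age3"
      ),
      physician_external = physician_label(data,
        definition = "external_reported", at = "age3"
      )
    )
  }
  outcome_tbl <- derive_outcomes(data, definition = asthma_definition)

  rows <- list()
  for (p in predictors) {
    for (o in outcomes) {
      cc <- confusion(pred_vectors[[p]], outcome_tbl[[o]])
      block <- dplyr::bind_rows(
        sensitivity(cc, conf_level),
        specificity(cc, conf_level),
        ppv(cc, conf_level),
        npv(cc, conf_level),
        auroc_binary(cc, ci_method = auroc_ci, conf_level = conf_level)
      )
      block$predictor <- p
      block$outcome <- o
      rows[[paste(p, o)]] <- block
    }
  }
  out <- dplyr::bind_rows(rows)
  out$asthma_definition <- asthma_definition
  out$physician_definition <- physician_definition
  dplyr::select(
    out, "predictor", "outcome", "metric", "estimate",
    "conf_low", "conf_high", "ci_method", "n_evaluable",
    "asthma_definition", "physician_definition"
  )
}

#' Format a 0-1 estimate as a percentage string
#'
#' Reporting helper: percentages to one decimal place, the presentation
#' convention used throughout the package's reports.
#'
#' @param x Numeric vector on the 0-1 scale.
#' @return Character vector like `"91.1%"`; `NA` stays `NA`.
#' @export
format_pct <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.1f%%", 100 * x))
}
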