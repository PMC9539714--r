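#' The CHART decision rule table
#'
#' CHART stratifies a preschool child into one of three asthma-risk tiers
#' from the 12-month symptom recall: children with 2 or more wheeze episodes
#' in the past year together with at least one supporting criterion (ED
#' visit, hospitalisation, asthma-medication use, or frequent dry cough
#' apart from colds) are high risk; children with no recent wheeze and at
#' most one lifetime wheeze episode, all before the past 12 months — which
#' includes cough-only and fully asymptomatic children — are low risk;
#' everyone else (any single recent wheeze episode, recurrent wheeze without
#' a supporting criterion, or recurrent wheeze confined to the remote past)
#' is moderate risk. Each tier carries a follow-up action: immediate further
#' evaluation (high), reassessment in 6 months (moderate) or 12 months
#' (low).
#'
#' The complete mapping ships as a versioned, human-readable CSV so the
#' reconstruction of the branch structure can be audited and corrected
#' without an API change; this function returns it as a tibble. Bands are
#' `recent_wheeze_band` (episodes in the past 12 months: `0`, `1`, `2+`)
#' and `prior_wheeze_band` (episodes before that window: `0`, `1`, `2+`).
#'
#' @return Tibble with one row per band combination and columns
#'   `category`, `rule_id`, `follow_up`.
#' @export
chart_rule_table <- function() {
  path <- system.file("extdata", "chart_rule_table.csv", package = "chartscreen")
  readr::read_csv(path, col_types = readr::cols(
    rule_version = "i", recent_wheeze_band = "c", prior_wheeze_band = "c",
    any_supporting_criterion = "i", category = "c", rule_id = "c",
    follow_up = "c"
  ))
}

chart_categories <- c("low", "moderate", "high")

follow_up_for <- function(category) {
  c(
    low = "reassess_12_months", moderate = "reassess_6_months",
    high = "further_evaluation_now"
  )[as.character(category)]
}

#' Evaluate the CHART supporting criteria
#'
#' The four supporting criteria are evaluated over the same 12-month recall
#' window as the wheeze count: `asthma_medication` (any of inhaled
#' corticosteroid, oral corticosteroid, or bronchodilator use), `ed_visit`
#' and `hospitalization` (respective wheeze/asthma utilisation count above
#' zero), and `frequent_dry_cough` (the `frequent` level of dry cough apart
#' from colds). Missing inputs propagate as three-valued logic: a criterion
#' is `TRUE` as soon as one contributing field establishes it, `FALSE` only
#' when all contributing fields are known negative, and `NA` otherwise.
#'
#' @param data Cohort tibble with the preschool symptom block.
#' @return Tibble with `child_id`, one logical column per criterion,
#'   `criteria` (list column naming criteria known to be met), `n_criteria`,
#'   `indeterminate` (`TRUE` when an unknown field could still add a
#'   criterion), and `missing_fields` (list column of the fields
#'   responsible).
#' @export
chart_supporting_criteria <- function(data) {
  med <- data$ics_use_last_12mo | data$ocs_use_last_12mo |
    data$bronchodilator_use_last_12mo
  ed <- data$ed_visits_wheeze_last_12mo > 0
  hosp <- data$hospitalizations_wheeze_last_12mo > 0
  fc <- data$dry_cough_without_cold == "frequent"
  crit <- cbind(
    ed_visit = ed, hospitalization = hosp,
    asthma_medication = med, frequent_dry_cough = fc
  )
  met <- lapply(seq_len(nrow(data)), function(i) colnames(crit)[which(crit[i, ])])
  med_na <- cbind(
    ics_use_last_12mo = is.na(data$ics_use_last_12mo),
    ocs_use_last_12mo = is.na(data$ocs_use_last_12mo),
    bronchodilator_use_last_12mo = is.na(data$bronchodilator_use_last_12mo)
  )
  missing_fields <- lapply(seq_len(nrow(data)), function(i) {
    c(
      if (is.na(ed[i])) "ed_visits_wheeze_last_12mo",
      if (is.na(hosp[i])) "hospitalizations_wheeze_last_12mo",
      if (is.na(med[i])) colnames(med_na)[med_na[i, ]],
      if (is.na(fc[i])) "dry_cough_without_cold"
    )
  })
  tibble::tibble(
    child_id = data$child_id,
    ed_visit = ed, hospitalization = hosp,
    asthma_medication = med, frequent_dry_cough = fc,
    criteria = met,
    n_criteria = rowSums(crit, na.rm = TRUE),
    indeterminate = is.na(ed) | is.na(hosp) | is.na(med) | is.na(fc),
    missing_fields = missing_fields
  )
}

#' Classify children with CHART
#'
#' Applies the CHART rule (see [chart_rule_table()]) to every child.
#' Classification is deterministic and total on complete records. When core
#' fields are unknown the rule is evaluated under every completion of the
#' missing values: a category is still returned if all completions agree
#' (for instance, two recent wheeze episodes plus known medication use is
#' high risk regardless of a missing ED-visit count); otherwise the category
#' is `NA` with `indeterminate = TRUE` and the blocking fields listed —
#' never a silent default tier.
#'
#' @param data Cohort tibble with the preschool symptom block.
#' @param age_window Applicable age range in years; children assessed
#'   outside it are still classified but flagged (`age_out_of_window`) with
#'   a warning, since the rule was developed for roughly 2- to 3-year-olds.
#' @return Tibble with `child_id`, `category` (ordered factor
#'   low < moderate < high, `NA` when indeterminate), `supporting_criteria`
#'   (list column), `fired_rule`, `follow_up`, `indeterminate`,
#'   `missing_fields`, `age_out_of_window`.
#' @examples
#' kid <- tibble::tibble(
#'   child_id = "a", age_years = 3.1,
#'   wheeze_episodes_last_12mo = 3L, wheeze_episodes_prior = 0L,
#'   dry_cough_without_cold = factor("none", c("none", "occasional", "frequent")),
#'   cough_episodes_last_12mo = 0L,
#'   ics_use_last_12mo = FALSE, ocs_use_last_12mo = FALSE,
#'   bronchodilator_use_last_12mo = TRUE,
#'   ed_visits_wheeze_last_12mo = 0L, hospitalizations_wheeze_last_12mo = 0L
#' )
#' chart_classify(kid)$category
#' @export
chart_classify <- function(data, age_window = c(1.5, 4.0)) {
  n <- nrow(data)
  crit <- chart_supporting_criteria(data)
  support <- crit$ed_visit | crit$hospitalization |
    crit$asthma_medication | crit$frequent_dry_cough
  w12 <- data$wheeze_episodes_last_12mo
  prior <- data$wheeze_episodes_prior

  category <- rep(NA_character_, n)
  rule <- rep(NA_character_, n)

  known_w <- !is.na(w12)
  # recurrent recent wheeze: tier decided by the supporting criteria
  idx <- known_w & w12 >= 2 & !is.na(support) & support
  category[idx] <- "high"; rule[idx] <- "high_recent_wheeze_with_support"
  idx <- known_w & w12 >= 2 & !is.na(support) & !support
  category[idx] <- "moderate"; rule[idx] <- "moderate_recent_wheeze_no_support"
  # a single recent episode is moderate whatever else holds
  idx <- known_w & w12 == 1
  category[idx] <- "moderate"; rule[idx] <- "moderate_single_recent_wheeze"
  # no recent wheeze: prior history decides low vs moderate
  idx <- known_w & w12 == 0 & !is.na(prior) & prior <= 1
  category[idx] <- "low"; rule[idx] <- "low_no_recent_wheeze"
  idx <- known_w & w12 == 0 & !is.na(prior) & prior >= 2
  category[idx] <- "moderate"; rule[idx] <- "moderate_remote_recurrent_wheeze"
  # unknown recent count: every completion is moderate only when a high tier
  # is excluded (no criterion can be met) and a low tier is excluded
  # (recurrent remote wheeze on record)
  idx <- !known_w & !is.na(support) & !support & !is.na(prior) & prior >= 2
  category[idx] <- "moderate"; rule[idx] <- "moderate_any_completion"

  indeterminate <- is.na(category)
  missing_fields <- vector("list", n)
  for (i in which(indeterminate)) {
    f <- character()
    if (is.na(w12[i])) f <- c(f, "wheeze_episodes_last_12mo")
    if ((is.na(w12[i]) || w12[i] >= 2) && is.na(support[i])) {
      f <- c(f, crit$missing_fields[[i]])
    }
    if ((is.na(w12[i]) || w12[i] == 0) && is.na(prior[i])) {
      f <- c(f, "wheeze_episodes_prior")
    }
    missing_fields[[i]] <- unique(f)
  }
  missing_fields[!indeterminate] <- list(character())

  out_of_window <- !is.na(data$age_years) &
    (data$age_years < age_window[1] | data$age_years > age_window[2])
  if (any(out_of_window)) {
    rlang::warn(paste0(
      sum(out_of_window), " child(ren) assessed outside the ",
      age_window[1], "-", age_window[2],
      " year applicability window; classification returned with a flag"
    ), class = "chartscreen_age_warning")
  }

  category <- factor(category, levels = chart_categories, ordered = TRUE)
  tibble::tibble(
    child_id = data$child_id,
    category = category,
    supporting_criteria = crit$criteria,
    fired_rule = rule,
    follow_up = unname(follow_up_for(category)),
    indeterminate = indeterminate,
    missing_fields = missing_fields,
    age_out_of_window = out_of_window
  )
}

#' Classify a whole cohort and summarise tier frequencies
#'
#' @inheritParams chart_classify
#' @return A list with `assessments` (per-child tibble from
#'   [chart_classify()], input order preserved) and `summary` (one row per
#'   tier plus one for indeterminate children, with counts and the share of
#'   classifiable children; tier counts sum to the number of classifiable
#'   children).
#' @export
chart_classify_cohort <- function(data, age_window = c(1.5, 4.0)) {
  assessments <- chart_classify(data, age_window = age_window)
  n_complete <- sum(!assessments$indeterminate)
  tiers <- table(factor(assessments$category, levels = chart_categories))
  summary <- tibble::tibble(
    category = c(chart_categories, "indeterminate"),
    n = c(as.integer(tiers), sum(assessments$indeterminate)),
    proportion = c(
      if (n_complete > 0) as.integer(tiers) / n_complete else rep(NA_real_, 3),
      NA_real_
    )
  )
  list(assessments = assessments, summary = summary)
}
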