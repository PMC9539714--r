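# Builders for in-memory cohort rows used across the test files.

dry_cough_levels <- c("none", "occasional", "frequent")
dx_levels <- c("definite", "possible", "none")

# One schema-typed child row; override any field by name. NA is allowed and
# means "unknown".
snapshot <- function(...) {
  defaults <- tibble::tibble(
    child_id = "s1",
    age_years = 3.0,
    wheeze_episodes_last_12mo = 0L,
    wheeze_episodes_prior = 0L,
    dry_cough_without_cold = factor("none", dry_cough_levels),
    cough_episodes_last_12mo = 0L,
    ics_use_last_12mo = FALSE,
    ocs_use_last_12mo = FALSE,
    bronchodilator_use_last_12mo = FALSE,
    ed_visits_wheeze_last_12mo = 0L,
    hospitalizations_wheeze_last_12mo = 0L,
    parental_asthma = FALSE,
    eczema_dx = FALSE,
    aeroallergen_sensitized = FALSE,
    food_sensitized = FALSE,
    eosinophils_ge_4pct = FALSE,
    wheeze_apart_from_colds = FALSE,
    asthma_dx_in_study = factor("none", dx_levels),
    asthma_dx_external = FALSE,
    out5_age_years = 5.1,
    out5_wheeze_episodes_last_12mo = 0L,
    out5_asthma_dx_in_study = factor("none", dx_levels),
    out5_asthma_dx_external = FALSE,
    out5_ics_use = FALSE,
    out5_ocs_use = FALSE,
    out5_bronchodilator_use = FALSE,
    out5_ed_or_hosp_wheeze = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) {
    v <- mods[[nm]]
    if (nm %in% c("dry_cough_without_cold")) v <- factor(v, dry_cough_levels)
    if (nm %in% c("asthma_dx_in_study", "out5_asthma_dx_in_study")) v <- factor(v, dx_levels)
    defaults[[nm]] <- v
  }
  defaults
}

# Stack several snapshot() rows with distinct ids.
snapshots <- function(...) {
  rows <- list(...)
  out <- dplyr::bind_rows(rows)
  out$child_id <- sprintf("s%03d", seq_len(nrow(out)))
  out
}

# Generator defaults with all missingness switched off.
params_no_missing <- function() {
  p <- chartscreen::sim_default_params()
  for (k in names(p$missingness)) p$missingness[[k]] <- 0
  p
}

# Brute-force all-pairs tie-corrected concordance; the independent AUROC
# oracle (quadratic, only for small fixtures).
auc_all_pairs <- function(scores, truths) {
  pos <- scores[truths]
  neg <- scores[!truths]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
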