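# Exhaustive factorial grid of small field values with all four supporting
# criteria toggled; complete snapshots only.
rule_grid <- function() {
  g <- expand.grid(
    w12 = 0:3, prior = 0:2,
    ed = c(0L, 1L), hosp = c(0L, 1L),
    med = c(FALSE, TRUE), fc = c(FALSE, TRUE)
  )
  rows <- purrr::pmap(g, function(w12, prior, ed, hosp, med, fc) {
    snapshot(
      wheeze_episodes_last_12mo = as.integer(w12),
      wheeze_episodes_prior = as.integer(prior),
      ed_visits_wheeze_last_12mo = ed,
      hospitalizations_wheeze_last_12mo = hosp,
      ics_use_last_12mo = med,
      dry_cough_without_cold = if (fc) "frequent" else "none"
    )
  })
  cohort <- dplyr::bind_rows(rows)
  cohort$child_id <- sprintf("g%03d", seq_len(nrow(cohort)))
  list(grid = g, cohort = cohort)
}

test_that("classification matches the shipped rule table over the full grid", {
  rg <- rule_grid()
  got <- chart_classify(rg$cohort)
  expect_false(any(got$indeterminate))
  band <- c("0", "1", "2+", "2+")[rg$grid$w12 + 1]
  prior_band <- c("0", "1", "2+")[pmin(rg$grid$prior, 2) + 1]
  support <- as.integer(
    rg$grid$ed > 0 | rg$grid$hosp > 0 | rg$grid$med | rg$grid$fc
  )
  tab <- chart_rule_table()
  key <- paste(tab$recent_wheeze_band, tab$prior_wheeze_band,
    tab$any_supporting_criterion,
    sep = "|"
  )
  expected <- tab$category[match(paste(band, prior_band, support, sep = "|"), key)]
  expect_equal(as.character(got$category), expected)
  expect_equal(
    got$follow_up,
    tab$follow_up[match(paste(band, prior_band, support, sep = "|"), key)]
  )
})

test_that("high risk requires recurrent recent wheeze plus a criterion, exhaustively", {
  rg <- rule_grid()
  got <- chart_classify(rg$cohort)
  is_high <- got$category == "high"
  qualifies <- rg$grid$w12 >= 2 &
    (rg$grid$ed > 0 | rg$grid$hosp > 0 | rg$grid$med | rg$grid$fc)
  expect_equal(is_high, qualifies)
  expect_true(all(lengths(got$supporting_criteria[is_high]) >= 1))
})

test_that("worked single-child classifications", {
  expect_equal(as.character(chart_classify(
    snapshot(wheeze_episodes_last_12mo = 3L, bronchodilator_use_last_12mo = TRUE)
  )$category), "high")
  # cough episodes plus one remote wheeze episode stays low risk
  expect_equal(as.character(chart_classify(
    snapshot(
      wheeze_episodes_last_12mo = 0L, wheeze_episodes_prior = 1L,
      cough_episodes_last_12mo = 4L,
      dry_cough_without_cold = "occasional"
    )
  )$category), "low")
  # recurrent recent wheeze without any supporting criterion is not high
  expect_equal(as.character(chart_classify(
    snapshot(wheeze_episodes_last_12mo = 2L)
  )$category), "moderate")
  expect_equal(as.character(chart_classify(snapshot())$category), "low")
})

test_that("category is monotone in wheeze count and in supporting criteria", {
  base_rows <- rule_grid()$cohort
  got <- chart_classify(base_rows)
  # adding one more recent wheeze episode never lowers the tier
  bumped <- base_rows
  bumped$wheeze_episodes_last_12mo <- bumped$wheeze_episodes_last_12mo + 1L
  got_up <- chart_classify(bumped)
  expect_true(all(got_up$category >= got$category))
  # adding a supporting criterion never lowers the tier
  with_crit <- base_rows
  with_crit$ocs_use_last_12mo <- TRUE
  got_crit <- chart_classify(with_crit)
  expect_true(all(got_crit$category >= got$category))
})

test_that("classification is deterministic and total on complete snapshots", {
  rg <- rule_grid()
  a <- chart_classify(rg$cohort)
  b <- chart_classify(rg$cohort)
  expect_identical(a, b)
  expect_false(any(is.na(a$category)))
})

test_that("missing fields give an indeterminate result, not a default tier", {
  out <- chart_classify(snapshot(
    wheeze_episodes_last_12mo = 2L,
    ics_use_last_12mo = NA, ocs_use_last_12mo = NA,
    bronchodilator_use_last_12mo = NA,
    ed_visits_wheeze_last_12mo = NA, hospitalizations_wheeze_last_12mo = NA,
    dry_cough_without_cold = NA
  ))
  expect_true(out$indeterminate)
  expect_true(is.na(out$category))
  expect_true("ed_visits_wheeze_last_12mo" %in% out$missing_fields[[1]])
  # but a known criterion settles the tier despite other unknowns
  settled <- chart_classify(snapshot(
    wheeze_episodes_last_12mo = 2L, ics_use_last_12mo = TRUE,
    ed_visits_wheeze_last_12mo = NA
  ))
  expect_equal(as.character(settled$category), "high")
  # and an unknown wheeze count can still be moderate when every
  # completion agrees
  agreed <- chart_classify(snapshot(
    wheeze_episodes_last_12mo = NA, wheeze_episodes_prior = 3L
  ))
  expect_equal(as.character(agreed$category), "moderate")
})

test_that("supporting criteria are reported as a set with missingness detail", {
  got <- chart_supporting_criteria(snapshots(
    snapshot(ics_use_last_12mo = TRUE),
    snapshot(),
    snapshot(ed_visits_wheeze_last_12mo = 1L, dry_cough_without_cold = "frequent"),
    snapshot(ocs_use_last_12mo = NA)
  ))
  expect_equal(got$criteria[[1]], "asthma_medication")
  expect_equal(got$criteria[[2]], character(0))
  expect_setequal(got$criteria[[3]], c("ed_visit", "frequent_dry_cough"))
  expect_true(got$indeterminate[4])
  expect_equal(got$missing_fields[[4]], "ocs_use_last_12mo")
  expect_false(any(got$indeterminate[1:3]))
})

test_that("cohort summary conserves counts and is permutation invariant", {
  sim <- simulate_cohort(n = 2000, seed = 5)
  res <- chart_classify_cohort(sim$cohort)
  tiers <- res$summary[res$summary$category %in% c("low", "moderate", "high"), ]
  expect_equal(sum(tiers$n), sum(!res$assessments$indeterminate))
  expect_equal(sum(res$summary$n), 2000)
  perm <- withr::with_seed(1, sample(nrow(sim$cohort)))
  res_perm <- chart_classify_cohort(sim$cohort[perm, ])
  expect_equal(res_perm$summary, res$summary)
  empty <- chart_classify_cohort(sim$cohort[0, ])
  expect_equal(nrow(empty$assessments), 0)
  expect_equal(sum(empty$summary$n), 0)
})

test_that("assessment outside the applicability window is flagged but returned", {
  expect_warning(
    out <- chart_classify(snapshot(age_years = 5.2)),
    class = "chartscreen_age_warning"
  )
  expect_true(out$age_out_of_window)
  expect_false(is.na(out$category))
})
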