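#' Default calibrated generator parameters
#'
#' Loads the shipped generator configuration
#' (`inst/extdata/sim_default.yaml`). Its defaults are calibrated — see
#' `scripts/calibrate_generator.R` in the source repository — so that the
#' generated preschool marginals reproduce the development cohort's
#' headline prevalences (any wheeze 16.5%, two or more wheeze episodes
#' 8.8%, bronchodilator use 9.8%, corticosteroid use 11.0%, ED visit or
#' hospitalisation 3.5%, risk tiers 7.1/23.8/69.1%) and the school-entry
#' outcome layer reproduces the qualitative operating characteristics
#' (high sensitivity for persistent wheeze, about one half for asthma).
#' The generator claims marginal plus qualitative operating-characteristic
#' fidelity only; the true joint symptom distribution of any real cohort
#' is richer than this two-class mixture.
#'
#' @param path Optional alternative YAML parameter file.
#' @return Nested named list of generator parameters.
#' @export
sim_default_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sim_default.yaml", package = "chartscreen")
  }
  yaml::read_yaml(path)
}

prob_in_01 <- function(x) all(is.finite(unlist(x))) && all(unlist(x) >= 0) && all(unlist(x) <= 1)

validate_sim_params <- function(p) {
  bad <- function(msg) {
    rlang::abort(paste0("inadmissible generator config: ", msg),
      class = "chartscreen_config_error"
    )
  }
  probs <- list(
    p$latent$p_prone,
    p$wheeze3$prone, p$wheeze3$nonprone,
    p$prior_wheeze$recent0$p0, p$prior_wheeze$recent0$p1, p$prior_wheeze$recent0$cont,
    p$prior_wheeze$recent_pos$p_any, p$prior_wheeze$recent_pos$cont,
    p$supporting$p_bronch, p$supporting$p_cort, p$supporting$p_both,
    p$supporting$p_ics_given_cort, p$supporting$p_ocs_given_cort,
    p$supporting$p_edh_given_med, p$supporting$p_edh_given_nomed,
    p$supporting$p_hosp_given_edh, p$supporting$p_hosp_only_given_hosp,
    p$supporting$p_freq_cough, p$supporting$p_occ_cough,
    p$atopy, p$dx3$p_definite, p$dx3$p_definite_band2_support,
    p$dx3$p_possible, p$dx3$p_external,
    p$persistence$cont5, p$persistence$p_w5_one_nonpersist,
    p$incident_wheeze5$p_any_prone, p$incident_wheeze5$p_any_nonprone,
    p$incident_wheeze5$cont,
    p$asthma5$p_possible_by_category, p$asthma5$p_external,
    p$missingness
  )
  if (!prob_in_01(probs)) bad("a probability lies outside [0, 1]")
  s <- p$supporting
  if (length(s$p_bronch) != 3 || length(s$p_cort) != 3 || length(s$p_both) != 3) {
    bad("per-band probability vectors must have length 3")
  }
  if (any(s$p_both > pmin(s$p_bronch, s$p_cort) + 1e-12)) {
    bad("joint medication probability exceeds a marginal")
  }
  if (any(s$p_bronch + s$p_cort - s$p_both > 1 + 1e-12)) {
    bad("medication union probability exceeds 1")
  }
  if (p$prior_wheeze$recent0$p0 + p$prior_wheeze$recent0$p1 > 1 + 1e-12) {
    bad("prior-wheeze category probabilities sum above 1")
  }
  invisible(p)
}

#' Build a validated cohort-generator configuration
#'
#' @param n Number of children (non-negative integer).
#' @param seed Integer random seed; every run with the same configuration
#'   is byte-identical.
#' @param params Generator parameters, defaulting to the calibrated
#'   [sim_default_params()]. Validated before any sampling: every
#'   probability must lie in `[0, 1]` and joint probabilities must be
#'   admissible.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n = 2500, seed = 1L, params = sim_default_params()) {
  if (!(length(n) == 1 && is.finite(n) && n >= 0 && n == round(n))) {
    rlang::abort("n must be a single non-negative integer",
      class = "chartscreen_config_error"
    )
  }
  if (!(length(seed) == 1 && is.finite(seed) && seed == round(seed))) {
    rlang::abort("seed must be a single integer",
      class = "chartscreen_config_error"
    )
  }
  validate_sim_params(params)
  structure(list(n = as.integer(n), seed = as.integer(seed), params = params),
    class = "cohort_config"
  )
}

rbern <- function(n, p) stats::runif(n) < p

# shifted geometric: value k >= shift with P(X >= k+1 | X >= k) = cont
rgeom_shift <- function(n, cont, shift = 1L) {
  shift + stats::rgeom(n, prob = 1 - cont)
}

sample_band_meds <- function(band, s) {
  n <- length(band)
  pb <- s$p_bronch[band]
  pc <- s$p_cort[band]
  pboth <- s$p_both[band]
  u <- stats::runif(n)
  bronch <- u < pb
  cort <- (u < pboth) | (u >= pb & u < pb + pc - pboth)
  ics <- cort & rbern(n, s$p_ics_given_cort)
  ocs <- cort & rbern(n, s$p_ocs_given_cort)
  ics[cort & !ics & !ocs] <- TRUE
  med <- bronch | cort
  edh <- rbern(n, ifelse(med, s$p_edh_given_med[band], s$p_edh_given_nomed[band]))
  hosp <- edh & rbern(n, s$p_hosp_given_edh)
  hosp_only <- hosp & rbern(n, s$p_hosp_only_given_hosp)
  ed_visits <- ifelse(edh & !hosp_only, 1L + stats::rpois(n, s$lambda_extra_ed), 0L)
  u2 <- stats::runif(n)
  cough <- ifelse(u2 < s$p_freq_cough[band], "frequent",
    ifelse(u2 < s$p_freq_cough[band] + s$p_occ_cough[band], "occasional", "none")
  )
  list(
    bronch = bronch, ics = ics, ocs = ocs, med = med,
    edh = edh, hosp = as.integer(hosp), ed_visits = as.integer(ed_visits),
    cough = cough
  )
}

#' Generate a synthetic preschool cohort
#'
#' Simulates child-level records with the dependence structure needed to
#' exercise the whole screening pipeline: a latent two-class mixture (a
#' small "wheeze-prone" class against the rest) drives the preschool wheeze
#' episode counts (zero-inflated shifted-geometric per class); medication
#' use, ED visits/hospitalisations and dry cough are drawn conditionally on
#' the recent-wheeze band (ED nested within medication users, matching the
#' strong observed overlap); physician labels and the atopy block follow;
#' and school-entry outcomes (wheeze persistence, specialist asthma
#' diagnosis, burden components) depend on the latent class and the
#' preschool presentation. Missingness is applied last,
#' missing-completely-at-random per field (block-wise for the atopy and
#' outcome blocks).
#'
#' @param config A [cohort_config()]; alternatively pass `n`, `seed`,
#'   `params` directly.
#' @inheritParams cohort_config
#' @return Object of class `chart_sim`: list with `cohort` (schema-typed
#'   tibble, see [cohort_schema()]), `latent` (tibble with the ground-truth
#'   class and pre-missingness tier per child, kept separate so recovery
#'   can be scored), and `config`.
#' @examples
#' sim <- simulate_cohort(n = 200, seed = 42)
#' marginal_report(sim)
#' @export
simulate_cohort <- function(config = NULL, n = 2500, seed = 1L,
                            params = sim_default_params()) {
  if (is.null(config)) config <- cohort_config(n = n, seed = seed, params = params)
  stopifnot(inherits(config, "cohort_config"))
  p <- config$params
  n <- config$n
  cohort <- withr::with_seed(config$seed, {
    z <- rbern(n, p$latent$p_prone)
    p_any <- ifelse(z, p$wheeze3$prone$p_any, p$wheeze3$nonprone$p_any)
    p_cont <- ifelse(z, p$wheeze3$prone$p_cont, p$wheeze3$nonprone$p_cont)
    w3 <- ifelse(rbern(n, p_any), rgeom_shift(n, p_cont), 0L)
    band <- pmin(w3, 2L) + 1L

    # wheeze history before the recall window
    pr0 <- p$prior_wheeze$recent0
    u <- stats::runif(n)
    prior0 <- ifelse(u < pr0$p0, 0L,
      ifelse(u < pr0$p0 + pr0$p1, 1L, rgeom_shift(n, pr0$cont, 2L))
    )
    prp <- p$prior_wheeze$recent_pos
    prior_pos <- ifelse(rbern(n, prp$p_any), rgeom_shift(n, prp$cont), 0L)
    prior <- ifelse(w3 == 0, prior0, prior_pos)

    m3 <- sample_band_meds(band, p$supporting)
    support <- m3$med | m3$edh | (m3$cough == "frequent")
    high <- w3 >= 2 & support
    low <- w3 == 0 & prior <= 1
    tier <- ifelse(high, "high", ifelse(low, "low", "moderate"))

    # preschool physician labels
    p_def3 <- ifelse(band == 3 & support, p$dx3$p_definite_band2_support,
      p$dx3$p_definite[band]
    )
    def3 <- rbern(n, p_def3)
    poss3 <- !def3 & rbern(n, p$dx3$p_possible[band])
    dx3 <- ifelse(def3, "definite", ifelse(poss3, "possible", "none"))
    ext3 <- rbern(n, unname(unlist(p$dx3$p_external)[dx3]))

    # atopy block for the mAPI
    at <- p$atopy
    atopy_p <- function(f) ifelse(z, at[[f]]$prone, at[[f]]$nonprone)
    parental <- rbern(n, atopy_p("parental_asthma"))
    eczema <- rbern(n, atopy_p("eczema_dx"))
    aero <- rbern(n, atopy_p("aeroallergen_sensitized"))
    food <- rbern(n, atopy_p("food_sensitized"))
    eos <- rbern(n, atopy_p("eosinophils_ge_4pct"))
    wapart <- rbern(n, at$wheeze_apart_from_colds[band])

    # school-entry wheeze: persistence for recurrent recent wheezers,
    # incident wheeze otherwise
    pe <- p$persistence
    p_persist <- stats::plogis(
      pe$intercept + pe$beta_support * support + pe$beta_prone * z
    )
    persist <- (w3 >= 2) & rbern(n, p_persist)
    iw <- p$incident_wheeze5
    p_any5 <- ifelse(z, iw$p_any_prone, iw$p_any_nonprone[band])
    w5 <- ifelse(persist, rgeom_shift(n, pe$cont5, 2L),
      ifelse(w3 >= 2, as.integer(rbern(n, pe$p_w5_one_nonpersist)),
        ifelse(rbern(n, p_any5), rgeom_shift(n, iw$cont), 0L)
      )
    )
    band5 <- pmin(w5, 2L) + 1L

    # school-entry asthma labels
    as5 <- p$asthma5
    p_def5 <- stats::plogis(
      as5$definite$intercept + as5$definite$beta_high * high +
        as5$definite$beta_prone * z
    )
    def5 <- rbern(n, p_def5)
    poss5 <- !def5 & rbern(n, unname(unlist(as5$p_possible_by_category)[tier]))
    dx5 <- ifelse(def5, "definite", ifelse(poss5, "possible", "none"))
    ext5 <- rbern(n, unname(unlist(as5$p_external)[dx5]))

    # school-entry burden reuses the per-band utilisation model
    m5 <- sample_band_meds(band5, p$supporting)

    cough_lv <- factor(m3$cough, levels = c("none", "occasional", "frequent"))
    ce <- p$cough_episodes
    cough_n <- ifelse(m3$cough == "frequent", ce$base_freq + stats::rpois(n, ce$lambda_freq),
      ifelse(m3$cough == "occasional", 1L + stats::rpois(n, ce$lambda_occ),
        as.integer(rbern(n, ce$p_one_given_none))
      )
    )

    age3 <- pmin(pmax(stats::rnorm(n, p$age3$mean, p$age3$sd), p$age3$min), p$age3$max)
    age5 <- pmin(pmax(stats::rnorm(n, p$age5$mean, p$age5$sd), p$age5$min), p$age5$max)

    cohort <- tibble::tibble(
      child_id = sprintf("C%05d", seq_len(n)),
      age_years = round(age3, 2),
      wheeze_episodes_last_12mo = as.integer(w3),
      wheeze_episodes_prior = as.integer(prior),
      dry_cough_without_cold = cough_lv,
      cough_episodes_last_12mo = as.integer(cough_n),
      ics_use_last_12mo = m3$ics,
      ocs_use_last_12mo = m3$ocs,
      bronchodilator_use_last_12mo = m3$bronch,
      ed_visits_wheeze_last_12mo = m3$ed_visits,
      hospitalizations_wheeze_last_12mo = m3$hosp,
      parental_asthma = parental,
      eczema_dx = eczema,
      aeroallergen_sensitized = aero,
      food_sensitized = food,
      eosinophils_ge_4pct = eos,
      wheeze_apart_from_colds = wapart,
      asthma_dx_in_study = factor(dx3, levels = c("definite", "possible", "none")),
      asthma_dx_external = ext3,
      out5_age_years = round(age5, 2),
      out5_wheeze_episodes_last_12mo = as.integer(w5),
      out5_asthma_dx_in_study = factor(dx5, levels = c("definite", "possible", "none")),
      out5_asthma_dx_external = ext5,
      out5_ics_use = m5$ics,
      out5_ocs_use = m5$ocs,
      out5_bronchodilator_use = m5$bronch,
      out5_ed_or_hosp_wheeze = m5$edh | m5$hosp > 0
    )

    # missing-completely-at-random masks, per field or block
    mr <- p$missingness
    atopy_cols <- c(
      "parental_asthma", "eczema_dx", "aeroallergen_sensitized",
      "food_sensitized", "eosinophils_ge_4pct", "wheeze_apart_from_colds"
    )
    out5_cols <- grep("^out5_", names(cohort), value = TRUE)
    for (col in setdiff(names(mr), c("atopy_block", "ed_hosp_block", "outcome_record"))) {
      if (mr[[col]] > 0 && col %in% names(cohort)) {
        cohort[[col]][rbern(n, mr[[col]])] <- NA
      }
    }
    if (!is.null(mr$ed_hosp_block) && mr$ed_hosp_block > 0) {
      # ED visits and hospitalisations come from one questionnaire item and
      # go missing together
      mask <- rbern(n, mr$ed_hosp_block)
      cohort$ed_visits_wheeze_last_12mo[mask] <- NA
      cohort$hospitalizations_wheeze_last_12mo[mask] <- NA
    }
    if (!is.null(mr$atopy_block) && mr$atopy_block > 0) {
      mask <- rbern(n, mr$atopy_block)
      for (col in atopy_cols) cohort[[col]][mask] <- NA
    }
    if (!is.null(mr$outcome_record) && mr$outcome_record > 0) {
      mask <- rbern(n, mr$outcome_record)
      for (col in out5_cols) cohort[[col]][mask] <- NA
    }

    list(
      cohort = cohort,
      latent = tibble::tibble(
        child_id = cohort$child_id,
        prone = z,
        true_tier = factor(tier, levels = chart_categories, ordered = TRUE)
      )
    )
  })
  structure(
    list(cohort = cohort$cohort, latent = cohort$latent, config = config),
    class = "chart_sim"
  )
}

#' Realized versus target prevalences of a generated cohort
#'
#' One row per calibrated preschool marginal with the realized prevalence
#' (computed among children with the field observed), the calibration
#' target, the binomial Monte-Carlo standard error at the target, and
#' whether the realized value falls within 3 such standard errors. Small
#' cohorts are flagged under-powered, since at a few hundred children the
#' 3-SE band is too wide to be an interesting check.
#'
#' @param sim A `chart_sim` object from [simulate_cohort()], or a cohort
#'   tibble (then `targets` must be supplied).
#' @param targets Named list of target proportions; defaults to the
#'   generator config targets.
#' @return Tibble with columns `marginal`, `realized`, `target`, `mc_se`,
#'   `n_evaluable`, `within_3se`, plus a logical `underpowered` attribute.
#' @export
marginal_report <- function(sim, targets = NULL) {
  if (inherits(sim, "chart_sim")) {
    data <- sim$cohort
    if (is.null(targets)) targets <- sim$config$params$targets
  } else {
    data <- sim
    if (is.null(targets)) targets <- sim_default_params()$targets
  }
  realized <- list(
    any_wheeze = data$wheeze_episodes_last_12mo >= 1,
    wheeze_ge2 = data$wheeze_episodes_last_12mo >= 2,
    bronchodilator = data$bronchodilator_use_last_12mo,
    corticosteroid = data$ics_use_last_12mo | data$ocs_use_last_12mo,
    ed_or_hosp = data$ed_visits_wheeze_last_12mo > 0 |
      data$hospitalizations_wheeze_last_12mo > 0
  )
  rows <- purrr::imap(realized, function(x, nm) {
    t <- targets[[nm]]
    n_eval <- sum(!is.na(x))
    se <- if (n_eval > 0) sqrt(t * (1 - t) / n_eval) else NA_real_
    r <- if (n_eval > 0) mean(x, na.rm = TRUE) else NA_real_
    tibble::tibble(
      marginal = nm, realized = r, target = t, mc_se = se,
      n_evaluable = n_eval,
      within_3se = !is.na(r) & abs(r - t) <= 3 * se
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "underpowered") <- any(out$n_evaluable < 1000)
  out
}
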