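#!/usr/bin/env Rscript
# Calibrates the default parameters of the synthetic-cohort generator and
# writes them to inst/extdata/sim_default.yaml (versioned with the package).
#
# Layer 1 (preschool marginals) is solved analytically: the latent-mixture
# wheeze model and the per-band medication/utilisation/cough probabilities
# are chosen so the implied population marginals equal the published
# development-cohort prevalences exactly (any wheeze 16.5%, >=2 wheeze
# episodes 8.8%, bronchodilator 9.8%, corticosteroid 11.0%, ED/hosp 3.5%,
# high-risk tier 7.1%, low-risk tier 69.1%, medication use among recurrent
# wheezers 171/220).
#
# Layer 2 (school-entry outcomes) fixes the latent-class effect sizes and
# root-finds the intercept/predictor coefficients of the logistic
# persistence and asthma models so the exact cell expectations hit the
# published persistence rate among recurrent wheezers (79/220), the
# screening sensitivity for persistent wheeze (72/79), the asthma
# prevalence implied by the published sensitivity/PPV pair (50.0% / 41.5%),
# and the asthma sensitivity (50.0%).
#
# Run from the repository root:  Rscript scripts/calibrate_generator.R

suppressMessages({
  library(yaml)
})

out_path <- file.path("inst", "extdata", "sim_default.yaml")

# ---- published anchors ------------------------------------------------
t_any <- 0.165 # any wheeze in past year
t_ge2 <- 0.088 # >= 2 wheeze episodes
t_bronch <- 0.098 # bronchodilator use
t_cort <- 0.110 # corticosteroid use (inhaled or oral)
t_edh <- 0.035 # ED visit or hospitalisation for wheeze/asthma
t_high <- 0.071 # high-risk tier share
t_low <- 0.691 # low-risk tier share
med_ge2 <- 171 / 220 # asthma-medication use among recurrent wheezers
pw_ge2 <- 79 / 220 # wheeze persistence among recurrent wheezers
sens_pw <- 72 / 79 # screening sensitivity for persistent wheeze
sens_as <- 0.500 # screening sensitivity for asthma at school entry
ppv_as <- 0.415 # screening PPV for asthma at school entry

# ---- latent mixture for the recent wheeze count ----------------------
p_prone <- 0.07
prone_any <- 0.90
prone_cont <- 0.75
non_any <- (t_any - p_prone * prone_any) / (1 - p_prone)
non_cont <- (t_ge2 - p_prone * prone_any * prone_cont) /
  ((1 - p_prone) * non_any)

P0 <- 1 - t_any # band weights: 0, 1, >=2 recent episodes
P1 <- t_any - t_ge2
P2 <- t_ge2

# ---- remote wheeze history (decides low vs moderate when no recent) --
p_prior_le1 <- t_low / P0
prior_p1 <- 0.10
prior_p0 <- p_prior_le1 - prior_p1

# ---- per-band medication / utilisation / cough -----------------------
b <- c(0.040, NA, 0.55) # bronchodilator by band, middle solved
b[2] <- (t_bronch - P0 * b[1] - P2 * b[3]) / P1
cc <- c(NA, 0.223, 0.49) # corticosteroid by band, first solved
cc[1] <- (t_cort - P1 * cc[2] - P2 * cc[3]) / P0
med <- c(0.060, 0.350, med_ge2) # medication union by band
p_both <- b + cc - med # joint from the union identity
stopifnot(p_both >= 0, p_both <= pmin(b, cc) + 1e-12, med <= 1)

pn <- c(0.004, 0.020, 0.050) # P(ED/hosp | no medication), by band
pm <- c(0.040, 0.120, NA) # P(ED/hosp | medication), last solved
pm[3] <- (t_edh -
  P0 * (med[1] * pm[1] + (1 - med[1]) * pn[1]) -
  P1 * (med[2] * pm[2] + (1 - med[2]) * pn[2]) -
  P2 * (1 - med[3]) * pn[3]) / (P2 * med[3])
stopifnot(pm[3] > 0, pm[3] < 1)

s2 <- t_high / t_ge2 # P(any supporting criterion | >=2 recent episodes)
f <- c(0.020, 0.050, NA) # frequent dry cough by band, last solved so that
# med OR ED/hosp OR frequent cough hits s2 (ED nested in medication)
f[3] <- 1 - ((1 - s2) / (1 - med[3])) / (1 - pn[3])
stopifnot(f[3] > 0, f[3] < 1)

# ---- outcome layer: persistence among recurrent recent wheezers ------
pz1_ge2 <- p_prone * prone_any * prone_cont / t_ge2 # P(prone | >=2)
cells_zs <- expand.grid(z = c(0, 1), s = c(0, 1))
w_zs <- ifelse(cells_zs$z == 1, pz1_ge2, 1 - pz1_ge2) *
  ifelse(cells_zs$s == 1, s2, 1 - s2)
beta_prone_pw <- 1.3

expect_pw <- function(a, bs) {
  p <- plogis(a + bs * cells_zs$s + beta_prone_pw * cells_zs$z)
  c(rate = sum(w_zs * p), with_s = sum(w_zs * p * cells_zs$s))
}
solve_pw <- function(bs) {
  a <- uniroot(function(a) expect_pw(a, bs)["rate"] - pw_ge2,
    c(-20, 20), tol = 1e-12
  )$root
  e <- expect_pw(a, bs)
  list(a = a, sens = unname(e["with_s"] / e["rate"]))
}
bs_pw <- uniroot(function(bs) solve_pw(bs)$sens - sens_pw,
  c(0, 15), tol = 1e-12
)$root
a_pw <- solve_pw(bs_pw)$a

# ---- outcome layer: specialist asthma diagnosis at school entry ------
prev_as <- t_high * ppv_as / sens_as
p_high_z1 <- prone_any * prone_cont * s2
p_high_z0 <- non_any * non_cont * s2
cells_zh <- expand.grid(z = c(0, 1), h = c(0, 1))
w_zh <- ifelse(cells_zh$z == 1, p_prone, 1 - p_prone) *
  ifelse(cells_zh$h == 1,
    ifelse(cells_zh$z == 1, p_high_z1, p_high_z0),
    ifelse(cells_zh$z == 1, 1 - p_high_z1, 1 - p_high_z0)
  )
beta_prone_as <- 1.6

expect_as <- function(c0, ch) {
  p <- plogis(c0 + ch * cells_zh$h + beta_prone_as * cells_zh$z)
  c(prev = sum(w_zh * p), with_h = sum(w_zh * p * cells_zh$h))
}
solve_as <- function(ch) {
  c0 <- uniroot(function(c0) expect_as(c0, ch)["prev"] - prev_as,
    c(-20, 20), tol = 1e-12
  )$root
  e <- expect_as(c0, ch)
  list(c0 = c0, sens = unname(e["with_h"] / e["prev"]))
}
ch_as <- uniroot(function(ch) solve_as(ch)$sens - sens_as,
  c(0, 15), tol = 1e-12
)$root
c0_as <- solve_as(ch_as)$c0

# ---- assemble and write ----------------------------------------------
params <- list(
  version = 1L,
  targets = list(
    any_wheeze = t_any, wheeze_ge2 = t_ge2, bronchodilator = t_bronch,
    corticosteroid = t_cort, ed_or_hosp = t_edh,
    chart_high = t_high, chart_moderate = 1 - t_high - t_low,
    chart_low = t_low
  ),
  latent = list(p_prone = p_prone),
  wheeze3 = list(
    prone = list(p_any = prone_any, p_cont = prone_cont),
    nonprone = list(p_any = non_any, p_cont = non_cont)
  ),
  prior_wheeze = list(
    recent0 = list(p0 = prior_p0, p1 = prior_p1, cont = 0.45),
    recent_pos = list(p_any = 0.50, cont = 0.45)
  ),
  age3 = list(mean = 3.08, sd = 0.17, min = 2.5, max = 3.7),
  age5 = list(mean = 5.08, sd = 0.19, min = 4.5, max = 5.8),
  supporting = list(
    p_bronch = b, p_cort = cc, p_both = p_both,
    p_ics_given_cort = 0.92, p_ocs_given_cort = 0.18,
    p_edh_given_med = pm, p_edh_given_nomed = pn,
    p_hosp_given_edh = 0.22, p_hosp_only_given_hosp = 0.30,
    lambda_extra_ed = 0.4,
    p_freq_cough = f, p_occ_cough = c(0.10, 0.20, 0.30)
  ),
  cough_episodes = list(
    p_one_given_none = 0.30, lambda_occ = 1, base_freq = 4, lambda_freq = 2
  ),
  atopy = list(
    parental_asthma = list(prone = 0.40, nonprone = 0.21),
    eczema_dx = list(prone = 0.30, nonprone = 0.11),
    aeroallergen_sensitized = list(prone = 0.35, nonprone = 0.19),
    food_sensitized = list(prone = 0.18, nonprone = 0.095),
    eosinophils_ge_4pct = list(prone = 0.30, nonprone = 0.12),
    wheeze_apart_from_colds = c(0.02, 0.35, 0.65)
  ),
  dx3 = list(
    p_definite = c(0.012, 0.070, 0.100),
    p_definite_band2_support = 0.50,
    p_possible = c(0.045, 0.160, 0.280),
    p_external = list(definite = 0.55, possible = 0.12, none = 0.008)
  ),
  persistence = list(
    intercept = a_pw, beta_support = bs_pw, beta_prone = beta_prone_pw,
    cont5 = 0.45, p_w5_one_nonpersist = 0.40
  ),
  incident_wheeze5 = list(
    p_any_prone = 0.55, p_any_nonprone = c(0.09, 0.30), cont = 0.45
  ),
  asthma5 = list(
    definite = list(
      intercept = c0_as, beta_high = ch_as, beta_prone = beta_prone_as
    ),
    p_possible_by_category = list(low = 0.04, moderate = 0.095, high = 0.24),
    p_external = list(definite = 0.75, possible = 0.25, none = 0.008)
  ),
  missingness = list(
    ed_hosp_block = 0.076,
    dry_cough_without_cold = 0.002,
    ics_use_last_12mo = 0.001,
    ocs_use_last_12mo = 0.001,
    bronchodilator_use_last_12mo = 0.001,
    atopy_block = 0.012,
    outcome_record = 0.063
  )
)

writeLines(as.yaml(params, precision = 12), out_path)
cat("wrote", out_path, "\n")
cat(sprintf(
  "persistence: intercept %.6f beta_support %.6f | asthma: intercept %.6f beta_high %.6f\n",
  a_pw, bs_pw, c0_as, ch_as
))
cat(sprintf("implied asthma prevalence %.5f\n", prev_as))
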