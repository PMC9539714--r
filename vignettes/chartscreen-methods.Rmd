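---
title: "Methods: symptom-based preschool asthma risk screening and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symptom-based preschool asthma risk screening and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chartscreen)
```

## The screening problem

Wheeze is reported at least once for a third to a half of all preschool
children, yet only a small subset go on to persistent symptoms, an asthma
diagnosis, and repeated emergency-department (ED) visits by school age.
Established predictive indices such as the modified Asthma Predictive Index
(mAPI) need skin-prick tests or blood eosinophil counts, which limits their
use in primary care. `chartscreen` implements a purely symptom-based
alternative: the CHILDhood Asthma Risk Tool (CHART), a deterministic rule
that stratifies children around 2–3 years of age into three risk tiers from
parent-reported information alone, together with the comparator indices,
the school-entry outcome definitions, and a diagnostic-accuracy engine to
evaluate all of them on a common cohort table.

## The decision rule

All inputs refer to a 12-month recall window before the assessment visit.
Writing $W$ for the number of wheeze episodes in that window, $W_p$ for
episodes before it, and $S$ for the event that at least one *supporting
criterion* holds — an ED visit for wheeze/asthma, a hospitalisation for
wheeze/asthma, asthma-medication use (inhaled corticosteroid, oral
corticosteroid, or bronchodilator), or frequent dry cough apart from colds
— the tier is

* **high** when $W \ge 2$ and $S$: recurrent recent wheeze with concurrent
  utilisation, medication, or frequent cough; follow-up action is further
  evaluation now;
* **low** when $W = 0$ and $W_p \le 1$: cough-only, single-remote-wheeze,
  and fully asymptomatic children; reassess in 12 months;
* **moderate** otherwise: one recent episode, recurrent recent wheeze
  without any supporting criterion, or recurrent wheeze confined to the
  remote past; reassess in 6 months.

The complete band-by-band mapping ships as a versioned CSV
(`chart_rule_table()`), so the branch structure can be audited and, if the
reconstruction needs correction, amended without an API change. Three
boundary placements in this table were genuinely open and are our own
design choices: fully asymptomatic children are placed in the low tier
(the only placement consistent with roughly 69% of a general population
being low risk); a single wheeze episode *within* the window is moderate,
because the low tier explicitly restricts the single episode to the remote
past; and two or more episodes that all occurred before the window, with
none since, are conservatively moderate. "Frequent" dry cough is
operationalised as the top level of a three-level ordinal
(none/occasional/frequent) because no numeric cut-off is published; the
episode-count field is carried alongside so a different threshold can be
studied. The applicability window defaults to 1.5–4.0 years; outside it a
classification is still returned but flagged.

### Missing fields

Unknown is distinct from zero everywhere (empty CSV cell, `NA` in R). The
classifier evaluates the rule under *every completion* of the missing
fields and returns a tier only when all completions agree; otherwise the
result is indeterminate with the blocking fields named — never a silent
default tier. This matters in practice: a child with two recent episodes
and known medication use is high risk even if the ED-visit count is
missing, so sporadic utilisation-item missingness rarely blocks
classification. The same three-valued logic (Kleene) runs through the
supporting-criteria set, the mAPI, and the outcome definitions: a
disjunction is true as soon as one member is known true, false only when
all members are known false.

## Comparators and outcomes

The mAPI is evaluated from a versioned configuration
(`mapi_rules()`): at least 4 wheeze episodes per year *and* at least one
major criterion (parental asthma, eczema, aeroallergen sensitisation) or
two minor criteria (food sensitisation, wheeze apart from colds, blood
eosinophils ≥ 4%). Children missing any required atopy field are
indeterminate, mirroring evaluations restricted to children with available
test data. Physician-diagnosis predictors and the asthma outcome take an
explicit definition variant (`in_study_definite`,
`in_study_definite_or_possible`, `external_reported`); the variant is
carried through every report because published accuracy figures can hinge
on whether "possible asthma" counts as positive, and the operative variant
behind the figures we compare against is not stated. The default is
definite-only.

The three school-entry outcomes are: *persistent wheeze* — two or more
episodes annually at both assessments, each over its own 12-month recall
(no interpolation between visits); *asthma* — the in-study specialist
diagnosis at 5 years under a named variant; and *health-care burden* —
inhaled corticosteroid use, oral corticosteroid or bronchodilator use, and
ED visit/hospitalisation, reported as separate components plus their
disjunction. Burden components at 5 years are assumed to use a 12-month
recall window (the alternative, since-last-visit, is not distinguishable
from the available descriptions). Children indeterminate for one outcome
stay evaluable for the others (complete-case per predictor–outcome pair).

## Accuracy metrics

`confusion()` tabulates a binary predictor against a binary outcome over
pairwise-complete entries; CHART is binarised as high versus
moderate-plus-low. Sensitivity, specificity, PPV and NPV carry Wilson
score 95% intervals — chosen over Wald for its behaviour at boundary
counts (endpoints are exact 0/1 at $x=0$ and $x=n$) and over
Clopper–Pearson for not being conservative. For a binary predictor the
tie-corrected Mann–Whitney AUROC has the closed form
$(\text{sensitivity}+\text{specificity})/2$, identical to the rank AUROC
of a univariate logistic regression on the predictor; the interval uses
the DeLong variance by default, with a percentile bootstrap
(`bootstrap_ci()`, seeded, percentile endpoints from `quantile()` type 7)
as the alternative. `auroc_empirical()` computes the midrank concordance
for arbitrary (e.g. three-level ordinal) scores; using the three risk
tiers as an ordinal score is offered only as a clearly separate
exploratory analysis, as the published comparison is the binarised one.
Zero-denominator metrics and single-class AUROCs surface as explicit
undefined rows (`ci_method = "undefined"`) with a classed warning, never
as silent zeros or dropped rows. Estimates are kept on the 0–1 scale;
reports format percentages to one decimal place (`format_pct()`).

## The synthetic cohort generator

No child-level data are distributed with the publications this package
works from, so the generator exists to exercise the pipeline end to end
and to check, on data with known structure, that the implementation
reproduces the documented operating characteristics. It is a first-class,
tested module, not a fixture.

Structure, per child: a latent two-class mixture (`p_prone = 0.07`,
matching the reported share of persistent-wheeze-prone children in a
general population) drives the recent wheeze count through a zero-inflated
shifted-geometric model per class; medication use (bronchodilator and
corticosteroid jointly, with an explicit overlap probability),
ED/hospitalisation (nested within medication users — independence within a
wheeze band cannot reproduce the observed 77.7% medication share among
recurrent wheezers, the 7.1% high-risk share and the 3.5% ED marginal
simultaneously), and dry cough are drawn conditionally on the wheeze band
(0, 1, 2+ recent episodes); physician labels and the atopy block follow;
school-entry persistence and the specialist asthma diagnosis are logistic
in the latent class and the preschool presentation; burden at 5 years
reuses the per-band utilisation model on the 5-year wheeze band.
Missingness is missing-completely-at-random per field, block-wise for the
atopy fields (skin-prick availability) and the ED/hospitalisation pair
(one questionnaire item) and record-wise for the 5-year block (lost to
follow-up); real missingness mechanisms are unknown, so MCAR is a
deliberate simplification.

The defaults are calibrated once, by `scripts/calibrate_generator.R`, and
versioned in `inst/extdata/sim_default.yaml`. The marginal layer is solved
analytically so the implied population prevalences equal the published
ones exactly (any wheeze 16.5%, ≥2 episodes 8.8%, bronchodilator 9.8%,
corticosteroid 11.0%, ED/hospitalisation 3.5%, tiers 7.1/23.8/69.1%); the
outcome layer fixes the latent-class log-odds effects (1.3 for
persistence, 1.6 for asthma — moderate within-stratum effects) and
root-finds intercepts and coefficients against exact cell expectations so
that persistence among recurrent wheezers is 79/220, screening sensitivity
for persistent wheeze 72/79, asthma prevalence 5.9% (implied by the
published sensitivity/PPV pair 50.0%/41.5%) and asthma sensitivity 50.0%.
`marginal_report()` compares realized to target prevalences with binomial
Monte-Carlo standard errors; at the working size of $n = 10{,}000$ the
3-SE band is about ±1 percentage point on the wheeze marginal, and cohorts
under 1,000 children are flagged under-powered.

What passing checks on generated data do and do not show: they demonstrate
that the classifier, comparators, outcome definitions and metrics engine
jointly reproduce the documented marginals and operating characteristics
*under this generative model*. They cannot validate the tool on real
children — the generator claims marginal fidelity plus qualitative
operating-characteristic fidelity only, and quantities that were not
calibration targets (for example mAPI sensitivity on generated data, which
runs low at ~36% against a published 48.5%) should be read as qualitative,
order-preserving reproductions (screening tool above physician above mAPI
for persistent wheeze), not point estimates. Demographic covariates,
seasonality, correlated questionnaire errors, and informative missingness
are all absent by design.

## Numerical and reproducibility choices

Every stochastic routine takes an explicit integer seed and restores the
caller's RNG state (`withr::with_seed`); the same configuration and seed
give byte-identical cohorts and pipeline outputs. Generator configurations
are validated before any sampling (probabilities in $[0,1]$, joint
probabilities admissible). CSV serialisation uses 0/1 booleans and empty
cells for unknowns to avoid locale-dependent parsing; reading is total —
every cell either parses or becomes an explicitly counted unknown, and no
row is ever dropped. The test suite exercises the classifier exhaustively
over the factorial grid of small inputs against the shipped rule table,
checks the closed-form AUROC against a brute-force all-pairs oracle at
$10^{-12}$, the Wilson interval against the score interval of
`prop.test()`, and the DeLong interval against an independent
implementation; simulation-based checks use cohorts of 2,000–10,000
children, sizes at which the calibrated marginals are sharp but the full
suite stays fast.

## Known limitations

The rule table is a reconstruction from published descriptions of the
decision logic, not a transcription of the original flow diagram; the
boundary placements listed above are documented choices kept behind the
versioned table. The questionnaire schema is a semantic reconstruction,
not the original instruments. The asthma outcome depends on a diagnosis
variant that must be named rather than assumed. And all quantitative
claims about accuracy on generated data are conditional on the generative
model described here.

```{r}
sim <- simulate_cohort(n = 2000, seed = 1)
marginal_report(sim)
```
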