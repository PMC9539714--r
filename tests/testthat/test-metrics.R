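test_that("confusion cross-tabulates and partitions evaluable pairs", {
  perfect <- confusion(rep(c(TRUE, FALSE), c(6, 4)), rep(c(TRUE, FALSE), c(6, 4)))
  expect_equal(
    unlist(perfect[c("tp", "fp", "tn", "fn")]),
    c(tp = 6L, fp = 0L, tn = 4L, fn = 0L)
  )
  all_neg <- confusion(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(all_neg$tp + all_neg$fp, 0L)
  withr::with_seed(99, {
    p <- sample(c(TRUE, FALSE, NA), 200, replace = TRUE, prob = c(.4, .5, .1))
    t <- sample(c(TRUE, FALSE, NA), 200, replace = TRUE, prob = c(.3, .6, .1))
  })
  got <- confusion(p, t)
  # brute-force tally oracle
  tally <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in 1:200) {
    if (is.na(p[i]) || is.na(t[i])) next
    cell <- if (p[i] && t[i]) "tp" else if (p[i]) "fp" else if (t[i]) "fn" else "tn"
    tally[cell] <- tally[cell] + 1L
  }
  expect_equal(unlist(got[c("tp", "fp", "tn", "fn")]), tally)
  expect_equal(got$n_evaluable + got$n_dropped, 200L)
})

test_that("published contingency numerators reproduce the printed accuracy", {
  expect_equal(
    round(100 * sensitivity(confusion_counts(tp = 72, fp = 0, tn = 0, fn = 7))$estimate, 1),
    91.1
  )
  expect_equal(
    round(100 * sensitivity(confusion_counts(tp = 49, fp = 0, tn = 0, fn = 30))$estimate, 1),
    62.0
  )
  expect_equal(
    round(100 * sensitivity(confusion_counts(tp = 33, fp = 0, tn = 0, fn = 35))$estimate, 1),
    48.5
  )
  expect_equal(
    round(100 * ppv(confusion_counts(tp = 72, fp = 94, tn = 0, fn = 0))$estimate, 1),
    43.4
  )
})

test_that("the four operating characteristics use the textbook ratios", {
  cc <- confusion_counts(tp = 30, fp = 20, tn = 40, fn = 10)
  expect_equal(sensitivity(cc)$estimate, 30 / 40)
  expect_equal(specificity(cc)$estimate, 40 / 60)
  expect_equal(ppv(cc)$estimate, 30 / 50)
  expect_equal(npv(cc)$estimate, 40 / 50)
  expect_equal(sensitivity(cc)$ci_method, "wilson")
  # complement identities hold exactly
  expect_identical(sensitivity(cc)$estimate + cc$fn / (cc$tp + cc$fn), 1)
  expect_identical(specificity(cc)$estimate + cc$fp / (cc$tn + cc$fp), 1)
})

test_that("Wilson interval matches the score interval of prop.test", {
  for (case in list(c(8, 10), c(72, 79), c(0, 5), c(5, 5), c(1, 1000))) {
    got <- wilson_ci(case[1], case[2])
    ref <- suppressWarnings(
      stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    )
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("Wilson endpoints stay inside [0,1] for all counts", {
  for (n in c(1, 2, 7, 40)) {
    for (x in 0:n) {
      ci <- wilson_ci(x, n)
      expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= x / n && x / n <= ci[2])
    }
  }
})

test_that("zero denominators surface as explicit undefined signals", {
  no_pos <- confusion_counts(tp = 0, fp = 3, tn = 5, fn = 0)
  expect_warning(
    row <- sensitivity(no_pos),
    class = "chartscreen_undefined_metric"
  )
  expect_true(is.na(row$estimate))
  expect_equal(row$ci_method, "undefined")
  zero_sens <- suppressWarnings(sensitivity(confusion_counts(0, 0, 5, 5)))
  expect_equal(zero_sens$estimate, 0)
  expect_equal(unname(zero_sens$conf_low), 0)
  expect_warning(
    auroc_binary(confusion_counts(tp = 2, fp = 0, tn = 0, fn = 3)),
    class = "chartscreen_undefined_metric"
  )
})

test_that("PPV obeys the Bayes identity on random confusion counts", {
  withr::with_seed(7, {
    for (i in 1:60) {
      cc <- confusion_counts(
        tp = sample(1:80, 1), fp = sample(1:80, 1),
        tn = sample(1:80, 1), fn = sample(1:80, 1)
      )
      se <- sensitivity(cc)$estimate
      sp <- specificity(cc)$estimate
      prev <- (cc$tp + cc$fn) / cc$n_evaluable
      bayes <- se * prev / (se * prev + (1 - sp) * (1 - prev))
      expect_equal(ppv(cc)$estimate, bayes, tolerance = 1e-12)
    }
  })
})

test_that("binary AUROC closed form equals sensitivity/specificity average", {
  expect_equal(auroc_binary(confusion_counts(10, 0, 10, 0), "none")$estimate, 1)
  expect_equal(auroc_binary(confusion_counts(5, 5, 5, 5), "none")$estimate, 0.5)
  cc <- confusion_counts(tp = 72, fp = 94, tn = 2109, fn = 7)
  expect_equal(
    auroc_binary(cc, "none")$estimate,
    (sensitivity(cc)$estimate + specificity(cc)$estimate) / 2
  )
})

test_that("closed-form binary AUROC equals rank-based AUROC of logistic fits", {
  withr::with_seed(31, {
    for (i in 1:20) {
      truth <- sample(c(TRUE, FALSE), 300, replace = TRUE, prob = c(.3, .7))
      pred <- ifelse(truth, runif(300) < .7, runif(300) < .2)
      cc <- confusion(pred, truth)
      closed <- auroc_binary(cc, "none")$estimate
      # univariate logistic regression scores are a monotone relabelling
      fit <- stats::glm(truth ~ pred, family = stats::binomial())
      emp <- auroc_empirical(stats::fitted(fit), truth, "none")$estimate
      expect_equal(closed, emp, tolerance = 1e-12)
    }
  })
})

test_that("empirical AUROC matches the all-pairs concordance oracle", {
  expect_equal(auroc_empirical(rep(1, 20), rep(c(TRUE, FALSE), 10), "none")$estimate, 0.5)
  expect_equal(
    auroc_empirical(c(rep(2, 5), rep(1, 5)), rep(c(TRUE, FALSE), c(5, 5)), "none")$estimate,
    1
  )
  withr::with_seed(13, {
    for (i in 1:15) {
      scores <- sample(0:5, 50, replace = TRUE) + ifelse(runif(50) < .5, 0, .5)
      truth <- runif(50) < plogis(scores - 2.5)
      if (sum(truth) == 0 || sum(!truth) == 0) next
      expect_equal(
        auroc_empirical(scores, truth, "none")$estimate,
        auc_all_pairs(scores, truth),
        tolerance = 1e-12
      )
    }
  })
})

test_that("AUROC and DeLong interval agree with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(77, {
    scores <- rnorm(150) + rep(c(1, 0), c(60, 90))
    truth <- rep(c(TRUE, FALSE), c(60, 90))
  })
  got <- auroc_empirical(scores, truth, "delong")
  ref <- pROC::roc(truth, scores, quiet = TRUE, direction = "<")
  ref_ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(got$estimate, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(unname(got$conf_low), as.numeric(ref_ci[1]), tolerance = 1e-8)
  expect_equal(unname(got$conf_high), as.numeric(ref_ci[3]), tolerance = 1e-8)
  # binary predictor route against pROC as well
  pred <- scores > 0.5
  cc <- confusion(pred, truth)
  got_bin <- auroc_binary(cc, "delong")
  ref_bin <- pROC::roc(truth, as.numeric(pred), quiet = TRUE, direction = "<")
  expect_equal(got_bin$estimate, as.numeric(pROC::auc(ref_bin)), tolerance = 1e-12)
  ref_bin_ci <- pROC::ci.auc(ref_bin, method = "delong")
  expect_equal(unname(got_bin$conf_low), as.numeric(ref_bin_ci[1]), tolerance = 1e-8)
})

test_that("bootstrap intervals are reproducible and collapse when constant", {
  pred <- rep(c(TRUE, FALSE), c(30, 30))
  truth <- rep(c(TRUE, FALSE), c(30, 30))
  sens_fn <- function(p, t) {
    cc <- confusion(p, t)
    cc$tp / (cc$tp + cc$fn)
  }
  a <- bootstrap_ci(sens_fn, pred, truth, n_boot = 200, seed = 4)
  b <- bootstrap_ci(sens_fn, pred, truth, n_boot = 200, seed = 4)
  expect_identical(a, b)
  const <- bootstrap_ci(function(p, t) 0.42, pred, truth, n_boot = 50, seed = 1)
  expect_equal(unname(const[2] - const[1]), 0)
})

test_that("bootstrap percentile interval covers a known sensitivity", {
  true_sens <- 0.8
  covered <- withr::with_seed(2024, {
    vapply(1:300, function(r) {
      truth <- rep(c(TRUE, FALSE), c(60, 60))
      pred <- ifelse(truth, runif(120) < true_sens, runif(120) < 0.15)
      ci <- bootstrap_ci(function(p, t) {
        cc <- confusion(p, t)
        cc$tp / (cc$tp + cc$fn)
      }, pred, truth, n_boot = 199, seed = r)
      ci[1] <= true_sens && true_sens <= ci[2]
    }, logical(1))
  })
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("evaluation table has one row per predictor-outcome-metric", {
  sim <- simulate_cohort(n = 600, seed = 21)
  tab <- evaluation_table(sim$cohort,
    predictors = c("chart", "mapi"),
    outcomes = c("persistent_wheeze", "asthma")
  )
  expect_equal(nrow(tab), 2 * 2 * 5)
  expect_setequal(
    unique(tab$metric),
    c("sensitivity", "specificity", "ppv", "npv", "auroc")
  )
  expect_true(all(tab$n_evaluable <= 600))
  # permuting the children leaves the table unchanged
  perm <- withr::with_seed(3, sample(600))
  tab_perm <- evaluation_table(sim$cohort[perm, ],
    predictors = c("chart", "mapi"),
    outcomes = c("persistent_wheeze", "asthma")
  )
  expect_equal(tab_perm, tab)
})

test_that("an all-negative predictor yields zero sensitivity and NPV = 1 - prevalence", {
  truth <- rep(c(TRUE, FALSE), c(15, 45))
  cc <- confusion(rep(FALSE, 60), truth)
  expect_equal(suppressWarnings(sensitivity(cc))$estimate, 0)
  expect_equal(npv(cc)$estimate, 1 - mean(truth))
})

test_that("percent formatting matches the reporting convention", {
  expect_equal(format_pct(c(0.9114, NA, 0.5)), c("91.1%", NA, "50.0%"))
})
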