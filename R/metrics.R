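#' Confusion counts for a binary predictor against a binary outcome
#'
#' Cross-tabulates predictions against truths over the pairwise complete
#' entries only (complete-case per predictor-outcome pair): pairs where
#' either value is `NA` are excluded and counted as dropped. The four counts
#' always partition the evaluable pairs.
#'
#' @param predictions,truths Logical (or 0/1) vectors of equal length.
#' @return Object of class `confusion_counts`: a list with integer `tp`,
#'   `fp`, `tn`, `fn`, `n_evaluable`, `n_dropped`.
#' @examples
#' confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  p <- as.logical(predictions)
  t <- as.logical(truths)
  ok <- !is.na(p) & !is.na(t)
  confusion_counts(
    tp = sum(p[ok] & t[ok]), fp = sum(p[ok] & !t[ok]),
    tn = sum(!p[ok] & !t[ok]), fn = sum(!p[ok] & t[ok]),
    n_dropped = sum(!ok)
  )
}

#' Construct confusion counts directly
#'
#' Useful for reproducing accuracy figures from published contingency
#' numerators and denominators.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @param n_dropped Pairs excluded for missingness, if known.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn, n_dropped = 0L) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(
    list(
      tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      n_evaluable = as.integer(tp + fp + tn + fn),
      n_dropped = as.integer(n_dropped)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts (n =", x$n_evaluable, "evaluable,",
      x$n_dropped, "dropped)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
    dimnames = list(predicted = c("+", "-"), truth = c("+", "-"))
  )
  print(m)
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`, always inside `[0, 1]`
#'   (including at `x = 0` and `x = n`).
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  # endpoints are exact at the boundary counts; avoid sqrt round-off there
  c(
    low = if (x == 0) 0 else max(0, (centre - half) / denom),
    high = if (x == n) 1 else min(1, (centre + half) / denom)
  )
}

metric_row <- function(metric, estimate, ci, ci_method, n) {
  tibble::tibble(
    metric = metric, estimate = estimate,
    conf_low = ci[[1]], conf_high = ci[[2]],
    ci_method = ci_method, n_evaluable = n
  )
}

undefined_metric <- function(metric, n, reason) {
  rlang::warn(
    paste0(metric, " undefined: ", reason),
    class = "chartscreen_undefined_metric"
  )
  metric_row(metric, NA_real_, c(NA_real_, NA_real_), "undefined", n)
}

proportion_metric <- function(metric, num, den, n, conf_level) {
  if (den == 0) {
    return(undefined_metric(metric, n, "zero denominator"))
  }
  metric_row(metric, num / den, wilson_ci(num, den, conf_level), "wilson", n)
}

#' Operating characteristics of a binary predictor
#'
#' Sensitivity `tp / (tp + fn)`, specificity `tn / (tn + fp)`, positive
#' predictive value `tp / (tp + fp)` and negative predictive value
#' `tn / (tn + fn)` with Wilson 95 percent confidence intervals. A zero
#' denominator yields an explicit undefined row (estimate `NA`, interval
#' `NA`, `ci_method = "undefined"`) plus a classed warning — never a silent
#' zero.
#'
#' @param counts A `confusion_counts` object.
#' @param conf_level Confidence level for the Wilson interval.
#' @return One-row tibble: `metric`, `estimate` (on the 0-1 scale),
#'   `conf_low`, `conf_high`, `ci_method`, `n_evaluable`.
#' @examples
#' sensitivity(confusion_counts(tp = 72, fp = 94, tn = 2100, fn = 7))
#' @export
sensitivity <- function(counts, conf_level = 0.95) {
  proportion_metric(
    "sensitivity", counts$tp, counts$tp + counts$fn,
    counts$n_evaluable, conf_level
  )
}

#' @rdname sensitivity
#' @export
specificity <- function(counts, conf_level = 0.95) {
  proportion_metric(
    "specificity", counts$tn, counts$tn + counts$fp,
    counts$n_evaluable, conf_level
  )
}

#' @rdname sensitivity
#' @export
ppv <- function(counts, conf_level = 0.95) {
  proportion_metric(
    "ppv", counts$tp, counts$tp + counts$fp,
    counts$n_evaluable, conf_level
  )
}

#' @rdname sensitivity
#' @export
npv <- function(counts, conf_level = 0.95) {
  proportion_metric(
    "npv", counts$tn, counts$tn + counts$fn,
    counts$n_evaluable, conf_level
  )
}

# DeLong placement values from scores and binary truths (midrank form).
# Returns list(auc, var).
delong_auc_var <- function(scores, truths) {
  pos <- scores[truths]
  neg <- scores[!truths]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  list(auc = auc, var = s10 / m + s01 / n)
}

#' AUROC of a binary predictor from confusion counts
#'
#' For a binary predictor the tie-corrected area under the ROC curve has
#' the closed form `(sensitivity + specificity) / 2` — the Mann-Whitney
#' concordance probability of the 0/1 score, and identically the AUROC of a
#' univariate logistic regression on the predictor (whose fitted
#' probabilities are a monotone relabelling of the two score values). The
#' confidence interval uses the DeLong variance by default, or a percentile
#' bootstrap of the reconstructed score/truth pairs.
#'
#' @param counts A `confusion_counts` object; both outcome classes must be
#'   present.
#' @param ci_method `"delong"` (default), `"bootstrap"` or `"none"`.
#' @param conf_level Confidence level.
#' @param n_boot,seed Bootstrap replicates and seed when
#'   `ci_method = "bootstrap"`.
#' @return One-row tibble in the same shape as [sensitivity()].
#' @export
auroc_binary <- function(counts, ci_method = c("delong", "bootstrap", "none"),
                         conf_level = 0.95, n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  n1 <- counts$tp + counts$fn
  n0 <- counts$tn + counts$fp
  if (n1 == 0 || n0 == 0) {
    return(undefined_metric("auroc", counts$n_evaluable, "one outcome class absent"))
  }
  se <- counts$tp / n1
  sp <- counts$tn / n0
  auc <- (se + sp) / 2
  scores <- rep(c(1, 0, 1, 0), c(counts$tp, counts$fn, counts$fp, counts$tn))
  truths <- rep(c(TRUE, FALSE), c(n1, n0))
  ci <- switch(ci_method,
    none = c(NA_real_, NA_real_),
    delong = {
      dl <- delong_auc_var(scores, truths)
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      c(max(0, auc - z * sqrt(dl$var)), min(1, auc + z * sqrt(dl$var)))
    },
    bootstrap = bootstrap_ci(
      function(p, t) delong_auc_var(p, t)$auc,
      scores, truths,
      n_boot = n_boot, seed = seed, conf_level = conf_level
    )
  )
  metric_row("auroc", auc, ci, ci_method, counts$n_evaluable)
}

#' Empirical tie-corrected AUROC for arbitrary scores
#'
#' Mann-Whitney concordance probability computed from midranks: the
#' probability that a randomly chosen positive child scores above a
#' randomly chosen negative one, counting ties as one half. Supports
#' ordinal predictors (for example the three-level risk tier used as an
#' exploratory score); for binary scores it coincides with
#' [auroc_binary()].
#'
#' @param scores Numeric (or ordered-factor) predictor values.
#' @param truths Logical outcomes.
#' @inheritParams auroc_binary
#' @return One-row tibble in the same shape as [sensitivity()].
#' @export
auroc_empirical <- function(scores, truths,
                            ci_method = c("delong", "bootstrap", "none"),
                            conf_level = 0.95, n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(scores) == length(truths))
  s <- as.numeric(scores)
  t <- as.logical(truths)
  ok <- !is.na(s) & !is.na(t)
  s <- s[ok]
  t <- t[ok]
  if (sum(t) == 0 || sum(!t) == 0) {
    return(undefined_metric("auroc", length(s), "one outcome class absent"))
  }
  dl <- delong_auc_var(s, t)
  ci <- switch(ci_method,
    none = c(NA_real_, NA_real_),
    delong = {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      c(max(0, dl$auc - z * sqrt(dl$var)), min(1, dl$auc + z * sqrt(dl$var)))
    },
    bootstrap = bootstrap_ci(
      function(p, tt) delong_auc_var(p, tt)$auc,
      s, t,
      n_boot = n_boot, seed = seed, conf_level = conf_level
    )
  )
  metric_row("auroc", dl$auc, ci, ci_method, length(s))
}

#' Percentile bootstrap interval for any paired accuracy statistic
#'
#' Resamples prediction/truth pairs with replacement and returns the
#' percentile interval of the statistic. Reproducible for a fixed seed; the
#' caller's random-number state is left untouched.
#'
#' @param metric_fn `function(predictions, truths)` returning one number.
#' @param predictions,truths Paired vectors.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param conf_level Confidence level.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(metric_fn, predictions, truths,
                         n_boot = 2000, seed = 1L, conf_level = 0.95) {
  stopifnot(length(predictions) == length(truths), n_boot >= 1)
  n <- length(predictions)
  stats_out <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      as.numeric(metric_fn(predictions[idx], truths[idx]))
    }, numeric(1))
  })
  qs <- stats::quantile(stats_out,
    probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
    na.rm = TRUE, names = FALSE
  )
  c(low = qs[1], high = qs[2])
}
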