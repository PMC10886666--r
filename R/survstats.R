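# Evaluation harness: Kaplan-Meier curves, one-sided log-rank tests,
# optimal cut-off search, univariate and all-subsets multiple Cox
# regression with partial AIC and C-index, and rank tests between
# subgroups. All model fitting is delegated to the survival package;
# this file defines the result containers and the cohort-level logic.

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function. Censored times reduce
#' the at-risk set without dropping the curve.
#'
#' @param times positive follow-up times.
#' @param events binary event indicators.
#' @return A data.frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `survival`, starting at time 0 with survival 1.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(all(times > 0), length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(
    time = c(0, fit$time),
    n_risk = c(length(times), fit$n.risk),
    n_event = c(0, fit$n.event),
    survival = c(1, fit$surv)
  )
  class(out) <- c("km_curve", "data.frame")
  out
}

#' One-sided log-rank test
#'
#' Standard log-rank test comparing two survival curves, reported
#' one-sided in the direction "the high-risk group has worse survival".
#' The z statistic is the signed square root of the chi-square statistic,
#' positive when the high-risk group has more events than expected.
#'
#' @param time_high,event_high follow-up and event indicator for the
#'   putative high-risk group.
#' @param time_low,event_low same for the low-risk group.
#' @return List with `chisq`, `z`, `p_one_sided`, `p_two_sided`,
#'   `observed` and `expected` event counts (high-risk group first).
#' @export
logrank_one_sided <- function(time_high, event_high, time_low, event_low) {
  if (length(time_high) == 0 || length(time_low) == 0) {
    stop("both groups must be nonempty")
  }
  time <- c(time_high, time_low)
  event <- c(event_high, event_low)
  grp <- factor(rep(c("high", "low"), c(length(time_high), length(time_low))),
                levels = c("high", "low"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- sd$chisq
  z <- sign(sd$obs[1] - sd$exp[1]) * sqrt(chisq)
  list(
    chisq = chisq,
    z = z,
    p_one_sided = stats::pnorm(z, lower.tail = FALSE),
    p_two_sided = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    observed = sd$obs,
    expected = sd$exp
  )
}

#' Optimal risk cut-off by log-rank p-value
#'
#' Scans candidate thresholds (midpoints between consecutive sorted unique
#' risk values) and returns the cut-off giving the lowest one-sided
#' log-rank p-value for the "risk > cutoff is the high-risk group" split.
#' Splits leaving either group below `min_group_frac` of the cohort are
#' excluded. Ties in p are broken toward the lowest cut-off. Because the
#' cut-off is optimised, the returned p-value is optimistically biased; an
#' optional permutation-adjusted p is available.
#'
#' @param risks numeric risk scores.
#' @param times,events survival data aligned with `risks`.
#' @param min_group_frac minimum admissible group fraction (default 0.1).
#' @param n_perm if > 0, additionally estimate a permutation-adjusted p by
#'   re-optimising the cut-off on `n_perm` risk permutations.
#' @return List with `cutoff`, `p` (one-sided at the optimum), `n_high`,
#'   `n_low`, the scanned `candidates` data.frame, and optionally `p_adjusted`.
#' @export
best_cutoff <- function(risks, times, events, min_group_frac = 0.1, n_perm = 0) {
  n <- length(risks)
  stopifnot(n == length(times), n == length(events))
  u <- sort(unique(risks))
  if (length(u) < 2) stop("all risks identical: no valid cutoff")
  scan_once <- function(r) {
    cand <- (head(sort(unique(r)), -1) + tail(sort(unique(r)), -1)) / 2
    best <- list(p = Inf, cutoff = NA_real_)
    rows <- list()
    for (cu in cand) {
      hi <- r > cu
      if (min(sum(hi), sum(!hi)) < min_group_frac * n) next
      lr <- logrank_one_sided(times[hi], events[hi], times[!hi], events[!hi])
      rows[[length(rows) + 1L]] <- data.frame(cutoff = cu, p = lr$p_one_sided,
                                              n_high = sum(hi), n_low = sum(!hi))
      if (lr$p_one_sided < best$p) best <- list(p = lr$p_one_sided, cutoff = cu)
    }
    list(best = best, rows = rows)
  }
  res <- scan_once(risks)
  if (length(res$rows) == 0) stop("no admissible cutoff under min_group_frac")
  cand_df <- do.call(rbind, res$rows)
  out <- list(cutoff = res$best$cutoff, p = res$best$p,
              n_high = sum(risks > res$best$cutoff),
              n_low = sum(risks <= res$best$cutoff),
              candidates = cand_df)
  if (n_perm > 0) {
    perm_p <- vapply(seq_len(n_perm), function(i) {
      scan_once(sample(risks))$best$p
    }, numeric(1))
    out$p_adjusted <- (1 + sum(perm_p <= out$p)) / (n_perm + 1)
  }
  out
}

#' Univariate Cox regression
#'
#' Maximum partial-likelihood fit (Breslow ties) of a single covariate,
#' reported as hazard ratio with Wald 95% CI and p-value, plus the partial
#' AIC (2k - 2 log PL) and the model concordance index.
#'
#' @param covariate numeric or binary covariate vector.
#' @param times,events survival data.
#' @param name covariate label used in the result row.
#' @return A one-row data.frame of class `cox_result` with columns
#'   `feature`, `hazard_ratio`, `ci95_low`, `ci95_high`, `p_value`, `aic`,
#'   `c_index`, `converged`.
#' @export
cox_univariate <- function(covariate, times, events, name = "covariate") {
  df <- data.frame(x = covariate, time = times, event = events)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x, data = df, ties = "breslow"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ x, data = df, ties = "breslow"))
      attr(f, "warned") <- conditionMessage(w)
      f
    })
  s <- summary(fit)
  out <- data.frame(
    feature = name,
    hazard_ratio = unname(s$conf.int[1, "exp(coef)"]),
    ci95_low = unname(s$conf.int[1, "lower .95"]),
    ci95_high = unname(s$conf.int[1, "upper .95"]),
    p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
    aic = 2 * length(stats::coef(fit)) - 2 * fit$loglik[2],
    c_index = unname(s$concordance["C"]),
    converged = is.null(attr(fit, "warned")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cox_result", "data.frame")
  out
}

#' All-subsets multiple Cox regression
#'
#' Enumerates every non-empty subset of the supplied features, fits a
#' multivariable Cox model (Breslow ties) to each, and keeps models in
#' which every individual feature is significant (Wald p < `alpha`).
#' Each kept model is reported with per-feature hazard ratios, 95% CIs
#' and p-values, the partial AIC, and the model C-index.
#'
#' @param features data.frame of numeric/binary covariates (one column each).
#' @param times,events survival data.
#' @param alpha per-feature significance threshold (default 0.05).
#' @return List with `models` (kept models, each a list with `features`,
#'   `table`, `aic`, `c_index`), `n_subsets` enumerated, and `excluded`
#'   (subsets dropped for collinearity/non-convergence).
#' @export
cox_combinations <- function(features, times, events, alpha = 0.05) {
  stopifnot(is.data.frame(features), ncol(features) >= 1)
  nms <- names(features)
  subsets <- unlist(lapply(seq_along(nms), function(k)
    utils::combn(nms, k, simplify = FALSE)), recursive = FALSE)
  kept <- list()
  excluded <- character(0)
  for (ss in subsets) {
    df <- cbind(features[ss], time = times, event = events)
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(sprintf("`%s`", ss), collapse = " + ")))
    fit <- tryCatch(survival::coxph(fml, data = df, ties = "breslow"),
                    warning = function(w) structure(list(), class = "cox_failed"),
                    error = function(e) structure(list(), class = "cox_failed"))
    if (inherits(fit, "cox_failed") || anyNA(stats::coef(fit))) {
      excluded <- c(excluded, paste(ss, collapse = "+"))
      next
    }
    s <- summary(fit)
    tab <- data.frame(
      feature = ss,
      hazard_ratio = unname(s$conf.int[, "exp(coef)"]),
      ci95_low = unname(s$conf.int[, "lower .95"]),
      ci95_high = unname(s$conf.int[, "upper .95"]),
      p_value = unname(s$coefficients[, "Pr(>|z|)"]),
      stringsAsFactors = FALSE
    )
    if (all(tab$p_value < alpha)) {
      kept[[length(kept) + 1L]] <- list(
        features = ss,
        table = tab,
        aic = 2 * length(stats::coef(fit)) - 2 * fit$loglik[2],
        c_index = unname(s$concordance["C"])
      )
    }
  }
  list(models = kept, n_subsets = length(subsets), excluded = excluded)
}

#' Rank tests for prediction values between patient subgroups
#'
#' Two-sided Mann-Whitney U for two groups, Kruskal-Wallis for more.
#'
#' @param values numeric prediction values.
#' @param groups group labels (factor or vector coercible to factor).
#' @return List with `test` ("mann-whitney" or "kruskal-wallis"), `statistic`,
#'   and `p`.
#' @export
group_tests <- function(values, groups) {
  g <- factor(groups)
  if (any(table(g) == 0) || nlevels(g) < 2) stop("need >= 2 nonempty groups")
  if (nlevels(g) == 2) {
    ht <- suppressWarnings(stats::wilcox.test(values ~ g, exact = FALSE, correct = FALSE))
    list(test = "mann-whitney", statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- stats::kruskal.test(values, g)
    list(test = "kruskal-wallis", statistic = unname(ht$statistic), p = ht$p.value)
  }
}
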