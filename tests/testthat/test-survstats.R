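# Evaluation harness: KM, one-sided log-rank, cut-off search, Cox
# regression, subgroup rank tests.

test_that("km_estimate reproduces the product-limit form", {
  # n = 4, events at t = 1, 2, no censoring beyond: S(2) = (3/4)(2/3) = 0.5
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(km$survival[km$time == 2], 0.5)
  expect_equal(km$survival[1], 1)            # starts at 1 (t = 0)
  expect_true(all(diff(km$survival) <= 1e-12))
  # no events: survival stays 1
  km0 <- km_estimate(c(2, 3, 7), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # all events at one time: drops to 0 in one step
  km1 <- km_estimate(rep(4, 6), rep(1, 6))
  expect_equal(km1$survival[km1$time == 4], 0)
  # matches the hand oracle on a random instance
  s <- random_surv(25, 3)
  km2 <- km_estimate(s$times, s$events)
  orc <- oracle_km(s$times, s$events)
  expect_equal(km2$survival[match(orc$time, km2$time)], orc$survival)
})

test_that("one-sided log-rank matches the observed-minus-expected oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    n1 <- sample(4:15, 1); n2 <- sample(4:15, 1)
    t1 <- sample(1:10, n1, TRUE); t2 <- sample(1:10, n2, TRUE)
    e1 <- rbinom(n1, 1, 0.7); e2 <- rbinom(n2, 1, 0.7)
    if (sum(e1) + sum(e2) == 0) next
    lr <- logrank_one_sided(t1, e1, t2, e2)
    expect_equal(lr$chisq, oracle_logrank_chisq(t1, e1, t2, e2), tolerance = 1e-8)
    # one- and two-sided p consistency
    expect_equal(lr$p_two_sided, stats::pchisq(lr$chisq, 1, lower.tail = FALSE))
  }
})

test_that("log-rank direction and degenerate cases behave", {
  # identical groups -> zero statistic, one-sided p = 0.5
  t <- c(1, 2, 3, 4, 5); e <- c(1, 0, 1, 1, 0)
  lr <- logrank_one_sided(t, e, t, e)
  expect_equal(lr$z, 0, tolerance = 1e-12)
  expect_equal(lr$p_one_sided, 0.5)
  # clearly worse survival in the high group -> small one-sided p
  set.seed(1)
  th <- rexp(100, 0.5); tl <- rexp(100, 0.1)
  lr2 <- logrank_one_sided(ceiling(th * 10), rep(1, 100),
                           ceiling(tl * 10), rep(1, 100))
  expect_lt(lr2$p_one_sided, 0.001)
  # reversed orientation gives p near 1
  lr3 <- logrank_one_sided(ceiling(tl * 10), rep(1, 100),
                           ceiling(th * 10), rep(1, 100))
  expect_gt(lr3$p_one_sided, 0.999)
  expect_error(logrank_one_sided(numeric(0), numeric(0), t, e), "nonempty")
})

test_that("best_cutoff equals exhaustive scan and respects group bounds", {
  set.seed(5)
  n <- 50
  risk <- rnorm(n)
  times <- ceiling(rexp(n, 0.02 * exp(risk)))
  events <- as.integer(times < 60); times <- pmin(times, 60)
  bc <- best_cutoff(risk, times, events, min_group_frac = 0.1)
  # oracle: scan all midpoints directly
  u <- sort(unique(risk))
  cand <- (u[-1] + u[-length(u)]) / 2
  best_p <- Inf; best_c <- NA
  for (cu in cand) {
    hi <- risk > cu
    if (min(sum(hi), sum(!hi)) < 0.1 * n) next
    p <- logrank_one_sided(times[hi], events[hi], times[!hi], events[!hi])$p_one_sided
    if (p < best_p) { best_p <- p; best_c <- cu }
  }
  expect_equal(bc$p, best_p)
  expect_equal(bc$cutoff, best_c)
  expect_true(min(bc$candidates$n_high, bc$candidates$n_low) >= 0.1 * n)
  expect_error(best_cutoff(rep(1, 20), 1:20, rep(1, 20)), "identical")
})

test_that("best_cutoff separates planted risk groups", {
  set.seed(9)
  risk <- c(rnorm(30, -2), rnorm(30, 2))
  times <- c(ceiling(runif(30, 40, 60)), ceiling(rexp(30, 0.2)))
  events <- c(rep(0, 30), rep(1, 30))
  bc <- best_cutoff(risk, times, events)
  expect_gt(bc$cutoff, -1); expect_lt(bc$cutoff, 1)
  expect_lt(bc$p, 1e-4)
})

test_that("cox_univariate agrees with an independent partial-likelihood maximiser", {
  # oracle: direct optimisation of the brute-force partial likelihood
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    x <- rnorm(n)
    times <- sample(1:50, n, TRUE)   # mostly untied
    events <- rbinom(n, 1, 0.7)
    if (sum(events) < 3) next
    res <- cox_univariate(x, times, events)
    ora <- stats::optimize(function(b) oracle_cox_loss(b * x, times, events),
                           c(-8, 8), tol = 1e-9)
    expect_equal(log(res$hazard_ratio), ora$minimum, tolerance = 1e-4)
  }
})

test_that("cox_univariate recovers a planted hazard ratio and null", {
  set.seed(21)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.02 * 5^x)
  times <- pmin(ceiling(t_ev), 100)
  events <- as.integer(t_ev <= 100)
  res <- cox_univariate(x, times, events, name = "binary")
  expect_gt(res$hazard_ratio, 3.5)
  expect_lt(res$hazard_ratio, 7)
  expect_true(res$ci95_low <= res$hazard_ratio && res$hazard_ratio <= res$ci95_high)
  # independent covariate: HR near 1, p typically large
  z <- rnorm(n)
  res0 <- cox_univariate(z, times, events)
  expect_lt(abs(log(res0$hazard_ratio)), 0.35)
})

test_that("cox coefficient rescales reciprocally under covariate scaling", {
  set.seed(3)
  n <- 120
  x <- rnorm(n)
  t_ev <- rexp(n, 0.05 * exp(0.7 * x))
  times <- pmin(ceiling(t_ev), 40); events <- as.integer(t_ev <= 40)
  r1 <- cox_univariate(x, times, events)
  r2 <- cox_univariate(10 * x, times, events)
  expect_equal(log(r1$hazard_ratio), 10 * log(r2$hazard_ratio), tolerance = 1e-6)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
})

test_that("cox_combinations enumerates subsets and filters on significance", {
  set.seed(31)
  n <- 250
  informative <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  t_ev <- rexp(n, 0.02 * exp(1.3 * informative))
  times <- pmin(ceiling(t_ev), 80); events <- as.integer(t_ev <= 80)
  feats <- data.frame(informative = informative, noise = noise,
                      noise2 = rnorm(n))
  res <- cox_combinations(feats, times, events)
  expect_equal(res$n_subsets, 7)
  kept_feats <- lapply(res$models, `[[`, "features")
  # every kept model's features are all significant; the pure-noise
  # singleton model is not kept
  expect_false(list("noise") %in% kept_feats)
  expect_true(all(vapply(res$models, function(m) all(m$table$p_value < 0.05),
                         logical(1))))
  # the informative singleton survives and models carry AIC + C-index
  expect_true(any(vapply(kept_feats, function(f) identical(f, "informative"),
                         logical(1))))
  expect_true(all(vapply(res$models, function(m) is.finite(m$aic), logical(1))))
})

test_that("group_tests selects the right test and matches the U oracle", {
  set.seed(8)
  x <- rnorm(12); y <- rnorm(8, 1)
  gt <- group_tests(c(x, y), rep(c("a", "b"), c(12, 8)))
  expect_equal(gt$test, "mann-whitney")
  # wilcox.test reports U for the first group
  expect_equal(gt$statistic, oracle_mwu(x, y))
  g3 <- group_tests(rnorm(30), rep(c("a", "b", "c"), 10))
  expect_equal(g3$test, "kruskal-wallis")
  expect_true(g3$p >= 0 && g3$p <= 1)
  expect_error(group_tests(rnorm(5), rep("a", 5)), "2 nonempty")
})
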