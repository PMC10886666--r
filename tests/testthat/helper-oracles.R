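# Brute-force reference implementations used as independent oracles.
# These are deliberately naive (explicit loops, direct formulas) and
# share no code with the package.

oracle_cindex <- function(risks, times, events) {
  num <- 0; den <- 0
  n <- length(risks)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] == 1 && times[i] < times[j]) {
      den <- den + 1
      if (risks[i] > risks[j]) num <- num + 1
      else if (risks[i] == risks[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_cox_loss <- function(risks, times, events) {
  total <- 0
  for (i in seq_along(risks)) {
    if (events[i] != 1) next
    at_risk <- which(times >= times[i])
    total <- total - (risks[i] - log(sum(exp(risks[at_risk]))))
  }
  total
}

# Log-rank chi-square via observed-minus-expected event counts over the
# distinct event times, pooled variance (two groups).
oracle_logrank_chisq <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(c(1, 2), c(length(t1), length(t2)))
  o_minus_e <- 0; varsum <- 0
  for (tt in sort(unique(times[events == 1]))) {
    n_at <- sum(times >= tt)
    n1_at <- sum(times >= tt & grp == 1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & grp == 1)
    e1_exp <- d * n1_at / n_at
    o_minus_e <- o_minus_e + (d1 - e1_exp)
    if (n_at > 1) {
      varsum <- varsum + d * (n1_at / n_at) * (1 - n1_at / n_at) *
        (n_at - d) / (n_at - 1)
    }
  }
  (o_minus_e)^2 / varsum
}

# Mann-Whitney U for group x against group y: count of (x_i > y_j) pairs
# plus half ties.
oracle_mwu <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) u <- u + 1
    else if (xi == yj) u <- u + 0.5
  }
  u
}

oracle_km <- function(times, events) {
  s <- 1
  out_t <- numeric(0); out_s <- numeric(0)
  for (tt in sort(unique(times[events == 1]))) {
    n_at <- sum(times >= tt)
    d <- sum(times == tt & events == 1)
    s <- s * (1 - d / n_at)
    out_t <- c(out_t, tt); out_s <- c(out_s, s)
  }
  data.frame(time = out_t, survival = out_s)
}

# small random survival instance generator
random_surv <- function(n, seed) {
  set.seed(seed)
  list(risks = round(rnorm(n), 3),
       times = sample(1:12, n, replace = TRUE),
       events = rbinom(n, 1, 0.6))
}
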