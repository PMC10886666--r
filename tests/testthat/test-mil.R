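# Attention-MIL: labelling, oversampling, pooling properties, gradient
# correctness, cross-validated training on planted-signal cohorts.

toy_bags <- function(n = 12, m = 6, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(3:8, 1)
    instance_bag(sprintf("p%02d", i), matrix(rnorm(k * m), k, m),
                 sample(c("C1", "C2", "C3"), k, TRUE),
                 label = as.integer(i %% 2))
  })
}

test_that("label_bags applies the horizon rule and exclusion", {
  mk <- function(t, e) instance_bag("x", matrix(0, 1, 2), "C1",
                                    survival = list(time_days = t, event = e))
  bags <- list(mk(400, 1), mk(800, 0), mk(400, 0), mk(730, 1), mk(731, 0))
  lab <- label_bags(bags, 730)
  expect_equal(length(lab), 4)               # censored-before-horizon excluded
  expect_equal(vapply(lab, function(b) b$label, integer(1)), c(1L, 0L, 1L, 0L))
  expect_error(label_bags(bags, 0), "configuration error")
  # event-free follow-up reaching a horizon equal to the censoring cap is
  # a negative, so the 5-year experiment keeps its controls
  lab5 <- label_bags(list(mk(1826, 0), mk(1826, 1), mk(1000, 0)), 1826)
  expect_equal(vapply(lab5, function(b) b$label, integer(1)), c(0L, 1L))
})

test_that("oversample_minority balances classes deterministically", {
  set.seed(4)
  bags <- c(
    lapply(1:10, function(i) instance_bag(paste0("n", i), matrix(rnorm(4), 2, 2),
                                          c("C1", "C2"), label = 0L)),
    lapply(1:4, function(i) instance_bag(paste0("p", i), matrix(rnorm(4), 2, 2),
                                         c("C1", "C2"), label = 1L)))
  bal <- oversample_minority(bags, seed = 3)
  y <- vapply(bal, function(b) b$label, integer(1))
  expect_equal(sum(y == 1), sum(y == 0))
  expect_equal(length(bal), 20)
  # duplicates reference the same matrices
  ids <- vapply(bal, function(b) b$patient_id, character(1))
  dup <- bal[[which(duplicated(ids))[1]]]
  orig <- bags[[match(dup$patient_id, vapply(bags, function(b) b$patient_id,
                                             character(1)))]]
  expect_identical(dup$instances, orig$instances)
  expect_identical(oversample_minority(bags, seed = 3),
                   oversample_minority(bags, seed = 3))
  # already balanced input is returned unchanged
  expect_identical(oversample_minority(bags[c(1:4, 11:14)], seed = 1),
                   bags[c(1:4, 11:14)])
  expect_error(oversample_minority(bags[1:3], seed = 1), "class is absent")
})

test_that("attention pooling is normalised and permutation invariant", {
  bags <- toy_bags()
  params <- wsimil:::mil_init(6, 8L, 4L, seed = 2)
  model <- list(params = params)
  for (b in bags) {
    out <- mil_predict_bag(b, model)
    expect_equal(sum(out$attention), 1, tolerance = 1e-6)
    expect_true(out$p > 0 && out$p < 1)
    # permuting instances leaves p unchanged
    perm <- sample(nrow(b$instances))
    bp <- instance_bag(b$patient_id, b$instances[perm, , drop = FALSE],
                       b$cluster_labels[perm], label = b$label)
    expect_equal(mil_predict_bag(bp, model)$p, out$p, tolerance = 1e-12)
  }
  # single instance bag gets attention exactly 1
  b1 <- instance_bag("s", matrix(rnorm(6), 1, 6), "C2")
  expect_equal(mil_predict_bag(b1, model)$attention, 1)
  # duplicated instance rows share identical attention
  x <- matrix(rnorm(6), 1, 6)
  b2 <- instance_bag("d", rbind(x, x, x), rep("C1", 3))
  att <- mil_predict_bag(b2, model)$attention
  expect_equal(att, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("MIL backward pass matches finite differences", {
  bags <- toy_bags(n = 6)
  st <- wsimil:::stack_bags(bags)
  y <- vapply(bags, function(b) b$label, integer(1))
  params <- wsimil:::mil_init(6, 5L, 4L, seed = 2)
  # move biases off the ReLU kink (all-zero hidden rows make the loss
  # non-differentiable exactly at zero bias)
  set.seed(11)
  params$b1 <- rnorm(5, 0, 0.3); params$b2 <- rnorm(5, 0, 0.3)
  fw <- wsimil:::mil_forward(params, st$X, st$seg, st$n)
  bw <- wsimil:::mil_backward(params, fw, st$X, st$seg, y)
  v <- wsimil:::flatten_params(params)
  g <- wsimil:::flatten_params(bw$grads[names(params)])
  lossat <- function(vv) {
    p <- wsimil:::unflatten_params(vv, params)
    f <- wsimil:::mil_forward(p, st$X, st$seg, st$n)
    -mean(y * log(f$p + 1e-12) + (1 - y) * log(1 - f$p + 1e-12))
  }
  idx <- sample(length(v), 40)
  for (i in idx) {
    e <- 1e-6
    vp <- v; vp[i] <- vp[i] + e
    vm <- v; vm[i] <- vm[i] - e
    num <- (lossat(vp) - lossat(vm)) / (2 * e)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("attention export writes one row per instance", {
  bags <- toy_bags(n = 3)
  model <- list(params = wsimil:::mil_init(6, 8L, 4L, seed = 2))
  td <- withr::local_tempdir()
  df <- export_attention_csv(bags, model, file.path(td, "att.csv"))
  expect_equal(nrow(df), sum(vapply(bags, function(b) nrow(b$instances), integer(1))))
  back <- utils::read.csv(file.path(td, "att.csv"))
  expect_equal(nrow(back), nrow(df))
  # attention sums to one within each bag
  s <- tapply(df$attention, df$patient_id, sum)
  expect_true(all(abs(s - 1) < 1e-6))
})

test_that("evaluate_classification computes F1 and accuracy", {
  ev <- evaluate_classification(c(0.9, 0.2), c(1, 0))
  expect_equal(ev$f1, 1); expect_equal(ev$accuracy, 1)
  # all-negative predictions on 30% positive truth
  ev2 <- evaluate_classification(rep(0.1, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(ev2$accuracy, 0.7); expect_equal(ev2$f1, 0)
  ev3 <- evaluate_classification(c(0.6, 0.7, 0.2, 0.8), c(1, 0, 0, 1))
  expect_equal(ev3$f1, 2 * 2 / (2 * 2 + 1 + 0))
})

test_that("cross-validated MIL recovers a planted relapse signal", {
  spec <- cohort_spec(100, rng_seed = 303)
  co <- generate_cohort(spec)
  bags <- simulate_bags(co, seed = 303)
  lab <- label_bags(bags, 730)
  fit <- train_mil(lab, k = 5L, max_epochs = 200L, patience = 200L, seed = 303)
  expect_equal(nrow(fit$predictions), length(lab))  # one OOF prediction each
  ev <- evaluate_classification(fit$predictions$p, fit$predictions$label)
  expect_gt(ev$accuracy, 0.75)
  # determinism
  fit2 <- train_mil(lab, k = 5L, max_epochs = 200L, patience = 200L, seed = 303)
  expect_identical(fit$predictions, fit2$predictions)
})

test_that("MIL collapses to chance under label permutation", {
  # the relapse class is a minority, so raw accuracy under the null sits
  # anywhere between coin-flip and the majority base rate; balanced
  # accuracy has a base-rate-free chance level of 0.5
  spec <- cohort_spec(80, rng_seed = 909)
  co <- generate_cohort(spec)
  bags <- simulate_bags(co, seed = 909)
  lab <- label_bags(bags, 730)
  bal_accs <- vapply(1:3, function(s) {
    set.seed(s)
    y <- vapply(lab, function(b) b$label, integer(1))
    yp <- sample(y)
    pb <- lapply(seq_along(lab), function(i) { b <- lab[[i]]; b$label <- yp[i]; b })
    fit <- train_mil(pb, k = 5L, max_epochs = 120L, seed = s)
    ev <- evaluate_classification(fit$predictions$p, fit$predictions$label)
    sens <- if (ev$tp + ev$fn > 0) ev$tp / (ev$tp + ev$fn) else 0.5
    spec_ <- if (ev$tn + ev$fp > 0) ev$tn / (ev$tn + ev$fp) else 0.5
    (sens + spec_) / 2
  }, numeric(1))
  expect_gt(mean(bal_accs), 0.35)
  expect_lt(mean(bal_accs), 0.65)
})
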