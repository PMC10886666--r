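# Attention-based multiple instance learning for fixed-horizon relapse
# classification. Each patient is a bag of patch feature vectors; a
# per-instance multilayer perceptron produces instance scores z_i, an
# attention network produces nonnegative weights a_i summing to one, and
# the bag prediction is p = sigmoid(sum_i a_i z_i). The objective is the
# negative log-likelihood of the Bernoulli distribution; training uses
# Adam with early stopping on validation loss, minority-class
# oversampling inside each training fold, and stratified k-fold
# cross-validation producing one out-of-fold prediction per patient.
#
# All bags are processed in one stacked pass: instances are concatenated
# into a single matrix and the attention softmax is computed within
# per-bag segments, which keeps every epoch a handful of BLAS calls.

#' Label bags for a fixed-horizon relapse classification
#'
#' Label 1 when the event occurred at or before the horizon; label 0 when
#' event-free follow-up reaches (or passes) the horizon — which includes
#' patients administratively censored exactly at a horizon equal to the
#' censoring cap; patients censored strictly before the horizon without an
#' event are excluded (their status at the horizon is unknown).
#'
#' @param bags list of [instance_bag()]s with `survival` populated.
#' @param horizon_days classification horizon (730 or 1826 in the main
#'   experiments).
#' @return The labelled subset of `bags`.
#' @export
label_bags <- function(bags, horizon_days) {
  if (horizon_days <= 0) stop("configuration error: horizon must be positive")
  out <- lapply(bags, function(b) {
    t <- b$survival$time_days; e <- b$survival$event
    if (e == 1 && t <= horizon_days) b$label <- 1L
    else if (t > horizon_days || (e == 0 && t == horizon_days)) b$label <- 0L
    else return(NULL)                       # censored before horizon: unknown
    b
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Minority-class oversampling
#'
#' Repeatedly draws random cases from the minority pool until class
#' counts are equal. Duplicates reference the same underlying feature
#' matrices (bags are copied by reference semantics of R lists).
#'
#' @param bags labelled bags.
#' @param seed integer seed.
#' @return Balanced list of bags.
#' @export
oversample_minority <- function(bags, seed = 1) {
  y <- vapply(bags, function(b) b$label, integer(1))
  if (length(unique(y)) < 2) stop("fold error: a class is absent")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) return(bags)
  minority <- which(y == (if (n1 < n0) 1L else 0L))
  need <- abs(n0 - n1)
  local_seed(derive_seed(seed, "oversample"), {
    extra <- sample(minority, need, replace = TRUE)
    c(bags, bags[extra])
  })
}

# --- model -----------------------------------------------------------------

mil_init <- function(m, hidden = 32L, attn_hidden = 16L, seed = 1) {
  local_seed(derive_seed(seed, "mil_init"), {
    g <- function(a, b) matrix(stats::rnorm(a * b, 0, sqrt(2 / a)), a, b)
    list(W1 = g(m, hidden), b1 = numeric(hidden),
         W2 = g(hidden, hidden), b2 = numeric(hidden),
         wz = stats::rnorm(hidden, 0, sqrt(1 / hidden)), bz = 0,
         V = g(m, attn_hidden), wa = stats::rnorm(attn_hidden, 0, sqrt(1 / attn_hidden)))
  })
}

# Stacked forward over bags: X (N x m) all instances, seg integer bag index
# per instance (1..B). Returns bag logits s_b = sum_i a_i z_i, probabilities,
# attention, and caches.
mil_forward <- function(params, X, seg, nbags) {
  H1 <- pmax(X %*% params$W1 + rep(params$b1, each = nrow(X)), 0)
  H2 <- pmax(H1 %*% params$W2 + rep(params$b2, each = nrow(H1)), 0)
  z <- as.numeric(H2 %*% params$wz + params$bz)
  U <- tanh(X %*% params$V)
  u <- as.numeric(U %*% params$wa)
  a <- segment_softmax(u, seg)
  s <- as.numeric(segment_rowsum(matrix(a * z, ncol = 1), seg))
  p <- stats::plogis(s)
  list(H1 = H1, H2 = H2, z = z, U = U, u = u, a = a, s = s, p = p)
}

# Backward for Bernoulli NLL; y length-nbags in {0,1}. Mean loss over bags.
mil_backward <- function(params, fw, X, seg, y) {
  nb <- length(y)
  ds <- (fw$p - y) / nb                       # d loss / d s_b
  dsz <- ds[seg]
  # s = sum a_i z_i: dz_i = a_i ds; da_i = z_i ds
  dz <- fw$a * dsz
  da <- fw$z * dsz
  # softmax within segment: du_i = a_i (da_i - sum_j a_j da_j)
  inner <- as.numeric(segment_rowsum(matrix(fw$a * da, ncol = 1), seg))
  du <- fw$a * (da - inner[seg])
  # attention net
  dU <- outer(du, params$wa) * (1 - fw$U^2)
  gV <- crossprod(X, dU)
  gwa <- as.numeric(crossprod(fw$U, du))
  # scorer MLP
  dH2 <- outer(dz, params$wz)
  dH2 <- dH2 * (fw$H2 > 0)
  gW2 <- crossprod(fw$H1, dH2)
  gb2 <- colSums(dH2)
  dH1 <- dH2 %*% t(params$W2)
  dH1 <- dH1 * (fw$H1 > 0)
  gW1 <- crossprod(X, dH1)
  gb1 <- colSums(dH1)
  gwz <- as.numeric(crossprod(fw$H2, dz))
  gbz <- sum(dz)
  loss <- -mean(y * log(fw$p + 1e-12) + (1 - y) * log(1 - fw$p + 1e-12))
  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    wz = gwz, bz = gbz, V = gV, wa = gwa))
}

stack_bags <- function(bags) {
  X <- do.call(rbind, lapply(bags, function(b) b$instances))
  seg <- rep(seq_along(bags), vapply(bags, function(b) nrow(b$instances), integer(1)))
  list(X = X, seg = seg, n = length(bags))
}

#' Bag-level forward pass
#'
#' Computes the attention-MIL prediction for one bag: instance scores
#' from the MLP, attention weights summing to one, and
#' `p = sigmoid(sum_i a_i z_i)`.
#'
#' @param bag an [instance_bag()].
#' @param model list with `params` as produced by [train_mil()] (or
#'   `mil_init` internally).
#' @return List with `p`, `attention` (length-n, sums to 1), and `z`.
#' @export
mil_predict_bag <- function(bag, model) {
  if (nrow(bag$instances) == 0) stop("input error: empty bag")
  fw <- mil_forward(model$params, bag$instances,
                    rep(1L, nrow(bag$instances)), 1L)
  list(p = fw$p, attention = fw$a, z = fw$z)
}

# stratified fold assignment; returns integer folds 1..k per bag
stratified_folds <- function(y, k, seed) {
  local_seed(derive_seed(seed, "folds"), {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Train the attention-MIL classifier with k-fold cross-validation
#'
#' Splits patients into `k` label-stratified folds; for each fold, trains
#' on the remaining folds (after minority oversampling, with a small
#' label-stratified slice held out for early stopping) and predicts the
#' held-out fold. Optimisation is full-batch Adam on the Bernoulli
#' negative log-likelihood, stopping when the validation loss has not
#' improved by more than 1e-5 for `patience` epochs (best weights
#' restored).
#'
#' @param bags labelled bags from [label_bags()].
#' @param k number of folds (default 5).
#' @param hidden,attn_hidden MLP and attention hidden widths.
#' @param max_epochs epoch budget per fold.
#' @param patience early-stopping patience in epochs.
#' @param lr Adam learning rate.
#' @param seed integer seed (folds, oversampling, init).
#' @return List with `predictions` (data.frame patient_id, fold, p,
#'   label), `folds`, and `history` (per-fold stopping epoch and best
#'   validation loss).
#' @export
train_mil <- function(bags, k = 5L, hidden = 32L, attn_hidden = 16L,
                      max_epochs = 300L, patience = 200L, lr = 1e-3, seed = 1) {
  if (length(bags) < k) stop("configuration error: fewer bags than folds")
  y <- vapply(bags, function(b) b$label, integer(1))
  fold <- stratified_folds(y, k, seed)
  preds <- data.frame()
  history <- list()
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    if (length(unique(y[tr_idx])) < 2) stop("fold error: a class is absent in training fold")
    # hold out a stratified fifth of the training patients for early stopping
    inner <- stratified_folds(y[tr_idx], 5L, derive_seed(seed, paste0("inner", f)))
    va_idx <- tr_idx[inner == 1L]
    fit_idx <- setdiff(tr_idx, va_idx)
    fit_bags <- oversample_minority(bags[fit_idx], derive_seed(seed, paste0("os", f)))
    st_fit <- stack_bags(fit_bags)
    y_fit <- vapply(fit_bags, function(b) b$label, integer(1))
    st_va <- stack_bags(bags[va_idx])
    y_va <- y[va_idx]
    m <- ncol(st_fit$X)
    params <- mil_init(m, hidden, attn_hidden, derive_seed(seed, paste0("init", f)))
    opt <- adam_init(params, lr = lr)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    for (ep in seq_len(max_epochs)) {
      fw <- mil_forward(params, st_fit$X, st_fit$seg, st_fit$n)
      bw <- mil_backward(params, fw, st_fit$X, st_fit$seg, y_fit)
      st <- adam_step(opt, params, bw$grads)
      opt <- st$opt; params <- st$params
      fv <- mil_forward(params, st_va$X, st_va$seg, st_va$n)
      vloss <- -mean(y_va * log(fv$p + 1e-12) + (1 - y_va) * log(1 - fv$p + 1e-12))
      if (vloss < best$loss - 1e-5) {
        best <- list(loss = vloss, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    st_te <- stack_bags(bags[te_idx])
    fte <- mil_forward(best$params, st_te$X, st_te$seg, st_te$n)
    preds <- rbind(preds, data.frame(
      patient_id = vapply(bags[te_idx], function(b) b$patient_id, character(1)),
      fold = f, p = fte$p, label = y[te_idx], stringsAsFactors = FALSE))
    history[[f]] <- data.frame(fold = f, stop_epoch = best$epoch,
                               val_loss = best$loss)
  }
  list(predictions = preds, folds = fold,
       history = do.call(rbind, history))
}

#' Export per-patch attention weights to CSV
#'
#' Runs the bag-level forward pass for every bag and writes one row per
#' instance with its attention weight and instance score -- the tabular
#' counterpart of an attention heat-map (no viewer is provided).
#'
#' @param bags list of [instance_bag()]s.
#' @param model list with `params` (as used by [mil_predict_bag()]).
#' @param path output CSV path.
#' @return The written data.frame, invisibly.
#' @export
export_attention_csv <- function(bags, model, path) {
  rows <- lapply(bags, function(b) {
    out <- mil_predict_bag(b, model)
    data.frame(patient_id = b$patient_id,
               instance = seq_len(nrow(b$instances)),
               cluster = b$cluster_labels,
               attention = out$attention,
               score = out$z,
               p = out$p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Classification metrics for out-of-fold predictions
#'
#' F1 on the positive (relapse) class and overall accuracy, with
#' predictions thresholded at 0.5.
#'
#' @param p predicted probabilities.
#' @param labels true binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return List with `f1`, `accuracy`, `tp`, `fp`, `fn`, `tn`. `f1` is
#'   `NA` when truth has a single class and no positive predictions exist.
#' @export
evaluate_classification <- function(p, labels, threshold = 0.5) {
  pred <- as.integer(p > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  list(f1 = f1, accuracy = (tp + tn) / length(labels),
       tp = tp, fp = fp, fn = fn, tn = tn)
}
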