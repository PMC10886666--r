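# Multiple instance survival learning (MISL). Patients are bags of patch
# feature vectors partitioned into the stroma/epithelium composition
# clusters C1-C3; instances are aggregated within each cluster by an
# attention-weighted mean, cluster vectors are scored, and a cluster
# attention layer combines the cluster scores into one scalar log-risk
# per patient. The training objective is the Breslow-tie Cox partial
# likelihood over a survival-matrix oversampling grid: the cohort's
# follow-up axis is discretised into fixed timesteps, every patient is
# artificially extended to the cohort's longest follow-up, and every
# (patient, timestep) cell contributes one training replicate carrying
# the cell's status and the timestep time, so that short survival times
# are adequately represented.

.status_codes <- c(left_censored = 0L, event = 1L, right_censored = 2L)

#' Build the cohort survival matrix
#'
#' An m x n grid over patients and timesteps `t_k = k * tstep`,
#' `k = 1..n`, `n = ceil(tmax / tstep)` with `tmax` the longest observed
#' follow-up. For a patient with observed time t and event indicator e,
#' cells at timesteps before t are "left-censored" (under observation,
#' event not yet occurred); cells at or after t carry the terminal
#' status, "event" when e = 1 and "right-censored" otherwise.
#'
#' @param times,events cohort follow-up data (positive times).
#' @param tstep timestep width in days (default 30).
#' @param patient_ids optional row names.
#' @return Integer matrix (0 = left-censored, 1 = event,
#'   2 = right-censored) of class `survival_matrix` with attributes
#'   `tstep`, `tmax` and `timestep_days`.
#' @export
build_survival_matrix <- function(times, events, tstep = 30L, patient_ids = NULL) {
  if (length(times) == 0) stop("input error: empty cohort")
  if (any(times <= 0)) stop("input error: nonpositive follow-up time")
  tmax <- max(times)
  n <- as.integer(ceiling(tmax / tstep))
  tk <- seq_len(n) * tstep
  m <- length(times)
  T <- matrix(.status_codes[["left_censored"]], m, n)
  for (i in seq_len(m)) {
    terminal <- if (events[i] == 1) .status_codes[["event"]] else .status_codes[["right_censored"]]
    T[i, tk >= times[i]] <- terminal
  }
  rownames(T) <- patient_ids
  attr(T, "tstep") <- as.integer(tstep)
  attr(T, "tmax") <- tmax
  attr(T, "timestep_days") <- tk
  class(T) <- c("survival_matrix", class(T))
  T
}

#' Expand the survival matrix into training replicates
#'
#' One replicate per (patient, timestep) cell: the replicate carries the
#' cell's timestep time as its working time and its status ("event" cells
#' count as events; both censoring flavours as censored). Every patient
#' contributes exactly n replicates, balancing exposure across the
#' follow-up axis.
#'
#' @param T a [build_survival_matrix()] result.
#' @return data.frame with `patient` (row index), `time` (timestep days),
#'   `event` (0/1).
#' @export
matrix_to_training_samples <- function(T) {
  tk <- attr(T, "timestep_days")
  m <- nrow(T); n <- ncol(T)
  data.frame(
    patient = rep(seq_len(m), times = n),
    time = rep(tk, each = m),
    event = as.integer(as.vector(T) == .status_codes[["event"]])
  )
}

# --- cluster-attention model ----------------------------------------------

misl_init <- function(m, hidden = 16L, attn_hidden = 16L, seed = 1,
                      attn_scale = 0.1) {
  # attention nets start near-uniform (small init) so that aggregation
  # begins as a plain within-cluster mean and attention is learned only
  # where the data demand it
  local_seed(derive_seed(seed, "misl_init"), {
    g <- function(a, b) matrix(stats::rnorm(a * b, 0, sqrt(2 / a)), a, b)
    list(V = attn_scale * g(m, attn_hidden),
         wa = attn_scale * stats::rnorm(attn_hidden, 0, sqrt(1 / attn_hidden)),
         W1 = g(m, hidden), b1 = numeric(hidden),
         wz = stats::rnorm(hidden, 0, sqrt(1 / hidden)), bz = 0,
         Vc = attn_scale * g(m, attn_hidden),
         wc = attn_scale * stats::rnorm(attn_hidden, 0, sqrt(1 / attn_hidden)))
  })
}

# Stack bags for the cluster model. Returns instance matrix X, instance ->
# (bag, cluster) group index g1, group -> bag index bag2, counts.
stack_bags_clustered <- function(bags) {
  X <- do.call(rbind, lapply(bags, function(b) b$instances))
  bag <- rep(seq_along(bags), vapply(bags, function(b) nrow(b$instances), integer(1)))
  cl <- unlist(lapply(bags, function(b) match(b$cluster_labels, c("C1", "C2", "C3"))),
               use.names = FALSE)
  raw <- (bag - 1L) * 3L + cl
  g1 <- match(raw, sort(unique(raw)))       # dense ids; empty clusters absent
  bag2 <- as.integer((sort(unique(raw)) - 1L) %/% 3L) + 1L
  list(X = X, g1 = g1, bag2 = bag2, n_bags = length(bags))
}

# Forward: per-bag scalar log-risk. Empty clusters are naturally excluded
# from the cluster-attention softmax because their groups do not exist.
misl_forward <- function(params, st) {
  U <- tanh(st$X %*% params$V)
  u <- as.numeric(U %*% params$wa)
  a <- segment_softmax(u, st$g1)
  Vag <- segment_rowsum(a * st$X, st$g1)              # G x m cluster vectors
  H <- tanh(Vag %*% params$W1 + rep(params$b1, each = nrow(Vag)))
  z <- as.numeric(H %*% params$wz + params$bz)
  Uc <- tanh(Vag %*% params$Vc)
  e <- as.numeric(Uc %*% params$wc)
  ac <- segment_softmax(e, st$bag2)
  risk <- as.numeric(segment_rowsum(matrix(ac * z, ncol = 1), st$bag2))
  list(U = U, u = u, a = a, Vag = Vag, H = H, z = z, Uc = Uc, e = e,
       ac = ac, risk = risk)
}

# Backward given d loss / d risk per bag.
misl_backward <- function(params, fw, st, drisk) {
  dperg <- drisk[st$bag2]
  dac <- fw$z * dperg
  dz <- fw$ac * dperg
  inner_c <- as.numeric(segment_rowsum(matrix(fw$ac * dac, ncol = 1), st$bag2))
  de <- fw$ac * (dac - inner_c[st$bag2])
  dUc <- outer(de, params$wc) * (1 - fw$Uc^2)
  gVc <- crossprod(fw$Vag, dUc)
  gwc <- as.numeric(crossprod(fw$Uc, de))
  dH <- outer(dz, params$wz) * (1 - fw$H^2)
  gW1 <- crossprod(fw$Vag, dH)
  gb1 <- colSums(dH)
  gwz <- as.numeric(crossprod(fw$H, dz))
  gbz <- sum(dz)
  dVag <- dUc %*% t(params$Vc) + dH %*% t(params$W1)  # G x m
  da <- rowSums(st$X * dVag[st$g1, , drop = FALSE])
  inner_i <- as.numeric(segment_rowsum(matrix(fw$a * da, ncol = 1), st$g1))
  du <- fw$a * (da - inner_i[st$g1])
  dU <- outer(du, params$wa) * (1 - fw$U^2)
  gV <- crossprod(st$X, dU)
  gwa <- as.numeric(crossprod(fw$U, du))
  list(V = gV, wa = gwa, W1 = gW1, b1 = gb1, wz = gwz, bz = gbz,
       Vc = gVc, wc = gwc)
}

#' Per-bag MISL risk score
#'
#' @param bag an [instance_bag()] with cluster labels.
#' @param model list with `params` from [train_misl()].
#' @return List with `risk` (scalar log-risk) and `cluster_attention`.
#' @export
misl_predict_bag <- function(bag, model) {
  st <- stack_bags_clustered(list(bag))
  fw <- misl_forward(model$params, st)
  list(risk = fw$risk, cluster_attention = fw$ac)
}

#' Train the MISL model with k-fold cross-validation
#'
#' Event-stratified folds (default 3); in each fold the training
#' patients' survival matrix is built and expanded into replicates, and
#' the cluster-attention network is trained full-batch with Adam on the
#' Breslow Cox partial likelihood over the replicates. A stratified slice
#' of the training patients is held out for early stopping on its Cox
#' loss; the per-epoch validation concordance index is logged and
#' averaged per fold. Every patient receives one out-of-fold risk.
#'
#' The small cohorts this model faces make memorisation the dominant
#' failure mode, so training regularises aggressively: instances are
#' jittered with fresh Gaussian noise each epoch (`augment_sd`), all
#' weights carry decoupled decay (`weight_decay`, applied as a
#' `1 - lr * weight_decay` shrink per step), attention starts
#' near-uniform, and the model reported for a fold is the epoch with the
#' best held-out concordance index (the C-index is the training metric).
#'
#' @param bags list of [instance_bag()]s with `survival` and cluster labels.
#' @param k folds (default 3).
#' @param tstep survival-matrix timestep in days.
#' @param hidden,attn_hidden network widths.
#' @param max_epochs,patience,lr training schedule.
#' @param augment_sd sd of the per-epoch instance jitter (feature units).
#' @param weight_decay decoupled weight-decay coefficient.
#' @param seed integer seed.
#' @return List with `risks` (data.frame patient_id, fold, risk),
#'   `fold_metrics` (per-fold validation C-index at the stopping epoch
#'   and its per-epoch average), and `folds`.
#' @export
train_misl <- function(bags, k = 3L, tstep = 30L, hidden = 8L,
                       attn_hidden = 4L, max_epochs = 200L, patience = 200L,
                       lr = 1e-3, augment_sd = 1.0, weight_decay = 3, seed = 1) {
  if (length(bags) < k) stop("configuration error: fewer bags than folds")
  times <- vapply(bags, function(b) b$survival$time_days, numeric(1))
  events <- vapply(bags, function(b) b$survival$event, numeric(1))
  fold <- stratified_folds(events, k, seed)
  # a fold must contain events; redraw with a shifted seed if one does not
  tries <- 0L
  while (any(tapply(events, fold, sum) == 0) && tries < 20L) {
    tries <- tries + 1L
    message("train_misl: fold without events; resampling folds")
    fold <- stratified_folds(events, k, derive_seed(seed, paste0("refold", tries)))
  }
  risks <- data.frame()
  fold_metrics <- list()
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    inner <- stratified_folds(events[tr_idx], 4L, derive_seed(seed, paste0("inner", f)))
    va_idx <- tr_idx[inner == 1L]
    fit_idx <- setdiff(tr_idx, va_idx)
    T <- build_survival_matrix(times[fit_idx], events[fit_idx], tstep)
    cells <- matrix_to_training_samples(T)
    fit_bags <- bags[fit_idx]
    st_va <- stack_bags_clustered(bags[va_idx])
    m <- ncol(fit_bags[[1]]$instances)
    params <- misl_init(m, hidden, attn_hidden, derive_seed(seed, paste0("init", f)))
    opt <- adam_init(params, lr = lr)
    best <- list(cindex = -Inf, loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    ci_log <- numeric(0)
    local_seed(derive_seed(seed, paste0("train", f)), {
      for (ep in seq_len(max_epochs)) {
        bj <- if (augment_sd > 0) {
          lapply(fit_bags, function(b) {
            b$instances <- b$instances +
              matrix(stats::rnorm(length(b$instances), 0, augment_sd),
                     nrow(b$instances))
            b
          })
        } else fit_bags
        st_fit <- stack_bags_clustered(bj)
        fw <- misl_forward(params, st_fit)
        cell_risk <- fw$risk[cells$patient]
        gcell <- cox_loss_grad(cell_risk, cells$time, cells$event, average = TRUE)
        drisk <- as.numeric(rowsum(gcell, cells$patient))
        grads <- misl_backward(params, fw, st_fit, drisk)
        stp <- adam_step(opt, params, grads)
        opt <- stp$opt; params <- stp$params
        if (weight_decay > 0) {
          for (kk in names(params)) params[[kk]] <- params[[kk]] * (1 - lr * weight_decay)
        }
        fv <- misl_forward(params, st_va)
        vloss <- suppressWarnings(
          cox_loss(fv$risk, times[va_idx], events[va_idx], average = TRUE))
        ci <- suppressWarnings(concordance_index(fv$risk, times[va_idx], events[va_idx]))
        ci_log <- c(ci_log, ci)
        if (!is.na(ci) && ci > best$cindex + 1e-5) {
          best <- list(cindex = ci, loss = vloss, params = params, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
    })
    # degenerate validation splits (no comparable pairs at any epoch, as in
    # very small cohorts) never update `best`; fall back to the final epoch
    if (best$epoch == 0L) best$params <- params
    fte <- misl_forward(best$params, stack_bags_clustered(bags[te_idx]))
    risks <- rbind(risks, data.frame(
      patient_id = vapply(bags[te_idx], function(b) b$patient_id, character(1)),
      fold = f, risk = fte$risk, stringsAsFactors = FALSE))
    fold_metrics[[f]] <- data.frame(
      fold = f, stop_epoch = best$epoch, val_loss = best$loss,
      val_cindex = if (is.finite(best$cindex)) best$cindex else NA_real_,
      mean_epoch_cindex = mean(ci_log, na.rm = TRUE))
  }
  list(risks = risks, fold_metrics = do.call(rbind, fold_metrics), folds = fold)
}
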