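# Patch-identity feature extraction network. A small strided CNN trunk
# (stand-in for a full InceptionResNetV2 backbone, selectable in the
# config) feeds a compression layer -- the last layer before the decision
# layer -- realised either as a 1x1 convolution with d output channels
# followed by global average pooling ("conv2d"; algebraically a linear
# map of the pooled trunk channels, which is how it is computed) or as a
# dense layer of width d. A softmax head over slide identities provides
# the self-supervised training signal: every patch must be assigned to
# the slide it came from. Feature vectors are the compression-layer
# activations.
#
# Activations are stored as arrays (h, w, channels, batch); convolutions
# use im2col so all heavy lifting is BLAS matrix multiplication.

#' Encoder configuration
#'
#' @param compression_mode "conv2d" (default) or "dense".
#' @param width output feature width d; one of 1536, 1024, 512, 256, 128,
#'   64, 32, 16, 8, 4, 2.
#' @param input_px side of the square input fed to the trunk; 256-pixel
#'   patches are bilinearly downsampled to this size (desk-scale choice).
#' @param trunk_channels channel widths of the four strided conv blocks.
#' @param backbone "small_cnn" is the only implemented trunk.
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(compression_mode = c("conv2d", "dense"),
                           width = 64L,
                           input_px = 32L,
                           trunk_channels = c(8L, 16L, 32L, 64L),
                           backbone = "small_cnn") {
  compression_mode <- match.arg(compression_mode)
  allowed <- c(1536L, 1024L, 512L, 256L, 128L, 64L, 32L, 16L, 8L, 4L, 2L)
  if (!(width %in% allowed)) {
    stop("configuration error: width must be one of ", paste(allowed, collapse = ", "))
  }
  if (backbone != "small_cnn") {
    stop("configuration error: only the small_cnn backbone is implemented")
  }
  if (log2(input_px) %% 1 != 0 || input_px < 16) {
    stop("configuration error: input_px must be a power of two >= 16")
  }
  structure(list(compression_mode = compression_mode, width = as.integer(width),
                 input_px = as.integer(input_px),
                 trunk_channels = as.integer(trunk_channels),
                 backbone = backbone),
            class = "encoder_config")
}

# --- conv primitives -------------------------------------------------------
#
# Activations live in a flat row layout: a matrix with one row per
# (image, pixel) -- image-major, then row-major within the image -- and
# one column per channel. im2col becomes nine row-gathers through a
# precomputed index (out-of-bounds taps point at an appended zero row),
# and the backward scatter is a single rowsum() accumulation, so both
# passes are BLAS matrix products plus indexed copies.

# gather indices for a 3x3 stride-2 pad-1 conv on H x W images, batch B
conv_gather_idx <- function(H, W, B) {
  key <- sprintf("cidx_%d_%d_%d", H, W, B)
  idx <- .wsimil_cache[[key]]
  if (!is.null(idx)) return(idx)
  OH <- H %/% 2L; OW <- W %/% 2L
  zero_row <- B * H * W + 1L
  oi <- rep(rep(seq_len(OH), each = OW), times = B)
  oj <- rep(rep(seq_len(OW), times = OH), times = B)
  b <- rep(seq_len(B), each = OH * OW)
  gidx <- matrix(0L, B * OH * OW, 9L)
  o <- 0L
  for (di in 0:2) for (dj in 0:2) {
    o <- o + 1L
    ii <- 2L * oi + di - 2L
    jj <- 2L * oj + dj - 2L
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    g <- (b - 1L) * (H * W) + (ii - 1L) * W + jj
    g[!ok] <- zero_row
    gidx[, o] <- g
  }
  idx <- list(gidx = gidx, OH = OH, OW = OW, zero_row = zero_row)
  .wsimil_cache[[key]] <- idx
  idx
}

# M: (B*H*W) x cin activation matrix; W: (9*cin) x cout.
conv_forward <- function(M, W, b, H, Wd, B) {
  cin <- ncol(M)
  idx <- conv_gather_idx(H, Wd, B)
  Mx <- rbind(M, 0)
  P <- matrix(0, nrow(idx$gidx), 9L * cin)
  for (o in 1:9) P[, (o - 1L) * cin + seq_len(cin)] <- Mx[idx$gidx[, o], , drop = FALSE]
  Y <- P %*% W + rep(b, each = nrow(P))
  list(out = Y, P = P, H = H, W = Wd, B = B, cin = cin)
}

conv_backward <- function(dY, cache, W) {
  cin <- cache$cin
  idx <- conv_gather_idx(cache$H, cache$W, cache$B)
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- tcrossprod(dY, W)                      # N_out x 9cin
  n_out <- nrow(dP)
  stack <- matrix(aperm(array(dP, c(n_out, cin, 9L)), c(1, 3, 2)),
                  n_out * 9L, cin)
  rs <- rowsum(stack, as.vector(idx$gidx))
  dM <- matrix(0, cache$B * cache$H * cache$W + 1L, cin)
  dM[as.integer(rownames(rs)), ] <- rs
  list(dX = dM[-nrow(dM), , drop = FALSE], dW = dW, db = db)
}

# --- encoder model ---------------------------------------------------------

encoder_init <- function(config, n_identities, seed) {
  tc <- config$trunk_channels
  cin <- c(3L, tc[-length(tc)])
  local_seed(derive_seed(seed, "encoder_init"), {
    params <- list()
    for (l in seq_along(tc)) {
      fan_in <- 9L * cin[l]
      params[[paste0("W", l)]] <- matrix(stats::rnorm(fan_in * tc[l], 0, sqrt(2 / fan_in)),
                                         fan_in, tc[l])
      params[[paste0("b", l)]] <- numeric(tc[l])
    }
    s_out <- config$input_px %/% 2L^length(tc)
    flat <- s_out * s_out * tc[length(tc)]
    comp_in <- if (config$compression_mode == "conv2d") tc[length(tc)] else flat
    params$Wc <- matrix(stats::rnorm(comp_in * config$width, 0, sqrt(2 / comp_in)),
                        comp_in, config$width)
    params$bc <- numeric(config$width)
    params$Wh <- matrix(stats::rnorm(config$width * n_identities, 0,
                                     sqrt(1 / config$width)),
                        config$width, n_identities)
    params$bh <- numeric(n_identities)
    params
  })
}

# Forward pass. X: (s, s, 3, B). Returns per-image features (B x d),
# logits (B x k) and caches for backprop.
encoder_forward <- function(params, X, config, with_cache = TRUE) {
  tc <- config$trunk_channels
  s <- dim(X)[1]; B <- dim(X)[4]
  # flat row layout: rows (image-major, then row-major pixels), columns = channels
  A <- matrix(aperm(X, c(2, 1, 4, 3)), s * s * B, 3L) - 0.5
  H <- s
  caches <- vector("list", length(tc))
  for (l in seq_along(tc)) {
    cf <- conv_forward(A, params[[paste0("W", l)]], params[[paste0("b", l)]],
                       H, H, B)
    A <- cf$out * (cf$out > 0)
    caches[[l]] <- if (with_cache) {
      list(P = cf$P, H = cf$H, W = cf$W, B = cf$B, cin = cf$cin,
           mask = (cf$out > 0))
    } else NULL
    H <- H %/% 2L
  }
  hw <- H * H
  bgroup <- rep(seq_len(B), each = hw)
  if (config$compression_mode == "conv2d") {
    # 1x1 conv to width channels + global average pooling == linear map of
    # the pooled trunk channels (pooling and 1x1 conv commute)
    G <- rowsum(A, bgroup) / hw                       # B x ctrunk
  } else {
    G <- matrix(aperm(array(A, c(hw, B, ncol(A))), c(2, 1, 3)),
                B, hw * ncol(A))                      # B x flattened map
  }
  feat <- G %*% params$Wc + rep(params$bc, each = B)  # B x d
  logits <- feat %*% params$Wh + rep(params$bh, each = B)  # B x k
  list(feat = feat, logits = logits, caches = caches, G = G,
       h_last = H, c_last = ncol(A), B = B)
}

# Softmax cross-entropy loss and full backward pass; y: integer labels 1..k.
encoder_backward <- function(params, fw, X, y, config) {
  B <- fw$B
  L <- fw$logits - apply(fw$logits, 1, max)
  E <- exp(L)
  Pr <- E / rowSums(E)
  loss <- -mean(log(Pr[cbind(seq_len(B), y)] + 1e-12))
  dL <- Pr
  dL[cbind(seq_len(B), y)] <- dL[cbind(seq_len(B), y)] - 1
  dL <- dL / B                                        # B x k
  grads <- list()
  grads$Wh <- crossprod(fw$feat, dL)
  grads$bh <- colSums(dL)
  dfeat <- tcrossprod(dL, params$Wh)                  # B x d
  grads$Wc <- crossprod(fw$G, dfeat)
  grads$bc <- colSums(dfeat)
  dG <- tcrossprod(dfeat, params$Wc)                  # B x comp_in
  hw <- fw$h_last^2
  if (config$compression_mode == "conv2d") {
    # undo the spatial mean: gradient spreads uniformly over the hw positions
    dA <- dG[rep(seq_len(B), each = hw), , drop = FALSE] / hw
  } else {
    dA <- matrix(aperm(array(dG, c(B, hw, fw$c_last)), c(2, 1, 3)),
                 hw * B, fw$c_last)
  }
  tc <- config$trunk_channels
  for (l in rev(seq_along(tc))) {
    dZ <- dA * fw$caches[[l]]$mask
    cb <- conv_backward(dZ, fw$caches[[l]], params[[paste0("W", l)]])
    grads[[paste0("W", l)]] <- cb$dW
    grads[[paste0("b", l)]] <- cb$db
    dA <- cb$dX
  }
  list(loss = loss, grads = grads[names(params)])
}

# Stack a list of (s, s, 3) arrays into (s, s, 3, B).
stack_images <- function(imgs) {
  s <- dim(imgs[[1]])[1]
  array(unlist(imgs, use.names = FALSE), c(s, s, 3L, length(imgs)))
}

#' Train the patch-identity encoder
#'
#' Minibatch Adam on softmax cross-entropy over slide identities. The
#' returned encoder carries the trained parameters, the config, and a
#' per-epoch log of training loss and validation pairing accuracy.
#'
#' @param train_imgs list of (s x s x 3) arrays (one per training patch).
#' @param train_ids integer identity labels (1..k) aligned with `train_imgs`.
#' @param config an [encoder_config()].
#' @param val_imgs,val_ids optional held-out patches for the pairing
#'   accuracy log.
#' @param epochs number of passes (fixed budget; the identity task has no
#'   published schedule).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed integer seed controlling init and shuffling.
#' @return List of class `identity_encoder`.
#' @export
train_identity_encoder <- function(train_imgs, train_ids, config,
                                   val_imgs = NULL, val_ids = NULL,
                                   epochs = 20L, batch_size = 64L,
                                   lr = 2e-3, seed = 1) {
  k <- length(unique(train_ids))
  if (k < 2) stop("configuration error: need >= 2 identities (task degenerate)")
  stopifnot(length(train_imgs) == length(train_ids))
  params <- encoder_init(config, k, seed)
  opt <- adam_init(params, lr = lr)
  n <- length(train_imgs)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_accuracy = numeric(0))
  local_seed(derive_seed(seed, "encoder_train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        X <- stack_images(train_imgs[idx])
        fw <- encoder_forward(params, X, config)
        bw <- encoder_backward(params, fw, X, train_ids[idx], config)
        st <- adam_step(opt, params, bw$grads)
        opt <- st$opt; params <- st$params
        losses <- c(losses, bw$loss)
      }
      va <- NA_real_
      if (!is.null(val_imgs)) {
        va <- pairing_accuracy_raw(params, config, val_imgs, val_ids)
      }
      log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_accuracy = va))
    }
  })
  structure(list(params = params, config = config, n_identities = k, log = log),
            class = "identity_encoder")
}

pairing_accuracy_raw <- function(params, config, imgs, ids, chunk = 256L) {
  pred <- integer(length(imgs))
  for (start in seq(1L, length(imgs), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(imgs))
    fw <- encoder_forward(params, stack_images(imgs[idx]), config, with_cache = FALSE)
    pred[idx] <- max.col(fw$logits, ties.method = "first")
  }
  mean(pred == ids)
}

#' Patch-pairing accuracy
#'
#' Fraction of validation patches whose predicted identity equals their
#' true slide index (top-1 identity accuracy).
#'
#' @param encoder trained [train_identity_encoder()] result.
#' @param val_imgs list of validation patch arrays.
#' @param val_ids integer identity labels.
#' @return Scalar in \[0, 1\].
#' @export
pairing_accuracy <- function(encoder, val_imgs, val_ids) {
  if (length(val_imgs) == 0) stop("evaluation error: empty validation set")
  pairing_accuracy_raw(encoder$params, encoder$config, val_imgs, val_ids)
}

#' Extract feature vectors
#'
#' Runs the trained encoder in inference mode and returns the
#' compression-layer activations, one d-vector per patch.
#'
#' @param encoder trained encoder.
#' @param imgs list of (s x s x 3) arrays matching the encoder input size.
#' @param ids optional rownames for the result.
#' @return Matrix (patches x d).
#' @export
extract_features <- function(encoder, imgs, ids = NULL, chunk = 256L) {
  s <- encoder$config$input_px
  bad <- vapply(imgs, function(im) dim(im)[1] != s || dim(im)[2] != s, logical(1))
  if (any(bad)) stop("input error: patch size mismatch with encoder input")
  out <- matrix(0, length(imgs), encoder$config$width)
  for (start in seq(1L, length(imgs), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(imgs))
    fw <- encoder_forward(encoder$params, stack_images(imgs[idx]),
                          encoder$config, with_cache = FALSE)
    out[idx, ] <- fw$feat
  }
  if (!is.null(ids)) rownames(out) <- ids
  out
}
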