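# Pair dataset construction, encoder training mechanics, pairing
# accuracy, feature extraction.

sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_slides(4, 2048L, seed = 555)
    cache
  }
})

test_that("sample_pairs yields adjacent, disjoint, balanced splits", {
  sim <- sim_small()
  pairs <- sample_pairs(sim$manifest, "all", seed = 2)
  expect_gt(nrow(pairs), 0)
  leaves <- sim$manifest[sim$manifest$level_px == 256, ]
  for (i in seq_len(nrow(pairs))) {
    a <- leaves[leaves$patch_id == pairs$train_patch_id[i], ]
    b <- leaves[leaves$patch_id == pairs$val_patch_id[i], ]
    expect_equal(a$wsi_id, b$wsi_id)
    # 4-neighbourhood adjacency on the 256 grid
    expect_equal(abs(a$row - b$row) + abs(a$col - b$col), 256)
  }
  # train and val patch sets are disjoint and equal-sized (0.5 ratio)
  expect_equal(length(intersect(pairs$train_patch_id, pairs$val_patch_id)), 0)
  expect_equal(anyDuplicated(c(pairs$train_patch_id, pairs$val_patch_id)), 0)
  expect_equal(length(pairs$val_patch_id) / length(pairs$train_patch_id), 1.0)
  # requesting more than available returns all available; 3 returns 3
  p3 <- sample_pairs(sim$manifest, 3, seed = 2)
  expect_true(all(table(p3$wsi_id) <= 3))
  # deterministic under a fixed seed
  expect_identical(pairs, sample_pairs(sim$manifest, "all", seed = 2))
})

test_that("encoder config validates widths and modes", {
  expect_error(encoder_config(width = 100L), "width")
  expect_error(encoder_config(compression_mode = "other"), "arg")
  expect_equal(encoder_config(width = 2L)$width, 2L)
})

test_that("encoder training learns identities and logs epochs", {
  sim <- sim_small()
  pairs <- sample_pairs(sim$manifest, "all", seed = 3)
  ds <- make_identity_dataset(sim$slides, pairs, size = 32L)
  cfg <- encoder_config(width = 16L, input_px = 32L,
                        trunk_channels = c(16L, 32L, 64L, 64L))
  enc <- train_identity_encoder(ds$train_imgs, ds$train_ids, cfg,
                                val_imgs = ds$val_imgs, val_ids = ds$val_ids,
                                epochs = 25L, lr = 5e-3, seed = 5)
  expect_equal(nrow(enc$log), 25)
  acc <- pairing_accuracy(enc, ds$val_imgs, ds$val_ids)
  # 4 well-separated synthetic slides: far above the 1/4 chance level
  expect_gt(acc, 0.6)
  # untrained encoder sits near chance
  cfg0 <- encoder_config(width = 16L, input_px = 32L)
  p0 <- wsimil:::encoder_init(cfg0, length(unique(ds$train_ids)), seed = 5)
  acc0 <- wsimil:::pairing_accuracy_raw(p0, cfg0, ds$val_imgs, ds$val_ids)
  expect_lt(acc0, 0.55)
  expect_gt(acc, acc0 + 0.2)
  # deterministic retrain
  enc2 <- train_identity_encoder(ds$train_imgs, ds$train_ids, cfg,
                                 epochs = 25L, lr = 5e-3, seed = 5)
  expect_identical(enc$params, enc2$params)
  expect_error(train_identity_encoder(ds$train_imgs, rep(1L, length(ds$train_imgs)),
                                      cfg), "degenerate")
})

test_that("extract_features emits d-length deterministic vectors", {
  sim <- sim_small()
  pairs <- sample_pairs(sim$manifest, 3, seed = 9)
  ds <- make_identity_dataset(sim$slides, pairs, size = 16L)
  for (d in c(64L, 2L)) {
    cfg <- encoder_config(width = d, input_px = 16L)
    enc <- train_identity_encoder(ds$train_imgs, ds$train_ids, cfg,
                                  epochs = 2L, seed = 1)
    fx <- extract_features(enc, ds$val_imgs)
    expect_equal(ncol(fx), d)
    expect_equal(nrow(fx), length(ds$val_imgs))
    # duplicate image -> identical vector; repeated call identical
    fx2 <- extract_features(enc, ds$val_imgs[c(1, 1)])
    expect_identical(fx2[1, ], fx2[2, ])
    expect_identical(fx, extract_features(enc, ds$val_imgs))
  }
  cfg <- encoder_config(width = 8L, input_px = 16L)
  enc <- train_identity_encoder(ds$train_imgs, ds$train_ids, cfg,
                                epochs = 1L, seed = 1)
  bad <- list(array(0, c(32, 32, 3)))
  expect_error(extract_features(enc, bad), "size mismatch")
  expect_error(pairing_accuracy(enc, list(), integer(0)), "empty validation")
})

test_that("encoder backward pass matches finite differences", {
  set.seed(12)
  for (mode in c("conv2d", "dense")) {
    cfg <- encoder_config(compression_mode = mode, width = 4L, input_px = 16L,
                          trunk_channels = c(4L, 6L, 8L, 8L))
    params <- wsimil:::encoder_init(cfg, 3L, seed = 2)
    X <- array(runif(16 * 16 * 3 * 5), c(16, 16, 3, 5))
    y <- c(1L, 2L, 3L, 1L, 2L)
    fw <- wsimil:::encoder_forward(params, X, cfg)
    bw <- wsimil:::encoder_backward(params, fw, X, y, cfg)
    v <- wsimil:::flatten_params(params)
    g <- wsimil:::flatten_params(bw$grads[names(params)])
    lossat <- function(vv) {
      p <- wsimil:::unflatten_params(vv, params)
      f <- wsimil:::encoder_forward(p, X, cfg)
      wsimil:::encoder_backward(p, f, X, y, cfg)$loss
    }
    for (i in sample(length(v), 25)) {
      e <- 1e-5
      vp <- v; vp[i] <- vp[i] + e
      vm <- v; vm[i] <- vm[i] - e
      expect_equal(g[i], (lossat(vp) - lossat(vm)) / (2 * e), tolerance = 1e-3)
    }
  }
})

test_that("feature store round-trips bit-exactly", {
  td <- withr::local_tempdir()
  set.seed(3)
  feats <- list(w1 = matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL)),
                w2 = matrix(rnorm(8), 2, 4, dimnames = list(c("d", "e"), NULL)))
  save_feature_store(file.path(td, "store"), feats)
  back <- load_feature_store(file.path(td, "store"))
  expect_identical(back$w1, feats$w1)
  expect_identical(back$w2, feats$w2)
})
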