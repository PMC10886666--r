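# Hierarchical patch grid: geometry, tissue filtering, clustering,
# subdivision partition properties, bilinear resize, multiresolution
# concatenation.

mask_fixture <- function() {
  # deterministic 2048 x 2048 mask with blocky composition
  m <- matrix(0L, 2048, 2048)
  m[1:1024, 1:1024] <- 1L                    # pure stroma quadrant
  m[1:1024, 1025:2048] <- 2L                 # pure epithelium quadrant
  m[1025:2048, 1:512] <- 1L                  # half-stroma strip
  m                                          # lower-right: background
}

test_that("extract_grid tiles and computes fractions", {
  m <- mask_fixture()
  g <- extract_grid(m, "w", 1024L)
  expect_equal(nrow(g), 4)                   # 2048^2 -> 4 patches at 1024
  expect_setequal(g$level_px, 1024L)
  g <- g[order(g$row, g$col), ]
  expect_equal(g$stroma_frac, c(1, 0, 0.5, 0))
  expect_equal(g$epithelium_frac, c(0, 1, 0, 0))
  expect_equal(g$tissue_frac, g$stroma_frac + g$epithelium_frac)
  # all-background mask
  g0 <- extract_grid(matrix(0L, 1024, 1024), "w0", 1024L)
  expect_equal(g0$tissue_frac, 0)
  # half stroma / half epithelium in one patch
  mh <- matrix(c(rep(1L, 512 * 1024), rep(2L, 512 * 1024)), 1024, 1024)
  gh <- extract_grid(mh, "wh", 1024L)
  expect_equal(gh$stroma_frac, 0.5)
  expect_equal(gh$epithelium_frac, 0.5)
  expect_error(extract_grid(matrix(0L, 1000, 1000), level_px = 1024L), "divide")
})

test_that("filter_tissue applies an inclusive threshold and is monotone", {
  p <- data.frame(tissue_frac = c(0.49, 0.5, 0.51, 0))
  expect_equal(filter_tissue(p)$tissue_frac, c(0.5, 0.51))
  expect_equal(nrow(filter_tissue(p[0, , drop = FALSE])), 0)
  # raising the threshold never grows the retained set
  set.seed(2)
  q <- data.frame(tissue_frac = runif(100))
  sizes <- vapply(seq(0, 1, 0.1), function(th) nrow(filter_tissue(q, th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("assign_cluster implements the composition rule totally", {
  expect_equal(assign_cluster(0.6, 0.2), "C1")
  expect_equal(assign_cluster(0.2, 0.7), "C3")
  expect_equal(assign_cluster(0.5, 0.5), "C2")
  expect_equal(assign_cluster(0.51, 0.49), "C1")
  expect_error(assign_cluster(1.2, 0), "input error")
  # totality over a grid of admissible fractions
  s <- rep(seq(0, 1, 0.05), each = 21)
  e <- rep(seq(0, 1, 0.05), times = 21)
  keep <- s + e <= 1
  cl <- assign_cluster(s[keep], e[keep])
  expect_true(all(cl %in% c("C1", "C2", "C3")))
})

test_that("subdivision tiles parents exactly and conserves pixel counts", {
  m <- mask_fixture()
  g1024 <- extract_grid(m, "w", 1024L)
  kids <- subdivide(g1024, m)
  expect_equal(nrow(kids), 16)               # 4 children per parent
  for (pid in g1024$patch_id) {
    k <- kids[kids$parent_id == pid, ]
    expect_equal(nrow(k), 4)
    p <- g1024[g1024$patch_id == pid, ]
    # children tile the parent: fraction conservation
    expect_equal(mean(k$stroma_frac), p$stroma_frac)
    expect_equal(mean(k$epithelium_frac), p$epithelium_frac)
    # children cover the parent's extent without overlap
    expect_setequal(paste(k$row - p$row, k$col - p$col),
                    c("0 0", "0 512", "512 0", "512 512"))
  }
  leaves <- subdivide(kids, m)
  expect_equal(nrow(leaves), 64)             # 16 leaves per 1024 patch
  expect_error(subdivide(leaves, m), "usage error")
})

test_that("tile_wsi filters at 1024 and children inherit retention", {
  m <- mask_fixture()
  man <- tile_wsi(m, "w")                    # background quadrant dropped
  expect_equal(sum(man$level_px == 1024), 3)
  expect_equal(sum(man$level_px == 512), 12)
  expect_equal(sum(man$level_px == 256), 48)
  # a retained-but-low-tissue child exists (retention inherited, not re-filtered)
  kids <- man[man$level_px == 512, ]
  expect_true(any(kids$tissue_frac < 0.5))
})

test_that("resize_to_256 performs bilinear downsampling", {
  # constant image stays constant
  cimg <- array(0.42, c(1024, 1024, 3))
  out <- resize_to_256(cimg)
  expect_equal(dim(out), c(256, 256, 3))
  expect_equal(max(abs(out - 0.42)), 0, tolerance = 1e-12)
  # 256 input returned unchanged
  small <- array(runif(256 * 256 * 3), c(256, 256, 3))
  expect_identical(resize_to_256(small), small)
  # period-2 checkerboard downsampled 4x: mean preserved within 1 gray level
  cb <- (outer(1:1024, 1:1024, "+") %% 2)
  dcb <- resize_to_256(cb)
  expect_lt(abs(mean(dcb) - mean(cb)), 1 / 255)
  expect_error(resize_to_256(matrix(0, 512, 256)), "square")
})

test_that("multiresolution instances concatenate leaf-to-root with 1024 clusters", {
  m <- mask_fixture()
  man <- tile_wsi(m, "w")
  d <- 5L
  fake <- function(level) {
    rows <- man[man$level_px == level, ]
    mat <- matrix(rep(seq_len(nrow(rows)), each = d), ncol = d, byrow = TRUE) +
      level / 1e6
    rownames(mat) <- rows$patch_id
    mat
  }
  f256 <- fake(256L); f512 <- fake(512L); f1024 <- fake(1024L)
  mr <- build_multires_instances(man, f256, f512, f1024)
  expect_equal(ncol(mr$features), 3 * d)
  expect_equal(nrow(mr$features), 48)
  # concatenation order [256 || 512 || 1024] by the level marker
  expect_true(all(abs(mr$features[, 1] %% 1 - 0.000256) < 1e-9))
  expect_true(all(abs(mr$features[, d + 1] %% 1 - 0.000512) < 1e-9))
  expect_true(all(abs(mr$features[, 2 * d + 1] %% 1 - 0.001024) < 1e-9))
  # cluster comes from the 1024 ancestor
  leaves <- man[man$level_px == 256, ]
  mid <- man[man$level_px == 512, ]
  roots <- man[man$level_px == 1024, ]
  gid <- mid$parent_id[match(leaves$parent_id, mid$patch_id)]
  expect_equal(unname(mr$cluster), roots$cluster[match(gid, roots$patch_id)])
  # a leaf whose ancestors lack features raises a pipeline error naming it
  expect_error(
    build_multires_instances(man, f256, f512[-1, , drop = FALSE], f1024),
    "missing ancestor")
  # instance length scales with encoder width
  f256b <- fake(256L)[, 1:2]; f512b <- fake(512L)[, 1:2]; f1024b <- fake(1024L)[, 1:2]
  expect_equal(ncol(build_multires_instances(man, f256b, f512b, f1024b)$features), 6)
})
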