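# Neighbouring patch-pair dataset for self-supervised identity training,
# plus the on-disk feature store. Adjacency is the 4-neighbourhood on the
# 256-pixel leaf grid. One member of every sampled pair goes to the
# training split and the other to the validation split (a 0.5
# validation:total ratio); pairs are sampled node-disjointly so the two
# splits never share a patch.

#' Sample neighbouring patch pairs
#'
#' For each slide, enumerates edge-adjacent retained 256-pixel leaves and
#' samples up to `n_pairs_per_wsi` node-disjoint pairs without
#' replacement; when fewer are available, all available pairs are used.
#' Slides with no adjacent retained leaves are skipped with a message.
#'
#' @param manifest patch manifest (possibly several slides) from
#'   [tile_wsi()].
#' @param n_pairs_per_wsi 3, 10, or "all" (all available, capped at 100).
#' @param seed integer seed.
#' @return data.frame with columns `wsi_id`, `train_patch_id`,
#'   `val_patch_id`.
#' @export
sample_pairs <- function(manifest, n_pairs_per_wsi = "all", seed = 1) {
  cap <- if (identical(n_pairs_per_wsi, "all")) 100L else as.integer(n_pairs_per_wsi)
  leaves <- manifest[manifest$level_px == 256L, , drop = FALSE]
  out <- list()
  local_seed(derive_seed(seed, "pairs"), {
    for (w in unique(leaves$wsi_id)) {
      lv <- leaves[leaves$wsi_id == w, , drop = FALSE]
      key <- paste(lv$row, lv$col)
      right <- match(paste(lv$row, lv$col + 256L), key)
      down <- match(paste(lv$row + 256L, lv$col), key)
      edges <- rbind(
        cbind(seq_len(nrow(lv)), right)[!is.na(right), , drop = FALSE],
        cbind(seq_len(nrow(lv)), down)[!is.na(down), , drop = FALSE]
      )
      if (nrow(edges) == 0) {
        message(sprintf("sample_pairs: slide %s has no adjacent retained leaves; skipped", w))
        next
      }
      edges <- edges[sample.int(nrow(edges)), , drop = FALSE]
      used <- logical(nrow(lv))
      taken <- list()
      for (i in seq_len(nrow(edges))) {
        if (length(taken) >= cap) break
        a <- edges[i, 1]; b <- edges[i, 2]
        if (used[a] || used[b]) next
        used[a] <- used[b] <- TRUE
        # random side to train
        if (stats::runif(1) < 0.5) taken[[length(taken) + 1L]] <- c(a, b)
        else taken[[length(taken) + 1L]] <- c(b, a)
      }
      if (length(taken) == 0) next
      tk <- do.call(rbind, taken)
      out[[w]] <- data.frame(wsi_id = w,
                             train_patch_id = lv$patch_id[tk[, 1]],
                             val_patch_id = lv$patch_id[tk[, 2]],
                             stringsAsFactors = FALSE)
    }
  })
  if (length(out) == 0) {
    return(data.frame(wsi_id = character(0), train_patch_id = character(0),
                      val_patch_id = character(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Crop and downsample leaf patches to encoder input thumbnails
#'
#' @param image slide RGB array.
#' @param manifest the slide's manifest.
#' @param patch_ids which patches to extract (default: all 256 leaves).
#' @param size thumbnail side in pixels.
#' @return Named list of (size x size x 3) arrays.
#' @export
patch_thumbnails <- function(image, manifest, patch_ids = NULL, size = 32L) {
  rows <- manifest[manifest$level_px == 256L, , drop = FALSE]
  if (!is.null(patch_ids)) rows <- rows[match(patch_ids, rows$patch_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    resize_bilinear(crop_patch(image, rows[i, ]), size)
  })
  names(out) <- rows$patch_id
  out
}

#' Assemble the identity-training dataset from sampled pairs
#'
#' @param slides named list (by wsi_id) with elements `image` and
#'   `manifest`.
#' @param pairs data.frame from [sample_pairs()].
#' @param size encoder input side.
#' @return List with `train_imgs`, `train_ids`, `val_imgs`, `val_ids`,
#'   and `wsi_levels` (the identity index -> wsi_id mapping).
#' @export
make_identity_dataset <- function(slides, pairs, size = 32L) {
  wsis <- unique(pairs$wsi_id)
  tr <- list(); va <- list(); tri <- integer(0); vai <- integer(0)
  for (k in seq_along(wsis)) {
    w <- wsis[k]
    pw <- pairs[pairs$wsi_id == w, ]
    sl <- slides[[w]]
    th <- patch_thumbnails(sl$image, sl$manifest,
                           patch_ids = c(pw$train_patch_id, pw$val_patch_id),
                           size = size)
    tr <- c(tr, th[pw$train_patch_id])
    va <- c(va, th[pw$val_patch_id])
    tri <- c(tri, rep(k, nrow(pw)))
    vai <- c(vai, rep(k, nrow(pw)))
  }
  list(train_imgs = tr, train_ids = tri, val_imgs = va, val_ids = vai,
       wsi_levels = wsis)
}

# --- feature store ---------------------------------------------------------

#' Save per-slide feature matrices to a feature store
#'
#' One array file per slide plus a CSV manifest fixing the row order;
#' matrices round-trip bit-exactly.
#'
#' @param store_dir directory (created if needed).
#' @param features named list (by wsi_id) of matrices with patch-id rownames.
#' @return `store_dir`, invisibly.
#' @export
save_feature_store <- function(store_dir, features) {
  dir.create(store_dir, showWarnings = FALSE, recursive = TRUE)
  man <- list()
  for (w in names(features)) {
    m <- features[[w]]
    saveRDS(m, file.path(store_dir, paste0(w, ".rds")))
    man[[w]] <- data.frame(wsi_id = w, patch_id = rownames(m),
                           row_index = seq_len(nrow(m)), stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, c(man, list(make.row.names = FALSE))),
                   file.path(store_dir, "manifest.csv"), row.names = FALSE)
  invisible(store_dir)
}

#' Load a feature store written by [save_feature_store()]
#' @param store_dir store directory.
#' @return Named list of matrices in manifest order.
#' @export
load_feature_store <- function(store_dir) {
  man <- utils::read.csv(file.path(store_dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  out <- lapply(unique(man$wsi_id), function(w) {
    m <- readRDS(file.path(store_dir, paste0(w, ".rds")))
    m[man$patch_id[man$wsi_id == w], , drop = FALSE]
  })
  names(out) <- unique(man$wsi_id)
  out
}
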