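# Hierarchical patch extraction and composition clustering. Patches are
# square, axis-aligned, non-overlapping tiles addressed by 0-based pixel
# origins (row, col) with half-open extents [origin, origin + level).
# A 1024 patch subdivides into four 512 patches and sixteen 256 leaves;
# tissue-content filtering is applied at the 1024 level only, and
# children inherit retention.

patch_id_of <- function(wsi_id, level, row, col) {
  sprintf("%s_L%d_r%d_c%d", wsi_id, level, row, col)
}

#' Composition-cluster assignment
#'
#' C1 when stroma fraction strictly exceeds 0.5, C3 when epithelium
#' fraction strictly exceeds 0.5, C2 otherwise.
#'
#' @param stroma_frac,epithelium_frac fractions in \[0,1\] (vectorised).
#' @return Character vector in {"C1","C2","C3"}.
#' @export
assign_cluster <- function(stroma_frac, epithelium_frac) {
  if (any(stroma_frac < 0 | stroma_frac > 1 | epithelium_frac < 0 | epithelium_frac > 1)) {
    stop("input error: fractions must lie in [0, 1]")
  }
  ifelse(stroma_frac > 0.5, "C1", ifelse(epithelium_frac > 0.5, "C3", "C2"))
}

# Per-block label fractions for a regular grid of side `level` over
# `mask`, via two fold-and-sum passes (rows then columns).
block_sums <- function(M, level) {
  nr <- nrow(M); nc <- ncol(M)
  nbr <- nr %/% level
  # fold rows: column-major segments of length `level` within each column
  s1 <- matrix(.colSums(M, level, nbr * nc), nbr, nc)
  t(matrix(.colSums(t(s1), level, (nc %/% level) * nbr), nc %/% level, nbr))
}

block_fractions <- function(mask, level) {
  npx <- level * level
  s <- block_sums(mask == 1L, level) / npx
  e <- block_sums(mask == 2L, level) / npx
  nbr <- nrow(s)
  data.frame(block = seq_len(length(s)) - 1L,     # column-major, 0-based
              stroma_frac = as.vector(s), epithelium_frac = as.vector(e))
}

#' Extract a non-overlapping patch grid
#'
#' Tiles the image with `level_px` squares and computes per-patch stroma,
#' epithelium and tissue fractions from the label mask (stroma = 1,
#' epithelium = 2; background and artifact pixels count as non-tissue).
#'
#' @param mask integer label mask (rows x cols).
#' @param wsi_id slide identifier recorded in the manifest.
#' @param level_px patch side in pixels; must divide both mask dimensions.
#' @param parent_id optional parent patch id (used internally).
#' @param origin optional (row, col) offset of the mask within the slide.
#' @return Patch manifest data.frame with columns `wsi_id`, `patch_id`,
#'   `parent_id`, `level_px`, `row`, `col`, `stroma_frac`,
#'   `epithelium_frac`, `tissue_frac`, `cluster`.
#' @export
extract_grid <- function(mask, wsi_id = "wsi", level_px = 1024L,
                         parent_id = NA_character_, origin = c(0L, 0L)) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr %% level_px != 0 || nc %% level_px != 0) {
    stop("input error: level_px must divide the mask dimensions")
  }
  fr <- block_fractions(mask, level_px)
  nbr <- nr %/% level_px
  brow <- fr$block %% nbr
  bcol <- fr$block %/% nbr
  row0 <- origin[1] + brow * level_px
  col0 <- origin[2] + bcol * level_px
  data.frame(
    wsi_id = wsi_id,
    patch_id = patch_id_of(wsi_id, level_px, row0, col0),
    parent_id = parent_id,
    level_px = as.integer(level_px),
    row = as.integer(row0),
    col = as.integer(col0),
    stroma_frac = fr$stroma_frac,
    epithelium_frac = fr$epithelium_frac,
    tissue_frac = fr$stroma_frac + fr$epithelium_frac,
    cluster = assign_cluster(fr$stroma_frac, fr$epithelium_frac),
    stringsAsFactors = FALSE
  )
}

#' Tissue-content filter
#'
#' Keeps patches whose tissue fraction (stroma + epithelium) is at least
#' `threshold`. The comparison is `>=` ("at least 50% tissue content").
#'
#' @param patches patch manifest data.frame.
#' @param threshold minimum tissue fraction (default 0.5).
#' @return Filtered manifest.
#' @export
filter_tissue <- function(patches, threshold = 0.5) {
  patches[patches$tissue_frac >= threshold, , drop = FALSE]
}

#' Subdivide patches into four children each
#'
#' A 1024 patch yields four 512 children; a 512 patch yields four 256
#' children. Children tile the parent exactly and their fractions are
#' recomputed from the mask.
#'
#' @param patches manifest rows at level 1024 or 512 of one slide.
#' @param mask the slide's label mask.
#' @return Manifest of the children, with `parent_id` set.
#' @export
subdivide <- function(patches, mask) {
  if (any(patches$level_px <= 256L)) {
    stop("usage error: 256-pixel patches cannot be subdivided")
  }
  out <- lapply(seq_len(nrow(patches)), function(i) {
    p <- patches[i, ]
    child <- p$level_px %/% 2L
    sub <- mask[p$row + seq_len(p$level_px), p$col + seq_len(p$level_px), drop = FALSE]
    extract_grid(sub, wsi_id = p$wsi_id, level_px = child,
                 parent_id = p$patch_id, origin = c(p$row, p$col))
  })
  do.call(rbind, out)
}

#' Tile one slide into the full patch hierarchy
#'
#' Extracts the 1024 grid, applies the tissue-content filter, and
#' subdivides retained patches to 512 and 256. Children inherit retention
#' from their 1024 ancestor and are not re-filtered.
#'
#' @param mask slide label mask.
#' @param wsi_id slide identifier.
#' @param threshold tissue-content threshold at the 1024 level.
#' @return Manifest data.frame containing all three levels.
#' @export
tile_wsi <- function(mask, wsi_id = "wsi", threshold = 0.5) {
  g1024 <- filter_tissue(extract_grid(mask, wsi_id, 1024L), threshold)
  if (nrow(g1024) == 0) return(g1024)
  g512 <- subdivide(g1024, mask)
  g256 <- subdivide(g512, mask)
  rbind(g1024, g512, g256)
}

#' Crop a patch out of an image
#'
#' @param image array (rows x cols x channels) or matrix.
#' @param patch one manifest row.
#' @return The patch pixels (level x level x channels).
#' @export
crop_patch <- function(image, patch) {
  ri <- patch$row + seq_len(patch$level_px)
  ci <- patch$col + seq_len(patch$level_px)
  if (length(dim(image)) == 3) image[ri, ci, , drop = FALSE] else image[ri, ci, drop = FALSE]
}

#' Bilinear resize to 256 x 256
#'
#' Downsamples a square 512- or 1024-pixel patch to 256 pixels with
#' bilinear interpolation; a 256 input is returned unchanged.
#'
#' @param img square matrix or (h x w x c) array.
#' @return 256 x 256 (x c) image.
#' @export
resize_to_256 <- function(img) {
  d <- dim(img)
  if (d[1] != d[2]) stop("input error: patch must be square")
  if (d[1] == 256L) return(img)
  EBImage::imageData(EBImage::resize(img, w = 256L, h = 256L, filter = "bilinear"))
}

# generic bilinear resize used by the encoder's thumbnail path
resize_bilinear <- function(img, size) {
  if (dim(img)[1] == size && dim(img)[2] == size) return(img)
  EBImage::imageData(EBImage::resize(img, w = size, h = size, filter = "bilinear"))
}

#' Concatenate multiresolution features for retained leaves
#'
#' For every 256 leaf with a full ancestor chain, concatenates the
#' feature vectors in leaf-to-root order \[256 || 512 || 1024\] and labels
#' the instance with its 1024 ancestor's composition cluster.
#'
#' @param manifest patch manifest from [tile_wsi()] (all levels).
#' @param leaf_features,parent_features,grandparent_features numeric
#'   matrices with patch ids as rownames for levels 256, 512, 1024.
#' @return List with `features` (leaves x 3d matrix, rownames = leaf ids)
#'   and `cluster` (from the 1024 ancestor).
#' @export
build_multires_instances <- function(manifest, leaf_features, parent_features,
                                     grandparent_features) {
  leaves <- manifest[manifest$level_px == 256L, ]
  mid <- manifest[manifest$level_px == 512L, ]
  roots <- manifest[manifest$level_px == 1024L, ]
  leaves <- leaves[leaves$patch_id %in% rownames(leaf_features), , drop = FALSE]
  parent_of <- stats::setNames(mid$parent_id, mid$patch_id)
  cluster_of <- stats::setNames(roots$cluster, roots$patch_id)
  out <- lapply(seq_len(nrow(leaves)), function(i) {
    lid <- leaves$patch_id[i]
    pid <- leaves$parent_id[i]
    gid <- parent_of[[pid]]
    if (is.null(gid) || !(pid %in% rownames(parent_features)) ||
        !(gid %in% rownames(grandparent_features))) {
      stop(sprintf("pipeline error: missing ancestor features for leaf %s", lid))
    }
    list(f = c(leaf_features[lid, ], parent_features[pid, ],
               grandparent_features[gid, ]),
         cl = cluster_of[[gid]])
  })
  feats <- do.call(rbind, lapply(out, `[[`, "f"))
  rownames(feats) <- leaves$patch_id
  list(features = feats, cluster = vapply(out, `[[`, character(1), "cl"))
}
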