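# Compression-sweep harness. Slides are processed one at a time --
# generate, tile, sample pairs, cut thumbnails, discard pixels -- so the
# experiment's memory footprint is the thumbnail datasets, not the
# slide images.

#' Generate a set of synthetic slides with manifests
#'
#' Holds all slide images in memory; intended for small cohorts fed to
#' the end-to-end pipeline. For encoder sweeps over many slides use
#' [build_pair_datasets()], which streams slides.
#'
#' @param n_wsis number of slides.
#' @param image_size_px slide side (multiple of 1024).
#' @param seed root seed.
#' @param spec_args extra arguments passed to [cohort_spec()].
#' @return List with `slides` (named list of `image`, `mask`,
#'   `manifest`), `cohort`, `manifest` (all slides), and `spec`.
#' @export
simulate_slides <- function(n_wsis, image_size_px = 1024L, seed = 1,
                            spec_args = list()) {
  spec <- do.call(cohort_spec, c(list(n_patients = n_wsis,
                                      image_size_px = image_size_px,
                                      rng_seed = seed), spec_args))
  cohort <- generate_cohort(spec)
  slides <- lapply(seq_len(n_wsis), function(i) {
    gi <- generate_tissue_image(spec, cohort[i, ])
    list(image = gi$image, mask = gi$mask,
         manifest = tile_wsi(gi$mask, cohort$patient_id[i]))
  })
  names(slides) <- cohort$patient_id
  list(slides = slides, cohort = cohort,
       manifest = do.call(rbind, c(lapply(slides, `[[`, "manifest"),
                                   list(make.row.names = FALSE))),
       spec = spec)
}

#' Build identity-pair thumbnail datasets, streaming one slide at a time
#'
#' For each slide: generate image and mask, tile, sample neighbouring
#' pairs at every requested budget, cut encoder-input thumbnails for the
#' sampled patches, and release the pixels. All budgets share the same
#' slides.
#'
#' @param n_wsis number of slides (identities).
#' @param image_size_px slide side.
#' @param pair_budgets vector of budgets (3, 10, "all").
#' @param input_px thumbnail side.
#' @param seed root seed for slides and pair sampling.
#' @param spec_args extra [cohort_spec()] arguments.
#' @return Named list (by budget) of datasets with `train_imgs`,
#'   `train_ids`, `val_imgs`, `val_ids`, `wsi_levels`.
#' @export
build_pair_datasets <- function(n_wsis, image_size_px = 2048L,
                                pair_budgets = "all", input_px = 16L,
                                seed = 1, spec_args = list()) {
  spec <- do.call(cohort_spec, c(list(n_patients = n_wsis,
                                      image_size_px = image_size_px,
                                      rng_seed = seed), spec_args))
  cohort <- generate_cohort(spec)
  budgets <- as.character(pair_budgets)
  ds <- stats::setNames(lapply(budgets, function(b)
    list(train_imgs = list(), train_ids = integer(0),
         val_imgs = list(), val_ids = integer(0),
         wsi_levels = character(0))), budgets)
  for (i in seq_len(n_wsis)) {
    gi <- generate_tissue_image(spec, cohort[i, ])
    man <- tile_wsi(gi$mask, cohort$patient_id[i])
    for (b in budgets) {
      budget <- if (b == "all") "all" else as.integer(b)
      pairs <- sample_pairs(man, budget,
                            seed = derive_seed(seed, paste0("pairs_", b, "_", i)))
      if (nrow(pairs) == 0) next
      th <- patch_thumbnails(gi$image, man,
                             patch_ids = c(pairs$train_patch_id, pairs$val_patch_id),
                             size = input_px)
      k <- length(ds[[b]]$wsi_levels) + 1L
      ds[[b]]$train_imgs <- c(ds[[b]]$train_imgs, th[pairs$train_patch_id])
      ds[[b]]$val_imgs <- c(ds[[b]]$val_imgs, th[pairs$val_patch_id])
      ds[[b]]$train_ids <- c(ds[[b]]$train_ids, rep(k, nrow(pairs)))
      ds[[b]]$val_ids <- c(ds[[b]]$val_ids, rep(k, nrow(pairs)))
      ds[[b]]$wsi_levels <- c(ds[[b]]$wsi_levels, cohort$patient_id[i])
    }
  }
  ds
}

#' Pairing-accuracy sweep over encoder configurations
#'
#' Trains the identity encoder for each (pair budget, compression mode,
#' width, training seed) combination on a fixed slide set and records
#' validation pairing accuracy.
#'
#' @param datasets result of [build_pair_datasets()].
#' @param widths compression widths to test.
#' @param modes compression modes ("conv2d", "dense").
#' @param input_px encoder input side (must match the datasets).
#' @param epochs,lr,batch_size training schedule.
#' @param train_seeds one row of results per seed and configuration.
#' @param trunk_channels trunk widths.
#' @return data.frame with columns `seed`, `pairs`, `mode`, `width`,
#'   `n_train`, `accuracy`.
#' @export
pairing_sweep <- function(datasets, widths = c(1536L, 64L, 32L),
                          modes = "conv2d", input_px = 16L, epochs = 60L,
                          lr = 5e-3, batch_size = 64L, train_seeds = 1L,
                          trunk_channels = c(16L, 32L, 64L, 64L)) {
  out <- list()
  for (s in train_seeds) for (pb in names(datasets)) {
    d <- datasets[[pb]]
    for (mode in modes) for (wd in widths) {
      cfg <- encoder_config(compression_mode = mode, width = as.integer(wd),
                            input_px = input_px, trunk_channels = trunk_channels)
      enc <- train_identity_encoder(d$train_imgs, d$train_ids, cfg,
                                    epochs = epochs, batch_size = batch_size,
                                    lr = lr,
                                    seed = derive_seed(s, paste0(pb, mode, wd)))
      out[[length(out) + 1L]] <- data.frame(
        seed = s, pairs = pb, mode = mode, width = as.integer(wd),
        n_train = length(d$train_imgs),
        accuracy = pairing_accuracy(enc, d$val_imgs, d$val_ids),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
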