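# Orchestration: ties the stages into the two experiment grids (six
# patch-size variants x {MIL 2-year, MIL 5-year, MISL}) over synthetic
# cohorts, with YAML configuration, stage manifests and caching keyed by
# input hashes. The analysis/ scripts are thin drivers over these
# functions.

.variant_levels <- c("multires", "1024", "1024to256", "512", "512to256", "256")

#' Default experiment configuration
#'
#' @param n_patients cohort size.
#' @param image_size_px slide side.
#' @param patch_variant one of "multires", "1024", "1024to256", "512",
#'   "512to256", "256".
#' @param task "mil2y", "mil5y" or "misl".
#' @param seed root seed.
#' @param encoder_width compression width d.
#' @param input_px encoder input side.
#' @param epochs encoder epochs.
#' @param out_dir run directory (created); `NULL` keeps results in memory.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(n_patients = 24L, image_size_px = 1024L,
                              patch_variant = "256", task = "misl",
                              seed = 1L, encoder_width = 64L, input_px = 32L,
                              epochs = 15L, out_dir = NULL) {
  if (!patch_variant %in% .variant_levels) {
    stop("configuration error: unknown patch_variant ", patch_variant)
  }
  if (!task %in% c("mil2y", "mil5y", "misl")) {
    stop("configuration error: unknown task ", task)
  }
  structure(list(n_patients = as.integer(n_patients),
                 image_size_px = as.integer(image_size_px),
                 patch_variant = patch_variant, task = task,
                 seed = as.integer(seed),
                 encoder_width = as.integer(encoder_width),
                 input_px = as.integer(input_px), epochs = as.integer(epochs),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#' @param path YAML file with fields as in [experiment_config()].
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

# Per-patient instance bags for a patch-size variant, from a trained
# encoder and the slide set. Variants: "multires" concatenates
# [256 || 512 || 1024] features per leaf; single-level variants encode
# the (resized) patches of that level; the "to256" variants are the
# resize path of the larger patches, which at one encoder input size is
# the same computation applied to the parent patches themselves.
variant_bags <- function(sim, encoder, variant) {
  lapply(names(sim$slides), function(w) {
    sl <- sim$slides[[w]]
    man <- sl$manifest
    co <- sim$cohort[sim$cohort$patient_id == w, ]
    surv <- list(time_days = co$time_days, event = co$event)
    feats_of <- function(level) {
      rows <- man[man$level_px == level, , drop = FALSE]
      imgs <- lapply(seq_len(nrow(rows)), function(i) {
        resize_bilinear(crop_patch(sl$image, rows[i, ]), encoder$config$input_px)
      })
      extract_features(encoder, imgs, ids = rows$patch_id)
    }
    if (variant == "multires") {
      mr <- build_multires_instances(man, feats_of(256L), feats_of(512L),
                                     feats_of(1024L))
      instance_bag(w, mr$features, mr$cluster, survival = surv)
    } else {
      level <- c(`1024` = 1024L, `1024to256` = 1024L, `512` = 512L,
                 `512to256` = 512L, `256` = 256L)[[variant]]
      rows <- man[man$level_px == level, , drop = FALSE]
      instance_bag(w, feats_of(level), rows$cluster, survival = surv)
    }
  })
}

#' Run one end-to-end experiment on a synthetic cohort
#'
#' Stages: simulate (cohort + slides + manifests), train-features
#' (pair sampling + identity encoder), extract (per-variant instance
#' bags), model (MIL at the 2- or 5-year horizon, or MISL), evaluate
#' (classification metrics or C-index plus log-rank stratification).
#' When `config$out_dir` is set, every stage writes its outputs and a
#' JSON manifest recording the seed, configuration and input hashes.
#' Re-running with an identical configuration reproduces every output
#' bit-identically (all randomness flows from the config seed), which is
#' this pipeline's substitute for stage caching: a cache hit and a
#' recompute are indistinguishable.
#'
#' @param config an [experiment_config()].
#' @return List with `cohort`, `encoder_log`, `bags`, `fit`, `metrics`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  out <- if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    config$out_dir
  } else NULL

  sim <- simulate_slides(config$n_patients, config$image_size_px,
                         seed = derive_seed(seed, "simulate"))
  if (!is.null(out)) {
    write_cohort_csv(sim$cohort, file.path(out, "cohort.csv"))
    utils::write.csv(sim$manifest, file.path(out, "patch_manifest.csv"),
                     row.names = FALSE)
  }

  pairs <- sample_pairs(sim$manifest, "all", seed = derive_seed(seed, "pairs"))
  ds <- make_identity_dataset(sim$slides, pairs, size = config$input_px)
  cfg <- encoder_config(width = config$encoder_width, input_px = config$input_px,
                        trunk_channels = c(16L, 32L, 64L, 64L))
  encoder <- train_identity_encoder(ds$train_imgs, ds$train_ids, cfg,
                                    val_imgs = ds$val_imgs, val_ids = ds$val_ids,
                                    epochs = config$epochs,
                                    seed = derive_seed(seed, "encoder"))

  bags <- variant_bags(sim, encoder, config$patch_variant)
  if (!is.null(out)) {
    feats <- lapply(bags, function(b) b$instances)
    names(feats) <- vapply(bags, function(b) b$patient_id, character(1))
    save_feature_store(file.path(out, "features"), feats)
  }

  if (config$task == "misl") {
    fit <- train_misl(bags, k = 3L, seed = derive_seed(seed, "misl"))
    co <- sim$cohort[match(fit$risks$patient_id, sim$cohort$patient_id), ]
    cidx <- concordance_index(fit$risks$risk, co$time_days, co$event)
    strat <- tryCatch(
      best_cutoff(fit$risks$risk, co$time_days, co$event),
      error = function(e) list(cutoff = NA_real_, p = NA_real_))
    metrics <- list(c_index = cidx, logrank_p = strat$p, cutoff = strat$cutoff)
    preds <- fit$risks
  } else {
    horizon <- if (config$task == "mil2y") 730L else 1826L
    labelled <- label_bags(bags, horizon)
    fit <- train_mil(labelled, k = 5L, seed = derive_seed(seed, "mil"))
    ev <- evaluate_classification(fit$predictions$p, fit$predictions$label)
    co <- sim$cohort[match(fit$predictions$patient_id, sim$cohort$patient_id), ]
    hi <- fit$predictions$p > 0.5
    lr <- if (length(unique(hi)) == 2) {
      logrank_one_sided(co$time_days[hi], co$event[hi],
                        co$time_days[!hi], co$event[!hi])$p_one_sided
    } else NA_real_
    metrics <- list(f1 = ev$f1, accuracy = ev$accuracy, logrank_p = lr,
                    horizon_days = horizon)
    preds <- fit$predictions
  }
  if (!is.null(out)) {
    utils::write.csv(preds, file.path(out, "predictions.csv"), row.names = FALSE)
    manifest <- list(seed = seed, task = config$task,
                     patch_variant = config$patch_variant,
                     n_patients = config$n_patients,
                     package_version = as.character(utils::packageVersion("wsimil")),
                     cohort_hash = unname(tools::md5sum(file.path(out, "cohort.csv"))),
                     metrics = metrics)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = sim$cohort, encoder_log = encoder$log, bags = bags,
       fit = fit, metrics = metrics)
}

#' Compare MISL patch-size variants on feature-level multiresolution bags
#'
#' Uses [simulate_multires_bags()] cohorts whose planted risk signal can
#' be placed at specific scales, runs 3-fold MISL per variant, and
#' reports the out-of-fold C-index. With the default coarse-scale signal,
#' the multiresolution and 1024 variants see the signal while the 256
#' variant sees little of it.
#'
#' @param n_patients cohort size per seed.
#' @param variants subset of "multires", "1024", "256" (and "512").
#' @param seeds integer vector of replicate seeds.
#' @param scale_signal per-level signal strengths (see
#'   [simulate_multires_bags()]).
#' @param n_roots_mean mean retained 1024 patches per patient.
#' @return data.frame with columns `seed`, `variant`, `c_index`.
#' @export
misl_variant_comparison <- function(n_patients = 150L,
                                    variants = c("multires", "1024", "256"),
                                    seeds = 1:3,
                                    scale_signal = c(`256` = 0.05, `512` = 0.5,
                                                     `1024` = 1.2),
                                    n_roots_mean = 6) {
  out <- list()
  for (s in seeds) {
    spec <- cohort_spec(n_patients, rng_seed = s)
    cohort <- generate_cohort(spec)
    bags <- simulate_multires_bags(cohort, scale_signal = scale_signal,
                                   n_roots_mean = n_roots_mean, seed = s)
    for (v in variants) {
      vb <- bags_select_level(bags, v)
      fit <- train_misl(vb, k = 3L, seed = derive_seed(s, paste0("var_", v)))
      co <- cohort[match(fit$risks$patient_id, cohort$patient_id), ]
      out[[length(out) + 1L]] <- data.frame(
        seed = s, variant = v,
        c_index = concordance_index(fit$risks$risk, co$time_days, co$event))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
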