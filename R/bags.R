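# Feature-level bag simulators. These emulate the output of the trained
# patch-identity encoder -- per-patient bags of instance feature vectors
# with composition-cluster labels -- directly at the feature level, so
# that the MIL and MISL stages can be exercised and calibrated on large
# cohorts without paying for image synthesis and encoder training. The
# image path (generate_tissue_image -> tile -> encode) produces the same
# containers and is used in the end-to-end runs.

#' An instance bag
#'
#' @param patient_id patient identifier.
#' @param instances n x m numeric matrix (n instances, m features).
#' @param cluster_labels length-n character vector in {"C1","C2","C3"}.
#' @param label optional binary relapse label.
#' @param survival optional list(time_days, event).
#' @return List of class `instance_bag`.
#' @export
instance_bag <- function(patient_id, instances, cluster_labels,
                         label = NULL, survival = NULL) {
  instances <- as.matrix(instances)
  if (nrow(instances) < 1) stop("input error: bag must contain at least one instance")
  if (length(cluster_labels) != nrow(instances)) {
    stop("input error: one cluster label per instance required")
  }
  stopifnot(all(cluster_labels %in% c("C1", "C2", "C3")))
  structure(list(patient_id = patient_id, instances = instances,
                 cluster_labels = cluster_labels, label = label,
                 survival = survival),
            class = "instance_bag")
}

# Fixed unit signal direction over the first q of m feature dimensions.
signal_direction <- function(m, q = min(8L, m)) {
  v <- numeric(m)
  v[seq_len(q)] <- 1 / sqrt(q)
  v
}

#' Simulate feature-level instance bags with planted risk signal
#'
#' One bag per patient. Epithelium-dominant (C3) instances are shifted by
#' `signal_strength * latent_risk` along a fixed unit direction in feature
#' space; mixed (C2) instances receive half the shift; stroma-dominant
#' (C1) instances carry no risk information. Instance noise is standard
#' normal. This mirrors how the image generator plants risk in epithelium
#' appearance only.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param n_features feature dimension m (default 32).
#' @param mean_instances mean bag size (Poisson, with a floor of 8).
#' @param signal_strength feature-space shift per unit latent risk.
#' @param seed integer seed.
#' @return List of [instance_bag()]s with `survival` populated.
#' @export
simulate_bags <- function(cohort, n_features = 32L, mean_instances = 40,
                          signal_strength = 1.0, seed = 1) {
  v <- signal_direction(n_features)
  local_seed(derive_seed(seed, "bags"), {
    lapply(seq_len(nrow(cohort)), function(i) {
      n <- max(8L, stats::rpois(1, mean_instances))
      cl <- sample(c("C1", "C2", "C3"), n, replace = TRUE,
                   prob = c(0.3, 0.25, 0.45))
      w <- c(C1 = 0, C2 = 0.5, C3 = 1)[cl]
      X <- matrix(stats::rnorm(n * n_features), n, n_features) +
        outer(w * signal_strength * cohort$latent_risk[i], v)
      instance_bag(cohort$patient_id[i], X, cl,
                   survival = list(time_days = cohort$time_days[i],
                                   event = cohort$event[i]))
    })
  })
}

#' Simulate multiresolution instance bags with scale-specific signal
#'
#' Emulates the multiresolution feature concatenation: each leaf instance
#' carries three feature blocks (256-, 512- and 1024-level, in that
#' order), where the 512 block is shared by the four sibling leaves of a
#' 512 parent and the 1024 block by all sixteen descendants of a 1024
#' patch. The planted risk shift enters block b with strength
#' `scale_signal[b]`, so cohorts can be built whose risk signal lives at
#' coarse scale (visible in the 1024 block, absent from the 256 block).
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param d_per_level feature dimension of each block.
#' @param n_roots_mean mean number of retained 1024 patches per patient
#'   (each contributing 16 leaf instances).
#' @param scale_signal named numeric vector with elements `256`, `512`,
#'   `1024`: shift per unit risk in each block.
#' @param seed integer seed.
#' @return List of [instance_bag()]s whose instance matrices have
#'   `3 * d_per_level` columns, with a `feature_blocks` attribute giving
#'   the column indices of each block.
#' @export
simulate_multires_bags <- function(cohort, d_per_level = 16L, n_roots_mean = 3,
                                   scale_signal = c(`256` = 0.1, `512` = 0.3,
                                                    `1024` = 0.6),
                                   seed = 1) {
  d <- d_per_level
  v <- signal_direction(d)
  blocks <- list(`256` = 1:d, `512` = d + 1:d, `1024` = 2 * d + 1:d)
  local_seed(derive_seed(seed, "multires_bags"), {
    lapply(seq_len(nrow(cohort)), function(i) {
      r <- cohort$latent_risk[i]
      n_roots <- max(1L, stats::rpois(1, n_roots_mean))
      rows <- list()
      cl <- character(0)
      for (root in seq_len(n_roots)) {
        root_cl <- sample(c("C1", "C2", "C3"), 1, prob = c(0.3, 0.25, 0.45))
        w <- c(C1 = 0, C2 = 0.5, C3 = 1)[[root_cl]]
        f1024 <- stats::rnorm(d) + w * scale_signal[["1024"]] * r * v
        for (mid in 1:4) {
          f512 <- stats::rnorm(d) + w * scale_signal[["512"]] * r * v
          for (leaf in 1:4) {
            f256 <- stats::rnorm(d) + w * scale_signal[["256"]] * r * v
            rows[[length(rows) + 1L]] <- c(f256, f512, f1024)
            cl <- c(cl, root_cl)
          }
        }
      }
      bag <- instance_bag(cohort$patient_id[i], do.call(rbind, rows), cl,
                          survival = list(time_days = cohort$time_days[i],
                                          event = cohort$event[i]))
      attr(bag, "feature_blocks") <- blocks
      bag
    })
  })
}

#' Restrict multiresolution bags to one feature block
#'
#' @param bags list from [simulate_multires_bags()].
#' @param level one of "256", "512", "1024", or "multires" (no-op).
#' @return Bags whose instance matrices keep only the selected block.
#' @export
bags_select_level <- function(bags, level = c("multires", "256", "512", "1024")) {
  level <- match.arg(level)
  if (level == "multires") return(bags)
  lapply(bags, function(b) {
    blocks <- attr(b, "feature_blocks")
    if (is.null(blocks)) stop("bags carry no feature_blocks attribute")
    b$instances <- b$instances[, blocks[[level]], drop = FALSE]
    b
  })
}
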