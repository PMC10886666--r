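# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: per-patient latent risk expressed as a shift in
# epithelium texture, exponential relapse times tied to that risk,
# administrative censoring at five years, and blob-like tissue layouts
# whose stroma/epithelium composition varies across the slide. Nothing
# here claims histologic realism; see the methods vignette for what the
# generator does and does not emulate.

.wsimil_cache <- new.env(parent = emptyenv())

#' Cohort generator specification
#'
#' Bundles all generator parameters. Defaults are calibrated so that, at
#' the five-year administrative horizon with uniform loss to follow-up,
#' the expected event fraction is close to 0.30 (the class balance that
#' motivates minority oversampling) and the concordance index of the true
#' latent risk against the generated survival is close to 0.75.
#'
#' @param n_patients number of patients (>= 2).
#' @param image_size_px square image side in pixels, a multiple of 1024.
#' @param latent_risk_sd standard deviation of the latent risk score.
#' @param hazard_coefficient log-hazard increase per unit latent risk.
#' @param baseline_hazard baseline event rate, events/day.
#' @param censor_horizon_days administrative censoring horizon.
#' @param texture_shift_scale epithelium appearance shift per unit risk
#'   (channel intensity units).
#' @param artifact_fraction fraction of tissue pixels labelled artifact.
#' @param rng_seed root seed; all per-patient streams derive from it.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        image_size_px = 1024,
                        latent_risk_sd = 1,
                        hazard_coefficient = 1.1,
                        baseline_hazard = 1.7e-4,
                        censor_horizon_days = 1826,
                        texture_shift_scale = 0.12,
                        artifact_fraction = 0.05,
                        rng_seed = 1) {
  spec <- list(n_patients = as.integer(n_patients),
               image_size_px = as.integer(image_size_px),
               latent_risk_sd = latent_risk_sd,
               hazard_coefficient = hazard_coefficient,
               baseline_hazard = baseline_hazard,
               censor_horizon_days = as.integer(censor_horizon_days),
               texture_shift_scale = texture_shift_scale,
               artifact_fraction = artifact_fraction,
               rng_seed = as.integer(rng_seed))
  if (spec$n_patients < 2) stop("configuration error: n_patients must be >= 2")
  if (spec$image_size_px < 1024 || spec$image_size_px %% 1024 != 0) {
    stop("configuration error: image_size_px must be a positive multiple of 1024")
  }
  if (spec$latent_risk_sd <= 0 || spec$baseline_hazard <= 0) {
    stop("configuration error: latent_risk_sd and baseline_hazard must be positive")
  }
  if (spec$censor_horizon_days <= 0) stop("configuration error: censor_horizon_days must be > 0")
  if (spec$artifact_fraction < 0 || spec$artifact_fraction > 1) {
    stop("configuration error: artifact_fraction must lie in [0, 1]")
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic patient cohort with survival data
#'
#' Latent risk is Normal(0, `latent_risk_sd`); time to relapse is
#' exponential with hazard `baseline_hazard * exp(hazard_coefficient *
#' latent_risk)`; observed time is the minimum of the event time, a
#' uniform loss-to-follow-up time, and the administrative horizon.
#' Clinicopathological covariates (stage, grade, reTUR finding) are
#' binary draws mildly associated with the latent risk so that the Cox
#' evaluation harness has realistic confounders to work with.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with one row per patient: `patient_id`,
#'   `latent_risk`, `time_days`, `event`, `stage_pT1`, `grade_G3`,
#'   `retur_positive`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed(derive_seed(spec$rng_seed, "cohort"), {
    n <- spec$n_patients
    risk <- stats::rnorm(n, 0, spec$latent_risk_sd)
    hazard <- spec$baseline_hazard * exp(spec$hazard_coefficient * risk)
    t_event <- stats::rexp(n, rate = hazard)
    # a minority of patients are lost to follow-up at a uniform time; the
    # rest are followed to the administrative horizon
    dropped <- stats::runif(n) < 0.3
    t_dropout <- ifelse(dropped,
                        stats::runif(n, 0.1, 1) * spec$censor_horizon_days,
                        spec$censor_horizon_days)
    t_cens <- pmin(t_dropout, spec$censor_horizon_days)
    event <- as.integer(t_event <= t_cens)
    time_days <- pmax(1L, as.integer(ceiling(pmin(t_event, t_cens))))
    # administrative censoring invariant: a full-horizon observation is censored
    event[time_days >= spec$censor_horizon_days & t_event > t_cens] <- 0L
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      latent_risk = risk,
      time_days = time_days,
      event = event,
      stage_pT1 = stats::rbinom(n, 1, stats::plogis(-0.6 + 0.4 * risk)),
      grade_G3 = stats::rbinom(n, 1, stats::plogis(0.1 + 0.4 * risk)),
      retur_positive = stats::rbinom(n, 1, stats::plogis(-0.1 + 0.5 * risk)),
      stringsAsFactors = FALSE
    )
  })
}

#' Write the cohort survival table to CSV
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

# Bilinear upsampling of a square grid by two interpolation-matrix
# multiplications (half-pixel aligned). Much faster than generic image
# resampling for the coarse-to-fine field construction below.
upsample_bilinear <- function(m0, size) {
  n0 <- nrow(m0)
  if (n0 == size) return(m0)
  key <- sprintf("upW_%d_%d", n0, size)
  W <- .wsimil_cache[[key]]
  if (is.null(W)) {
    x <- (seq_len(size) - 0.5) * n0 / size + 0.5
    x <- pmin(pmax(x, 1), n0)
    lo <- floor(x)
    w <- x - lo
    hi <- pmin(lo + 1, n0)
    W <- matrix(0, size, n0)
    W[cbind(seq_len(size), lo)] <- 1 - w
    W[cbind(seq_len(size), hi)] <- W[cbind(seq_len(size), hi)] + w
    .wsimil_cache[[key]] <- W
  }
  W %*% m0 %*% t(W)
}

# Smooth random field: coarse iid normal grid bilinearly upsampled to
# size x size. `scale` is the approximate blob size in pixels.
smooth_field <- function(size, scale) {
  n0 <- max(4L, as.integer(round(size / scale)))
  m0 <- matrix(stats::rnorm(n0 * n0), n0, n0)
  upsample_bilinear(m0, size)
}

# Spatial scales (pixels) of the stationary texture bands carrying the
# slide-identity fingerprint.
.fingerprint_scales <- c(8, 16, 32, 64)

#' Generate one synthetic tissue image and its label mask
#'
#' The layout is blob-like: a smooth random field is thresholded into
#' background vs. tissue, a second field splits tissue into stroma and
#' epithelium, and a fine-scale field carves out artifact regions. The
#' epithelium channel intensities are shifted by
#' `texture_shift_scale * latent_risk` along a fixed colour direction, and
#' the fine/coarse texture mix shifts with risk, giving downstream feature
#' learning a monotone appearance signal. Each slide additionally carries
#' a stationary identity fingerprint: a per-slide mean-colour offset plus
#' per-scale, per-channel amplitudes of noise bands at fixed spatial
#' scales, constant across the slide, distinct across slides -- so every
#' patch of a slide shares the same local texture statistics.
#'
#' @param spec a [cohort_spec()].
#' @param patient one row of the data.frame from [generate_cohort()] (or a
#'   list with `patient_id` and `latent_risk`).
#' @return List with `image` (size x size x 3 array in \[0,1\]) and `mask`
#'   (size x size integer matrix; 0 background, 1 stroma, 2 epithelium,
#'   3 artifact).
#' @export
generate_tissue_image <- function(spec, patient) {
  stopifnot(inherits(spec, "cohort_spec"))
  size <- spec$image_size_px
  # deterministic strided subsample for cheap quantiles on large fields
  qstride <- function(x, p) stats::quantile(x[seq(1L, length(x), by = 7L)], p, names = FALSE)
  local_seed(derive_seed(spec$rng_seed, paste0("image/", patient$patient_id)), {
    f_tissue <- smooth_field(size, size / 8)
    f_comp <- smooth_field(size, size / 8)
    tissue <- f_tissue > qstride(f_tissue, 0.25)
    epi <- tissue & (f_comp > qstride(f_comp[tissue], 0.45))
    mask <- matrix(0L, size, size)
    mask[tissue] <- 1L
    mask[epi] <- 2L
    if (spec$artifact_fraction > 0) {
      f_art <- smooth_field(size, size / 32)
      thr <- qstride(f_art[tissue], 1 - spec$artifact_fraction)
      mask[tissue & (f_art > thr)] <- 3L
    }

    # base colours by label lookup; 0 background, 1 stroma, 2 epithelium, 3 artifact
    col_lut <- rbind(c(0.94, 0.94, 0.94),
                     c(0.86, 0.62, 0.72),
                     c(0.48, 0.34, 0.60),
                     c(0.30, 0.22, 0.20))

    # stationary slide-identity fingerprint: mean-colour offset, one noise
    # band per spatial scale mixed into the channels with per-slide
    # amplitudes (identity in the band covariances), and a per-channel
    # random tone curve (identity in the pointwise colour distribution);
    # together these span a few dozen identity dimensions
    mean_shift <- stats::rnorm(3, 0, 0.05)
    band_amp <- matrix(stats::rnorm(3L * length(.fingerprint_scales), 0, 0.06),
                       length(.fingerprint_scales), 3)
    bands <- lapply(.fingerprint_scales, function(s) smooth_field(size, s))
    # smooth random tone curves evaluated on a 256-level lookup table
    tone_coef <- matrix(stats::rnorm(3L * 8L, 0, 0.03), 8, 3)
    lut_x <- (0:255) / 255
    tone_lut <- sapply(1:3, function(ch) {
      y <- numeric(256)
      for (k in 1:8) y <- y + tone_coef[k, ch] * sin(pi * k * lut_x)
      y
    })

    # risk-dependent epithelium appearance: mean colour shift plus a shift
    # in the fine-vs-coarse texture mix
    shift_dir <- c(-0.55, -0.25, 0.79)
    fine <- smooth_field(size, 8)
    coarse <- smooth_field(size, size / 16)
    mix <- spec$texture_shift_scale * patient$latent_risk
    epi_ind <- (mask == 2L) * 1
    tex <- 0.1 * mix * (fine - coarse) * epi_ind
    img <- array(0, dim = c(size, size, 3))
    for (ch in 1:3) {
      sig <- matrix(mean_shift[ch], size, size)
      for (s in seq_along(bands)) sig <- sig + band_amp[s, ch] * bands[[s]]
      plane <- matrix(col_lut[mask + 1L, ch], size, size) + sig +
        mix * shift_dir[ch] * epi_ind + tex
      # per-slide tone curve applied pointwise through the lookup table
      idx <- pmin(pmax(as.integer(plane * 255), 0L), 255L) + 1L
      img[, , ch] <- plane + tone_lut[idx, ch]
    }
    img <- img + stats::rnorm(length(img), 0, 0.03)
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, mask = mask)
  })
}

#' Write an image and mask pair to disk
#'
#' Images are written as 8-bit RGB PNG or TIFF; masks as single-channel
#' PNG with the integer label stored in the low byte (value/255).
#'
#' @param x list with `image` and `mask` from [generate_tissue_image()].
#' @param image_path output image path (.png or .tif/.tiff).
#' @param mask_path output mask PNG path.
#' @return Invisibly, the two paths.
#' @export
write_tissue_image <- function(x, image_path, mask_path) {
  img <- aperm(x$image, c(1, 2, 3))
  if (grepl("\\.tiff?$", image_path, ignore.case = TRUE)) {
    tiff::writeTIFF(img, image_path, bits.per.sample = 8L)
  } else {
    png::writePNG(img, image_path)
  }
  png::writePNG(x$mask / 255, mask_path)
  invisible(c(image_path, mask_path))
}

#' Read a mask PNG written by [write_tissue_image()]
#' @param path mask PNG path.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
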