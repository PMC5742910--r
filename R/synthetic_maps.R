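#' Configuration for synthetic component-map generation
#'
#' Describes one synthetic activation overlay: an elliptical "brain" of
#' achromatic tissue pixels on a black background, blue activation blobs in
#' the lower ("occipital") third, and red artifact speckle elsewhere in the
#' brain. `intensity_heterogeneity` is the standard deviation (in gray
#' levels) of the tissue intensity distribution around `base_intensity`; it
#' is the dial that drives the retained-pixel entropy up, and is what the
#' calibration routines adjust to hit a target BEN.
#'
#' Tissue gray levels are kept a guard band away from the class decision
#' boundaries (background/grey near 64, grey/white near 191.5), so that the
#' intended class of every pixel survives both rounding and sub-margin RGB
#' noise: segmentation recovers the generator's ground truth exactly.
#'
#' @param image_size integer c(width, height) in pixels.
#' @param n_activation_blobs number of Gaussian activation blobs.
#' @param blob_scale blob kernel scale in pixels.
#' @param activation_fraction proportion of in-brain pixels coloured blue.
#' @param artifact_fraction proportion of in-brain pixels coloured red.
#' @param intensity_heterogeneity dispersion (gray levels) of tissue
#'   intensities; 0 makes every tissue pixel identical.
#' @param noise_amplitude per-channel uniform RGB noise half-width; must stay
#'   below the segmentation decision margin (capped at 20, well under 40% of
#'   the minimum inter-reference distance).
#' @param base_intensity centre of the tissue intensity distribution.
#' @param seed RNG seed; identical config + seed gives bit-identical images.
#' @return an object of class `map_gen_config`.
#' @export
map_gen_config <- function(image_size = c(64L, 64L),
                           n_activation_blobs = 3L,
                           blob_scale = 4,
                           activation_fraction = 0.08,
                           artifact_fraction = 0.02,
                           intensity_heterogeneity = 8,
                           noise_amplitude = 2,
                           base_intensity = 128,
                           seed = 1L) {
  if (length(image_size) != 2L || any(!is.finite(image_size)) ||
      any(image_size < 1)) {
    stop("configuration error: image_size must be two positive integers")
  }
  fr <- c(activation_fraction, artifact_fraction)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("configuration error: fractions must lie in [0, 1] and sum to <= 1")
  }
  if (!is.finite(intensity_heterogeneity) || intensity_heterogeneity < 0) {
    stop("configuration error: intensity_heterogeneity must be >= 0")
  }
  if (!is.finite(noise_amplitude) || noise_amplitude < 0 ||
      noise_amplitude > 20) {
    stop("configuration error: noise_amplitude must lie in [0, 20]")
  }
  if (base_intensity < 70 || base_intensity > 185) {
    stop("configuration error: base_intensity must lie in [70, 185] ",
         "(inside the grey decision region)")
  }
  structure(list(image_size = as.integer(image_size),
                 n_activation_blobs = as.integer(n_activation_blobs),
                 blob_scale = blob_scale,
                 activation_fraction = activation_fraction,
                 artifact_fraction = artifact_fraction,
                 intensity_heterogeneity = intensity_heterogeneity,
                 noise_amplitude = noise_amplitude,
                 base_intensity = base_intensity,
                 seed = as.integer(seed)),
            class = "map_gen_config")
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, i, j = 0L) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + i * 131 + j * 7) %%
               2147483647)
}

# Keep tissue gray levels a guard band away from the class decision
# boundaries so that rounding + sub-margin noise can never flip the class.
guard_gray_levels <- function(g, noise_amplitude) {
  a <- noise_amplitude + 1.5            # rounding adds up to 0.5 per channel
  lo <- ceiling(64 + a + 1)
  g <- pmin(pmax(g, lo), 255)
  band_lo <- floor(191.5 - a - 1)
  band_hi <- ceiling(191.5 + a + 1)
  in_band <- g > band_lo & g < band_hi
  g[in_band] <- ifelse(g[in_band] <= 191.5, band_lo, band_hi)
  g
}

#' Generate one synthetic component map
#'
#' Produces an H x W x 3 activation overlay whose every pixel belongs to
#' exactly one colour class, with the generator's intended per-pixel classes
#' recorded in the `true_labels` attribute (integer codes in canonical class
#' order). Activation is placed in the lower third of the image; entropy is
#' location-invariant, so the placement is purely cosmetic.
#'
#' @param config a [map_gen_config()].
#' @param subject_id,component_index metadata for the returned image.
#' @return a [component_image()] with attributes `true_labels` (H x W integer
#'   matrix) and `gen_config`.
#' @examples
#' img <- generate_component_map(map_gen_config(seed = 42))
#' table(attr(img, "true_labels"))
#' @export
generate_component_map <- function(config = map_gen_config(),
                                   subject_id = "synthetic",
                                   component_index = 1L) {
  stopifnot(inherits(config, "map_gen_config"))
  w <- config$image_size[1]; h <- config$image_size[2]
  with_seed(config$seed, {
    row <- matrix(seq_len(h), nrow = h, ncol = w)
    col <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    brain <- ((row - cy) / (0.45 * h))^2 + ((col - cx) / (0.45 * w))^2 <= 1
    brain_idx <- which(brain)
    n_brain <- length(brain_idx)
    lower <- brain & row > 2 * h / 3
    lower_idx <- which(lower)

    # activation: top-scoring lower-third pixels under a sum of Gaussian blobs
    k_blue <- min(round(config$activation_fraction * n_brain),
                  length(lower_idx))
    blue_idx <- integer(0)
    if (k_blue > 0 && length(lower_idx) > 0) {
      nb <- max(1L, config$n_activation_blobs)
      centers <- lower_idx[sample.int(length(lower_idx), nb,
                                      replace = length(lower_idx) < nb)]
      score <- numeric(length(lower_idx))
      r <- row[lower_idx]; c <- col[lower_idx]
      for (ct in centers) {
        score <- score + exp(-((r - row[ct])^2 + (c - col[ct])^2) /
                               (2 * config$blob_scale^2))
      }
      score <- score + runif(length(score)) * 1e-9   # deterministic tie-break
      blue_idx <- lower_idx[order(score, decreasing = TRUE)[seq_len(k_blue)]]
    }

    # artifacts: red speckle in the brain but outside the occipital third
    m_red <- round(config$artifact_fraction * n_brain)
    red_pool <- setdiff(which(brain & row <= 2 * h / 3), blue_idx)
    if (m_red > length(red_pool)) {
      red_pool <- setdiff(brain_idx, blue_idx)
    }
    red_idx <- if (m_red > 0) {
      red_pool[sample.int(length(red_pool), min(m_red, length(red_pool)))]
    } else integer(0)

    tissue_idx <- setdiff(brain_idx, c(blue_idx, red_idx))

    R <- matrix(0, h, w); G <- matrix(0, h, w); B <- matrix(0, h, w)
    labels <- matrix(1L, h, w)                        # background

    g <- round(config$base_intensity +
                 config$intensity_heterogeneity * rnorm(length(tissue_idx)))
    g <- guard_gray_levels(g, config$noise_amplitude)
    R[tissue_idx] <- g; G[tissue_idx] <- g; B[tissue_idx] <- g
    labels[tissue_idx] <- ifelse(g >= 192, 2L, 3L)    # white / grey

    if (length(blue_idx) > 0) {
      b <- pmin(40, round(abs(rnorm(length(blue_idx))) *
                            config$intensity_heterogeneity))
      R[blue_idx] <- b; G[blue_idx] <- b; B[blue_idx] <- 255
      labels[blue_idx] <- 4L
    }
    if (length(red_idx) > 0) {
      rc <- pmin(40, round(abs(rnorm(length(red_idx))) *
                             config$intensity_heterogeneity))
      R[red_idx] <- 255; G[red_idx] <- rc; B[red_idx] <- rc
      labels[red_idx] <- 5L
    }

    px <- array(c(R, G, B), dim = c(h, w, 3L))
    if (config$noise_amplitude > 0) {
      px <- px + array(runif(length(px), -config$noise_amplitude,
                             config$noise_amplitude), dim = dim(px))
      px <- pmin(pmax(round(px), 0), 255)
    }
    img <- component_image(px, subject_id = subject_id,
                           component_index = component_index)
    attr(img, "true_labels") <- labels
    attr(img, "gen_config") <- config
    img
  })
}

# Mean BEN over n_maps seeded maps at a given heterogeneity.
mean_ben_at <- function(h, config, n_maps, profiles = default_color_profiles()) {
  cfg <- config
  cfg$intensity_heterogeneity <- h
  bens <- vapply(seq_len(n_maps), function(i) {
    cfg$seed <- derive_seed(config$seed, i, round(h * 100))
    image_ben(generate_component_map(cfg), profiles)$ben
  }, numeric(1))
  mean(bens)
}

#' Calibrate the heterogeneity parameter to a target BEN
#'
#' Finds, by monotone bisection, the intensity-heterogeneity value at which
#' the mean BEN of generated maps matches `target_ben` within `tol`. Mean BEN
#' is monotone non-decreasing in the dispersion parameter over the searched
#' range (verified empirically when `verify_monotone = TRUE`, and by the
#' package's property tests).
#'
#' @param target_ben desired normalised entropy in `(0, 1)` (0 is accepted as
#'   the degenerate request and returns dispersion 0).
#' @param config a [map_gen_config()]; all fields except
#'   `intensity_heterogeneity` define the map population.
#' @param tol calibration tolerance on mean BEN (default 0.02).
#' @param n_maps number of seeded maps averaged per evaluation.
#' @param h_max upper end of the searched dispersion range.
#' @param verify_monotone also check monotonicity on a coarse grid.
#' @return the calibrated dispersion value.
#' @export
calibrate_heterogeneity <- function(target_ben, config = map_gen_config(),
                                    tol = 0.02, n_maps = 50, h_max = 60,
                                    verify_monotone = FALSE) {
  stopifnot(inherits(config, "map_gen_config"))
  if (!is.finite(target_ben) || target_ben < 0 || target_ben >= 1) {
    stop("target_ben must lie in [0, 1)")
  }
  if (target_ben == 0) return(0)
  b_lo <- mean_ben_at(0, config, n_maps)
  b_hi <- mean_ben_at(h_max, config, n_maps)
  if (target_ben < b_lo - tol / 2 || target_ben > b_hi + tol / 2) {
    stop(sprintf(
      "calibration error: target BEN %.3f outside achievable range [%.3f, %.3f]",
      target_ben, b_lo, b_hi))
  }
  if (verify_monotone) {
    grid <- seq(0, h_max, length.out = 7)
    vals <- vapply(grid, mean_ben_at, numeric(1), config = config,
                   n_maps = n_maps)
    if (any(diff(vals) < -0.015)) {
      stop("calibration error: mean BEN is not monotone in the dispersion ",
           "parameter over [0, ", h_max, "]")
    }
  }
  lo <- 0; hi <- h_max
  for (it in seq_len(40)) {
    mid <- (lo + hi) / 2
    b <- mean_ben_at(mid, config, n_maps)
    if (abs(b - target_ben) <= tol / 2 || (hi - lo) < 1e-3) return(mid)
    if (b < target_ben) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Precompute a BEN-vs-dispersion calibration curve
#'
#' Evaluates mean BEN on a grid of dispersion values and returns a monotone
#' curve that [heterogeneity_for_ben()] inverts by linear interpolation. Much
#' cheaper than calling [calibrate_heterogeneity()] per subject when
#' generating cohorts.
#'
#' @inheritParams calibrate_heterogeneity
#' @param h_grid dispersion grid.
#' @return data frame of class `ben_calibration` with columns `h`, `ben`.
#' @export
calibration_curve <- function(config = map_gen_config(),
                              h_grid = c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6.5, 8,
                                         10, 13, 17, 22, 30, 40, 55),
                              n_maps = 8) {
  stopifnot(inherits(config, "map_gen_config"))
  ben <- vapply(h_grid, mean_ben_at, numeric(1), config = config,
                n_maps = n_maps)
  ben <- cummax(ben)              # enforce monotonicity for stable inversion
  structure(data.frame(h = h_grid, ben = ben),
            class = c("ben_calibration", "data.frame"))
}

#' Invert a calibration curve
#'
#' @param target_ben desired normalised entropy; values outside the curve's
#'   achievable range are clamped to its ends.
#' @param curve a [calibration_curve()].
#' @return interpolated dispersion value.
#' @export
heterogeneity_for_ben <- function(target_ben, curve) {
  stopifnot(inherits(curve, "ben_calibration"))
  target <- pmin(pmax(target_ben, min(curve$ben)), max(curve$ben))
  stats::approx(curve$ben, curve$h, xout = target, ties = min)$y
}
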