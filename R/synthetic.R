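# run expr under a temporary RNG seed, restoring caller RNG state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Leaf-color mixture with a target dark fraction
#'
#' Builds a categorical color mixture over representative palette codes such
#' that `dark_fraction` of leaf pixels are dark green; the remainder is split
#' 80/20 between medium and light green. Used by [gen_canopy_image()] to
#' render canopies of controlled dark green proportion.
#'
#' @param dark_fraction target fraction of dark green pixels, in `[0, 1]`.
#' @return data.frame with columns `r`, `g`, `b`, `weight` (weights sum to 1).
#' @export
green_mixture <- function(dark_fraction = 0.3) {
  stopifnot(dark_fraction >= 0, dark_fraction <= 1)
  data.frame(
    r = c(0L, 0L, 102L, 102L, 153L),
    g = c(43L, 85L, 128L, 170L, 213L),
    b = c(0L, 0L, 51L, 51L, 102L),
    weight = c(dark_fraction / 2, dark_fraction / 2,
               (1 - dark_fraction) * 0.4, (1 - dark_fraction) * 0.4,
               (1 - dark_fraction) * 0.2)
  )
}

#' Specification of a synthetic canopy image
#'
#' Describes a top-down canopy scene: elliptical leaf blobs colored by a
#' categorical mixture of palette codes, over a noisy near-black background
#' (the black-sheet acquisition protocol). Geometry is deliberately minimal
#' -- only the color distribution matters to the indices under test.
#'
#' @param width,height image size in pixels.
#' @param background background mean color `c(r, g, b)`.
#' @param background_noise_sd per-channel Gaussian noise sd of the
#'   background, channel units.
#' @param n_blobs number of leaf ellipses.
#' @param blob_radius range `c(min, max)` of ellipse semi-axes, pixels.
#' @param mixture leaf-color mixture (`r`, `g`, `b`, `weight`); see
#'   [green_mixture()].
#' @param seed RNG seed for reproducibility.
#' @return a list of class `canopy_image_spec`.
#' @export
canopy_image_spec <- function(width = 160L, height = 160L,
                              background = c(2L, 2L, 2L),
                              background_noise_sd = 1.5,
                              n_blobs = 6L,
                              blob_radius = c(14, 32),
                              mixture = green_mixture(0.3),
                              seed = 1L) {
  stopifnot(width > 0, height > 0, n_blobs >= 1,
            length(blob_radius) == 2L, blob_radius[1] <= blob_radius[2],
            background_noise_sd >= 0,
            all(c("r", "g", "b", "weight") %in% names(mixture)))
  if (abs(sum(mixture$weight) - 1) > 1e-8)
    stop("mixture weights must sum to 1", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background,
                 background_noise_sd = background_noise_sd,
                 n_blobs = as.integer(n_blobs), blob_radius = blob_radius,
                 mixture = mixture, seed = seed),
            class = "canopy_image_spec")
}

#' Generate a synthetic canopy image with ground truth
#'
#' Renders the scene described by a [canopy_image_spec()]: leaf pixels take
#' exact palette codes drawn from the mixture (as after GIF quantization);
#' background pixels get Gaussian channel noise. Returns the exact leaf mask
#' and the color metrics computed from the emitted leaf pixels, so
#' segmentation and index computation can be tested against known truth.
#' Seed-deterministic: the same spec yields a bit-identical scene.
#'
#' @param spec a [canopy_image_spec()].
#' @param mode,denominator passed to [compute_metrics()] for the truth
#'   metrics.
#' @return list with `grid` ([pixel_grid()]), `mask` (ground-truth
#'   [segmentation_mask()]), `metrics` (ground-truth `color_metrics`), and
#'   `spec`.
#' @export
gen_canopy_image <- function(spec = canopy_image_spec(), mode = "threshold",
                             denominator = "green") {
  stopifnot(inherits(spec, "canopy_image_spec"))
  if (2 * spec$blob_radius[1] > min(spec$width, spec$height))
    stop("leaf blobs cannot fit: blob_radius too large for the image",
         call. = FALSE)
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    # noisy background
    grid <- array(0L, c(h, w, 3L))
    for (k in 1:3)
      grid[, , k] <- as.integer(clamp(round(
        spec$background[k] + stats::rnorm(h * w, 0, spec$background_noise_sd)),
        0, 255))

    # union of axis-aligned elliptical leaf blobs
    mask <- matrix(FALSE, h, w)
    row_i <- row(mask); col_i <- col(mask)
    for (b in seq_len(spec$n_blobs)) {
      a1 <- stats::runif(1, spec$blob_radius[1], spec$blob_radius[2])
      a2 <- stats::runif(1, spec$blob_radius[1], spec$blob_radius[2])
      cx <- stats::runif(1, a2, w - a2)
      cy <- stats::runif(1, a1, h - a1)
      mask <- mask | (((row_i - cy) / a1)^2 + ((col_i - cx) / a2)^2 <= 1)
    }

    # leaf pixels: exact palette codes drawn from the mixture
    n_leaf <- sum(mask)
    pick <- sample.int(nrow(spec$mixture), n_leaf, replace = TRUE,
                       prob = spec$mixture$weight)
    for (k in 1:3) {
      ch <- grid[, , k]
      ch[mask] <- spec$mixture[[c("r", "g", "b")[k]]][pick]
      grid[, , k] <- ch
    }
    grid <- pixel_grid(grid)
    mask <- segmentation_mask(mask)
    list(grid = grid, mask = mask,
         metrics = compute_metrics(build_histogram(grid, mask), mode = mode,
                                   denominator = denominator),
         spec = spec)
  })
}

#' Forward model of one camera device
#'
#' Two effects observed between smartphone brands are emulated: an additive
#' shift of the normalized intensity, and a saturation (chroma) gain that
#' scales each channel's deviation from the pixel mean. Gain 1 and bias 0 is
#' a faithful device.
#'
#' @param intensity_bias additive shift on the unit intensity scale.
#' @param saturation_gain multiplicative chroma factor (> 1 = more
#'   saturated).
#' @param noise_sd sd of per-measurement noise on the unit scale
#'   (metric-level use).
#' @return a list of class `device_model`.
#' @export
device_model <- function(intensity_bias = 0, saturation_gain = 1,
                         noise_sd = 0) {
  stopifnot(noise_sd >= 0, saturation_gain > 0)
  structure(list(intensity_bias = intensity_bias,
                 saturation_gain = saturation_gain, noise_sd = noise_sd),
            class = "device_model")
}

#' Render an image as a given device would record it
#'
#' Applies the device's saturation gain about each pixel's mean and its
#' intensity bias (scaled to channel units), clamping to 0-255.
#'
#' @param grid a [pixel_grid()].
#' @param device a [device_model()].
#' @return a [pixel_grid()].
#' @export
apply_device <- function(grid, device) {
  stopifnot(inherits(device, "device_model"))
  grid <- as_pixel_grid(grid)
  a <- unclass(grid)
  mu <- (a[, , 1] + a[, , 2] + a[, , 3]) / 3
  out <- array(0L, dim(a))
  for (k in 1:3)
    out[, , k] <- as.integer(clamp(round(
      mu + device$saturation_gain * (a[, , k] - mu) +
        255 * device$intensity_bias), 0, 255))
  pixel_grid(out)
}

#' Simulate paired measurements of the same targets by two devices
#'
#' Metric-level forward model: each device observes the true parameter value
#' plus its additive bias plus independent Gaussian noise. The expected
#' difference y - x equals the bias difference of the two devices.
#'
#' @param truth true parameter value(s); scalar or length-`n` vector.
#' @param device_a,device_b [device_model()]s (x and y respectively).
#' @param n number of paired targets (>= 2).
#' @param seed RNG seed.
#' @return a [paired_sample()].
#' @export
gen_paired_device <- function(truth, device_a, device_b, n, seed = NULL) {
  stopifnot(inherits(device_a, "device_model"),
            inherits(device_b, "device_model"), n >= 2)
  truth <- rep_len(truth, n)
  with_seed(seed, {
    x <- truth + device_a$intensity_bias +
      stats::rnorm(n, 0, device_a$noise_sd)
    y <- truth + device_b$intensity_bias +
      stats::rnorm(n, 0, device_b$noise_sd)
    paired_sample(x, y)
  })
}

#' Ground-truth configuration of a synthetic fertilizer experiment
#'
#' Encodes the generative pattern the analysis is tested against: the
#' nitrogen treatment darkens the canopy (high dark green proportion, low
#' intensity) and increases fresh weight; the untreated control is palest
#' and lightest. Fresh weight follows `a_t + beta * dark_proportion +
#' N(0, sigma)`; intensity is negatively tied to the dark proportion.
#'
#' @param n_per_treatment plants per treatment group (>= 2).
#' @param dark_mean named per-treatment mean dark green proportion.
#' @param dark_sd between-plant sd of the dark green proportion.
#' @param intensity_base,intensity_slope,intensity_sd linear intensity model
#'   `base + slope * dark + N(0, sd)` (slope < 0 gives the observed negative
#'   association).
#' @param intercepts named per-treatment weight intercepts a_t, grams.
#' @param beta weight-color slope, grams per unit dark proportion.
#' @param sigma residual weight sd, grams.
#' @param leaf_mean,leaf_sd leaf-count distribution (treatment-independent:
#'   leaf number responds little to fertilizer).
#' @param seed RNG seed.
#' @return a list of class `experiment_config`.
#' @export
synthetic_experiment_config <- function(
    n_per_treatment = 8L,
    dark_mean = c(C = 0.20, N = 0.60, LV = 0.45, I = 0.30),
    dark_sd = 0.08,
    intensity_base = 0.42, intensity_slope = -0.45, intensity_sd = 0.02,
    intercepts = c(C = 20, N = 20, LV = 20, I = 20),
    beta = 200, sigma = 5,
    leaf_mean = 25, leaf_sd = 4,
    seed = 1L) {
  stopifnot(n_per_treatment >= 2, sigma >= 0, dark_sd >= 0,
            setequal(names(dark_mean), TREATMENTS),
            setequal(names(intercepts), TREATMENTS))
  structure(list(n_per_treatment = as.integer(n_per_treatment),
                 dark_mean = dark_mean[TREATMENTS], dark_sd = dark_sd,
                 intensity_base = intensity_base,
                 intensity_slope = intensity_slope,
                 intensity_sd = intensity_sd,
                 intercepts = intercepts[TREATMENTS], beta = beta,
                 sigma = sigma, leaf_mean = leaf_mean, leaf_sd = leaf_sd,
                 seed = seed),
            class = "experiment_config")
}

#' Generate growth records for a synthetic experiment
#'
#' @param config a [synthetic_experiment_config()].
#' @param experiment_id label stored in the records.
#' @return a [plant_records()] data.frame with one row per plant.
#' @export
gen_experiment <- function(config = synthetic_experiment_config(),
                           experiment_id = "synthetic-1") {
  stopifnot(inherits(config, "experiment_config"))
  n <- config$n_per_treatment
  with_seed(config$seed, {
    rows <- lapply(TREATMENTS, function(tr) {
      dark <- clamp(stats::rnorm(n, config$dark_mean[[tr]], config$dark_sd),
                    0.01, 0.99)
      intensity <- clamp(config$intensity_base +
                           config$intensity_slope * dark +
                           stats::rnorm(n, 0, config$intensity_sd),
                         0.01, 0.99)
      weight <- pmax(config$intercepts[[tr]] + config$beta * dark +
                       stats::rnorm(n, 0, config$sigma), 1)
      leaves <- pmax(round(stats::rnorm(n, config$leaf_mean, config$leaf_sd)),
                     0L)
      data.frame(plant_id = sprintf("%s-%s-%02d", experiment_id, tr,
                                    seq_len(n)),
                 experiment_id = experiment_id, treatment = tr,
                 fresh_weight = weight, leaf_count = as.integer(leaves),
                 intensity = intensity, dark_green_proportion = dark)
    })
    plant_records(do.call(rbind, rows))
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Materializes a synthetic experiment the way a field campaign would be
#' archived: one PNG canopy image per plant and device (device B images are
#' passed through its [device_model()] rendering), a metadata CSV, and a
#' truth manifest with the generative parameters realized per plant.
#'
#' @param dir output directory (created if missing).
#' @param config a [synthetic_experiment_config()].
#' @param image_size pixel size of the square canopy images.
#' @param device_b [device_model()] used to render the second device's
#'   images (device A renders faithfully).
#' @return invisibly, the [plant_records()] table written to
#'   `metadata.csv`.
#' @export
simulate_canopy_dataset <- function(dir, config = synthetic_experiment_config(),
                                    image_size = 96L,
                                    device_b = device_model(
                                      intensity_bias = 0.02,
                                      saturation_gain = 1.15)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- gen_experiment(config)
  for (i in seq_len(nrow(records))) {
    spec <- canopy_image_spec(
      width = image_size, height = image_size,
      n_blobs = 4L, blob_radius = c(round(image_size * 0.12),
                                    round(image_size * 0.22)),
      mixture = green_mixture(records$dark_green_proportion[i]),
      seed = config$seed * 10000L + i)
    scene <- gen_canopy_image(spec)
    write_image(scene$grid,
                file.path(dir, paste0(records$plant_id[i], "_a.png")))
    write_image(apply_device(scene$grid, device_b),
                file.path(dir, paste0(records$plant_id[i], "_b.png")))
  }
  utils::write.csv(records[, c("plant_id", "experiment_id", "treatment",
                               "fresh_weight", "leaf_count")],
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(records, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(records)
}
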