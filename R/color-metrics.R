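#' Reference green palette
#'
#' Twelve RGB codes commonly observed in palette-quantized lettuce canopy
#' images, four per band. The four dark codes define the code-set variant of
#' the dark green proportion; the band is determined by the G channel alone:
#' dark G 0-85, medium G 86-170, light G 171-255.
#'
#' @return data.frame with columns `r`, `g`, `b`, `band`.
#' @export
reference_green_palette <- function() {
  data.frame(
    r = c(0L, 0L, 51L, 51L, 102L, 102L, 102L, 102L, 102L, 153L, 153L, 204L),
    g = c(43L, 85L, 85L, 85L, 128L, 128L, 170L, 170L, 213L, 213L, 213L, 255L),
    b = c(0L, 0L, 0L, 51L, 0L, 51L, 0L, 51L, 102L, 51L, 102L, 102L),
    band = rep(c("dark", "medium", "light"), each = 4L)
  )
}

#' @rdname reference_green_palette
#' @return `dark_green_codes()`: the four dark codes as a 4 x 3 integer
#'   matrix.
#' @export
dark_green_codes <- function() {
  p <- reference_green_palette()
  as.matrix(p[p$band == "dark", c("r", "g", "b")])
}

# G-channel band boundaries (inclusive)
.band_breaks <- c(-1, 85, 170, 255)
.band_levels <- c("dark", "medium", "light")

#' Classify a green color into its G-channel band
#'
#' @param color integer vector `c(r, g, b)`; must satisfy the green rule
#'   (G strictly greater than R and B).
#' @return `"dark"` (G 0-85), `"medium"` (G 86-170) or `"light"` (G 171-255).
#' @export
classify_green_band <- function(color) {
  stopifnot(length(color) == 3L)
  r <- color[1]; g <- color[2]; b <- color[3]
  if (!(g > r && g > b))
    stop("color (", r, ",", g, ",", b, ") does not satisfy the green rule",
         call. = FALSE)
  .band_levels[findInterval(g, .band_breaks[-1] + 1L) + 1L]
}

stop_no_green <- function() {
  stop("no green pixels: histogram is empty after the green filter",
       call. = FALSE)
}

#' Normalized intensity of a green-filtered histogram
#'
#' The pixel-weighted mean of I = (R + G + B)/3 after scaling each channel
#' to the unit interval; 0 is black, 1 is white. Lower values indicate a
#' darker canopy.
#'
#' @param hist a green-filtered [color_histogram()] (see [filter_green()]).
#' @return a fraction in `[0, 1]`.
#' @export
normalized_intensity <- function(hist) {
  stopifnot(inherits(hist, "color_histogram"))
  if (!nrow(hist)) stop_no_green()
  # integer channel sum first: exact in doubles, so the result is
  # bit-identical to a per-pixel tally dividing in the same order
  sum((hist$r + hist$g + hist$b) * hist$count) / 765 / sum(hist$count)
}

#' Dark green proportion
#'
#' Fraction of analyzed green pixels classified dark green. Two variants:
#' `"threshold"` counts every green pixel with G <= 85 (the dark band);
#' `"codeset"` counts only pixels whose RGB code is exactly one of the four
#' [dark_green_codes()], which arise naturally after GIF palette reduction.
#' The code set is a subset of the dark band, so the codeset value never
#' exceeds the threshold value.
#'
#' @param hist a green-filtered [color_histogram()].
#' @param mode `"threshold"` (default) or `"codeset"`.
#' @return a fraction in `[0, 1]`.
#' @export
dark_green_proportion <- function(hist, mode = c("threshold", "codeset")) {
  stopifnot(inherits(hist, "color_histogram"))
  mode <- match.arg(mode)
  if (!nrow(hist)) stop_no_green()
  dark <- if (mode == "threshold") {
    hist$g <= 85L
  } else {
    codes <- dark_green_codes()
    pack_rgb(hist$r, hist$g, hist$b) %in%
      pack_rgb(codes[, "r"], codes[, "g"], codes[, "b"])
  }
  sum(hist$count[dark]) / sum(hist$count)
}

#' Compute both color indices for one plant image
#'
#' Applies the green filter, then computes the normalized intensity, the
#' dark green proportion, and the dark/medium/light band proportions.
#'
#' @param hist a [color_histogram()] (unfiltered; the green rule is applied
#'   here).
#' @param mode dark-green variant passed to [dark_green_proportion()].
#' @param denominator `"green"` (default) divides the dark-pixel count by the
#'   green-filtered pixel total; `"all"` divides by every pixel in `hist`
#'   (the whole segmented leaf area).
#' @return an object of class `color_metrics`: a list with `intensity`,
#'   `dark_green_proportion`, `band_proportions` (named dark/medium/light),
#'   `n_green_pixels`, `mode`, `denominator`.
#' @export
compute_metrics <- function(hist, mode = c("threshold", "codeset"),
                            denominator = c("green", "all")) {
  stopifnot(inherits(hist, "color_histogram"))
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  n_all <- total_pixels(hist)
  green <- filter_green(hist)
  if (!nrow(green)) stop_no_green()
  n_green <- total_pixels(green)

  band <- .band_levels[findInterval(green$g, .band_breaks[-1] + 1L) + 1L]
  bp <- vapply(.band_levels,
               function(lv) sum(green$count[band == lv]) / n_green,
               numeric(1))

  dgp <- dark_green_proportion(green, mode)
  if (denominator == "all") dgp <- dgp * n_green / n_all

  structure(list(intensity = normalized_intensity(green),
                 dark_green_proportion = dgp,
                 band_proportions = bp,
                 n_green_pixels = n_green,
                 mode = mode,
                 denominator = denominator),
            class = "color_metrics")
}

#' @export
print.color_metrics <- function(x, ...) {
  cat(sprintf(paste0("<color_metrics> intensity %.3f, dark green proportion",
                     " %.3f (%s)\n"),
              x$intensity, x$dark_green_proportion, x$mode))
  cat(sprintf("  bands dark/medium/light: %.3f / %.3f / %.3f  (n = %d green px)\n",
              x$band_proportions["dark"], x$band_proportions["medium"],
              x$band_proportions["light"], x$n_green_pixels))
  invisible(x)
}

#' Average the color indices from two devices
#'
#' Two cameras photographing the same plant disagree systematically; the
#' arithmetic mean of the two measurements is used downstream to make the
#' growth statistics robust to that disagreement.
#'
#' @param a,b `color_metrics` for the same plant from two devices; must share
#'   `mode` and `denominator`.
#' @return a `color_metrics` whose indices are component-wise means.
#' @export
average_metrics <- function(a, b) {
  stopifnot(inherits(a, "color_metrics"), inherits(b, "color_metrics"))
  if (!identical(a$mode, b$mode) || !identical(a$denominator, b$denominator))
    stop("cannot average metrics computed under different modes",
         call. = FALSE)
  structure(list(intensity = (a$intensity + b$intensity) / 2,
                 dark_green_proportion =
                   (a$dark_green_proportion + b$dark_green_proportion) / 2,
                 band_proportions = (a$band_proportions + b$band_proportions) / 2,
                 n_green_pixels = as.integer(round((a$n_green_pixels +
                                                      b$n_green_pixels) / 2)),
                 mode = a$mode,
                 denominator = a$denominator),
            class = "color_metrics")
}
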