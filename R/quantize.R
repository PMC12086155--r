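#' GIF-style palette quantization (median cut, no dithering)
#'
#' Reduces an image to at most `max_colors` distinct colors, emulating the
#' palette reduction a GIF conversion performs. Dithering is deliberately not
#' applied: it would scatter palette colors across the canopy and corrupt the
#' per-color pixel histogram that downstream indices are computed from. If the
#' input already has at most `max_colors` distinct colors the input is
#' returned bit-identically.
#'
#' Boxes are split along the channel of largest range at the pixel-weighted
#' median; each final box is represented by its pixel-weighted mean color
#' (rounded), so a box holding a single color maps to itself exactly.
#'
#' @param grid a [pixel_grid()].
#' @param max_colors palette budget, at least 2 (GIF default 256).
#' @return a [pixel_grid()] of identical dimensions.
#' @export
quantize_palette <- function(grid, max_colors = 256L) {
  grid <- as_pixel_grid(grid)
  max_colors <- as.integer(max_colors)
  if (is.na(max_colors) || max_colors < 2L)
    stop("max_colors must be >= 2", call. = FALSE)

  ch <- grid_channels(grid)
  key <- pack_rgb(ch$r, ch$g, ch$b)
  tab <- table_int(key)
  if (nrow(tab) <= max_colors) return(grid)

  cols <- unpack_rgb(tab$key)          # k x 3 matrix of unique colors
  w <- tab$count                       # pixel weight per unique color

  boxes <- list(seq_len(nrow(cols)))
  repeat {
    if (length(boxes) >= max_colors) break
    sizes <- vapply(boxes, function(i) {
      if (length(i) < 2L) return(0)    # single color: unsplittable
      sum(w[i])
    }, numeric(1))
    if (all(sizes == 0)) break
    bi <- which.max(sizes)
    idx <- boxes[[bi]]
    rng <- apply(cols[idx, , drop = FALSE], 2, function(v) diff(range(v)))
    chn <- which.max(rng)
    ord <- idx[order(cols[idx, chn])]
    cw <- cumsum(w[ord])
    cut <- which(cw >= cw[length(cw)] / 2)[1]
    if (cut >= length(ord)) cut <- length(ord) - 1L
    boxes[[bi]] <- ord[seq_len(cut)]
    boxes[[length(boxes) + 1L]] <- ord[(cut + 1L):length(ord)]
  }

  # representative = weighted mean color of each box; remap every pixel
  rep_of <- integer(nrow(cols))
  reps <- matrix(0L, length(boxes), 3L)
  for (i in seq_along(boxes)) {
    idx <- boxes[[i]]
    wi <- w[idx]
    reps[i, ] <- as.integer(round(colSums(cols[idx, , drop = FALSE] * wi) /
                                    sum(wi)))
    rep_of[idx] <- i
  }
  m <- match(key, tab$key)
  box_px <- rep_of[m]
  d <- dim(grid)
  out <- array(0L, d)
  out[, , 1] <- reps[box_px, 1]
  out[, , 2] <- reps[box_px, 2]
  out[, , 3] <- reps[box_px, 3]
  pixel_grid(out)
}

# fast count table over integer keys, returned sorted by key
table_int <- function(key) {
  s <- sort(key, method = "radix")
  runs <- rle(s)
  data.frame(key = runs$values, count = runs$lengths)
}

#' Separate vegetation from background
#'
#' Two simple rules cover the study designs this package targets:
#' `"black-background"` marks a pixel as vegetation when its luminance
#' (R+G+B)/3 exceeds `threshold` (photographs of plants laid on a black
#' sheet); `"excess-green"` marks it when the excess-green index 2G - R - B
#' exceeds `threshold` (plants in pots over soil). An externally supplied
#' mask ([read_mask()]) bypasses this step entirely.
#'
#' @param grid a [pixel_grid()].
#' @param mode `"black-background"` or `"excess-green"`.
#' @param threshold decision threshold on the 0-255 channel scale; defaults
#'   to 12 luminance units (black background) or 20 excess-green units.
#' @return a [segmentation_mask()] with the grid's dimensions.
#' @export
segment_vegetation <- function(grid,
                               mode = c("black-background", "excess-green"),
                               threshold = NULL) {
  grid <- as_pixel_grid(grid)
  mode <- match.arg(mode)
  ch <- grid_channels(grid)
  d <- dim(grid)
  score <- switch(mode,
    "black-background" = {
      if (is.null(threshold)) threshold <- 12
      (ch$r + ch$g + ch$b) / 3
    },
    "excess-green" = {
      if (is.null(threshold)) threshold <- 20
      2 * ch$g - ch$r - ch$b
    }
  )
  segmentation_mask(matrix(score > threshold, d[1], d[2]))
}
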