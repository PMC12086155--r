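# Independent per-pixel oracles and small fixture builders.

# Random RGB image as a pixel_grid
random_grid <- function(w, h, seed = NULL, palette = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(palette)) {
    pixel_grid(array(sample(0:255, w * h * 3, replace = TRUE), c(h, w, 3)))
  } else {
    pick <- sample(nrow(palette), w * h, replace = TRUE)
    arr <- array(0L, c(h, w, 3))
    arr[, , 1] <- palette$r[pick]
    arr[, , 2] <- palette$g[pick]
    arr[, , 3] <- palette$b[pick]
    pixel_grid(arr)
  }
}

# Brute-force color metrics: explicit loop over pixels, no histogram.
# Integer accumulation, dividing in the same order as the package so exact
# agreement can be asserted.
brute_force_metrics <- function(grid, mask = NULL) {
  a <- unclass(grid)
  d <- dim(a)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  n_green <- 0L
  sum_rgb <- 0
  n_dark <- 0L; n_medium <- 0L; n_light <- 0L; n_codeset <- 0L
  codes <- dark_green_codes()
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (!mask[i, j]) next
      r <- a[i, j, 1]; g <- a[i, j, 2]; b <- a[i, j, 3]
      if (!(g > r && g > b)) next
      n_green <- n_green + 1L
      sum_rgb <- sum_rgb + (r + g + b)
      if (g <= 85) n_dark <- n_dark + 1L
      else if (g <= 170) n_medium <- n_medium + 1L
      else n_light <- n_light + 1L
      for (k in seq_len(nrow(codes)))
        if (r == codes[k, 1] && g == codes[k, 2] && b == codes[k, 3]) {
          n_codeset <- n_codeset + 1L
          break
        }
    }
  }
  if (n_green == 0L) return(NULL)
  list(intensity = sum_rgb / 765 / n_green,
       dark_threshold = n_dark / n_green,
       dark_codeset = n_codeset / n_green,
       band_proportions = c(dark = n_dark / n_green,
                            medium = n_medium / n_green,
                            light = n_light / n_green),
       n_green_pixels = n_green)
}

# Brute-force per-pixel color tally
brute_force_histogram <- function(grid, mask) {
  a <- unclass(grid)
  d <- dim(a)
  counts <- new.env()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!mask[i, j]) next
    k <- paste(a[i, j, 1], a[i, j, 2], a[i, j, 3])
    counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
  }
  keys <- ls(counts)
  if (!length(keys)) return(color_histogram())
  rgb <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  color_histogram(data.frame(r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
                             count = vapply(keys, function(k) counts[[k]],
                                            integer(1))))
}

# Histogram literal: one entry per row of data.frame(r, g, b, count)
hist_of <- function(...) {
  color_histogram(as.data.frame(rbind(...)))
}
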