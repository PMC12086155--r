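#' Per-color pixel histogram of a segmented region
#'
#' The raw reduction an image-analysis program makes of a segmented canopy:
#' every uniquely observed RGB code with its pixel count. All color indices
#' in this package are computed from this form, which is exactly equivalent
#' to the per-pixel data but far smaller after palette quantization.
#'
#' @param entries data.frame with integer columns `r`, `g`, `b`, `count`
#'   (all counts >= 1, colors distinct).
#' @return an object of class `color_histogram` (a data.frame).
#' @export
color_histogram <- function(entries = data.frame(r = integer(), g = integer(),
                                                 b = integer(),
                                                 count = integer())) {
  stopifnot(is.data.frame(entries),
            all(c("r", "g", "b", "count") %in% names(entries)))
  entries <- entries[, c("r", "g", "b", "count")]
  for (col in names(entries)) entries[[col]] <- as.integer(entries[[col]])
  if (nrow(entries)) {
    if (any(entries$count < 1L))
      stop("histogram counts must be >= 1", call. = FALSE)
    rng <- range(entries[c("r", "g", "b")])
    if (rng[1] < 0L || rng[2] > 255L)
      stop("channel values must lie in [0, 255]", call. = FALSE)
    if (anyDuplicated(pack_rgb(entries$r, entries$g, entries$b)))
      stop("histogram colors must be distinct", call. = FALSE)
  }
  rownames(entries) <- NULL
  class(entries) <- c("color_histogram", "data.frame")
  entries
}

#' @rdname color_histogram
#' @param hist a `color_histogram`.
#' @return `total_pixels()`: the number of pixels tallied.
#' @export
total_pixels <- function(hist) sum(hist$count)

#' @export
print.color_histogram <- function(x, ...) {
  cat(sprintf("<color_histogram> %d distinct colors, %d pixels\n",
              nrow(x), total_pixels(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Tally masked pixels into a color histogram
#'
#' @param grid a [pixel_grid()].
#' @param mask a [segmentation_mask()] of the same dimensions; `NULL` tallies
#'   every pixel.
#' @return a [color_histogram()] whose total equals the masked pixel count.
#' @export
build_histogram <- function(grid, mask = NULL) {
  grid <- as_pixel_grid(grid)
  d <- dim(grid)
  if (is.null(mask)) mask <- segmentation_mask(matrix(TRUE, d[1], d[2]))
  if (!identical(dim(unclass(mask)), d[1:2]))
    stop("mask dimensions do not match the image", call. = FALSE)
  ch <- grid_channels(grid)
  keep <- as.logical(mask)
  key <- pack_rgb(ch$r, ch$g, ch$b)[keep]
  if (!length(key)) return(color_histogram())
  tab <- table_int(key)
  rgb <- unpack_rgb(tab$key)
  color_histogram(data.frame(r = rgb[, "r"], g = rgb[, "g"], b = rgb[, "b"],
                             count = tab$count))
}

#' Keep only green pixels
#'
#' The inclusion rule for all color indices: a pixel enters the analysis only
#' if its G value strictly exceeds both its R and its B value. Ties are
#' excluded, so achromatic colors (black, grays, white) never pass.
#'
#' @param hist a [color_histogram()].
#' @return the filtered [color_histogram()]; counts of retained entries are
#'   unchanged. Idempotent.
#' @export
filter_green <- function(hist) {
  stopifnot(inherits(hist, "color_histogram"))
  color_histogram(as.data.frame(hist)[hist$g > hist$r & hist$g > hist$b, ,
                                      drop = FALSE])
}

#' Read or write a histogram as delimited text
#'
#' Tab-separated with header `r g b count` — the interchange format of the
#' per-color output of canopy image-analysis programs.
#'
#' @param hist a [color_histogram()].
#' @param path file path.
#' @return `write_histogram()`: `path` invisibly; `read_histogram()`: a
#'   [color_histogram()].
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "color_histogram"))
  utils::write.table(as.data.frame(hist), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  if (!file.exists(path))
    stop("histogram file not found: ", path, call. = FALSE)
  color_histogram(utils::read.table(path, header = TRUE, sep = "\t"))
}
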