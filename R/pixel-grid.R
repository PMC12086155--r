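#' Pixel grid: an 8-bit RGB raster
#'
#' A `pixel_grid` stores one canopy photograph as an integer array of
#' dimension `height x width x 3` with channel values in 0-255 (R, G, B).
#' Row-major, origin top-left. All image-level operations in the package
#' (palette quantization, segmentation, histogram extraction) consume and
#' produce this class.
#'
#' @param x integer array `h x w x 3`, values in 0-255, or a numeric array
#'   on the unit scale (auto-detected and rescaled by [as_pixel_grid()]).
#' @return an object of class `pixel_grid`.
#' @export
pixel_grid <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("pixel_grid requires an array of dimension h x w x 3", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("pixel_grid dimensions must be positive", call. = FALSE)
  storage.mode(x) <- "integer"
  if (anyNA(x) || min(x) < 0L || max(x) > 255L)
    stop("channel values must be integers in [0, 255]", call. = FALSE)
  structure(x, class = "pixel_grid")
}

#' @rdname pixel_grid
#' @export
as_pixel_grid <- function(x) {
  if (inherits(x, "pixel_grid")) return(x)
  if (is.array(x) && length(dim(x)) == 3L && is.double(x) && max(x) <= 1)
    x <- round(x * 255)
  pixel_grid(x)
}

#' @export
print.pixel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pixel_grid> %d x %d px, %d distinct colors\n",
              d[2], d[1], n_distinct_colors(x)))
  invisible(x)
}

#' @export
dim.pixel_grid <- function(x) dim(unclass(x))

# pack each pixel into a single integer key (r*2^16 + g*2^8 + b); channel
# values <= 255 so the key fits comfortably in a double/integer
pack_rgb <- function(r, g, b) r * 65536L + g * 256L + b

unpack_rgb <- function(key) {
  r <- key %/% 65536L
  g <- (key %% 65536L) %/% 256L
  b <- key %% 256L
  cbind(r = r, g = g, b = b)
}

grid_channels <- function(grid) {
  a <- unclass(grid)
  list(r = as.integer(a[, , 1]), g = as.integer(a[, , 2]),
       b = as.integer(a[, , 3]))
}

#' Number of distinct RGB colors in a grid
#' @param grid a [pixel_grid()].
#' @return integer count of unique colors.
#' @export
n_distinct_colors <- function(grid) {
  ch <- grid_channels(grid)
  length(unique(pack_rgb(ch$r, ch$g, ch$b)))
}

#' Read a raster image as an RGB pixel grid
#'
#' Supports PNG, JPEG and (if the \pkg{tiff} package is installed) TIFF.
#' Grayscale images are replicated across channels; an alpha channel is
#' discarded. The format is chosen by file extension.
#'
#' @param path path to an image file.
#' @return a [pixel_grid()].
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      tif  = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("reading TIFF requires the 'tiff' package", call. = FALSE)
        tiff::readTIFF(path)
      },
      stop("unsupported image format '", ext, "': ", path, call. = FALSE)
    ),
    error = function(e)
      stop("cannot read image ", path, ": ", conditionMessage(e),
           call. = FALSE)
  )
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  nch <- dim(img)[3]
  rgb <- if (nch == 1L) img[, , c(1L, 1L, 1L), drop = FALSE]
         else img[, , 1:3, drop = FALSE]  # drop alpha if present
  pixel_grid(array(as.integer(round(rgb * 255)), dim = dim(rgb)))
}

#' Write a pixel grid to a PNG file
#' @param grid a [pixel_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, path) {
  grid <- as_pixel_grid(grid)
  png::writePNG(unclass(grid) / 255, path)
  invisible(path)
}

#' Read a vegetation mask from a single-channel PNG
#'
#' Nonzero pixels are vegetation. Externally produced masks let index
#' computation proceed independently of the built-in segmentation.
#'
#' @param path path to a PNG mask.
#' @return a logical matrix (`TRUE` = vegetation) of class `segmentation_mask`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop("mask file not found: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  segmentation_mask(img > 0)
}

#' @rdname read_mask
#' @param mask logical matrix, `TRUE` = vegetation.
#' @export
segmentation_mask <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  structure(mask, class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d px, %d vegetation (%.1f%%)\n",
              ncol(x), nrow(x), sum(x), 100 * mean(x)))
  invisible(x)
}
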