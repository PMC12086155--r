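test_that("images round-trip through PNG exactly", {
  arr <- array(c(10L, 250L, 0L, 85L,
                 20L, 251L, 85L, 85L,
                 30L, 252L, 0L, 51L), c(2, 2, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_image(pixel_grid(arr), path)
  back <- read_image(path)
  expect_identical(unclass(back), unclass(pixel_grid(arr)))
})

test_that("grayscale input replicates the value across channels", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(100 / 255, 3, 3), path)
  g <- read_image(path)
  expect_true(all(unclass(g) == 100L))
  expect_equal(dim(g), c(3L, 3L, 3L))
})

test_that("alpha channels are discarded on read", {
  path <- withr::local_tempfile(fileext = ".png")
  rgba <- array(c(rep(0.5, 8), rep(0.2, 4)), c(2, 2, 3))
  png::writePNG(array(c(rgba, rep(0.7, 4)), c(2, 2, 4)), path)
  g <- read_image(path)
  expect_equal(dim(g)[3], 3L)
})

test_that("unreadable or missing image files signal input errors", {
  expect_error(read_image("no/such/file.png"), "not found")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(read_image(bad), "cannot read image")
  txt <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", txt)
  expect_error(read_image(txt), "unsupported")
})

test_that("quantization returns inputs already under the palette budget", {
  arr <- array(0L, c(4, 4, 3))
  arr[, , 2] <- rep(c(85L, 170L), each = 8)
  g <- pixel_grid(arr)
  expect_identical(unclass(quantize_palette(g, 256)), unclass(g))
})

test_that("quantization respects the budget and preserves dimensions", {
  set.seed(42)
  g <- random_grid(40, 25)
  stopifnot(n_distinct_colors(g) > 256)
  q <- quantize_palette(g, 256)
  expect_lte(n_distinct_colors(q), 256)
  expect_equal(dim(q), dim(g))
})

test_that("median cut on two clusters returns the cluster colors", {
  # two distinct colors within budget: returned bit-identically
  arr <- array(0L, c(2, 4, 3))
  arr[, 1:2, 1] <- 0L;   arr[, 1:2, 2] <- 85L;  arr[, 1:2, 3] <- 0L
  arr[, 3:4, 1] <- 255L; arr[, 3:4, 2] <- 255L; arr[, 3:4, 3] <- 255L
  g <- pixel_grid(arr)
  expect_identical(unclass(quantize_palette(g, 2)), unclass(g))

  # real split pass: a dark cluster and a near-white pair reduce to the
  # dark color (its own box) and the white cluster mean
  arr2 <- array(0L, c(2, 8, 3))
  arr2[, 1:4, 2] <- 85L
  arr2[, 5:6, ] <- 255L
  arr2[, 7:8, ] <- 253L
  q <- quantize_palette(pixel_grid(arr2), 2)
  h <- build_histogram(q)
  expect_equal(nrow(h), 2L)
  expect_true(any(h$r == 0 & h$g == 85 & h$b == 0))
  expect_true(any(h$r == 254 & h$g == 254 & h$b == 254))
  expect_equal(dim(q), dim(pixel_grid(arr2)))
})

test_that("quantization never increases the distinct-color count", {
  for (seed in 1:5) {
    g <- random_grid(24, 24, seed = seed)
    for (k in c(2, 16, 256)) {
      q <- quantize_palette(g, k)
      expect_lte(n_distinct_colors(q), min(k, n_distinct_colors(g)))
      expect_equal(dim(q), dim(g))
    }
  }
  expect_error(quantize_palette(random_grid(4, 4, seed = 1), 1), "max_colors")
})

test_that("black-background segmentation keeps background dark", {
  g <- pixel_grid(array(0L, c(5, 5, 3)))
  m <- segment_vegetation(g, "black-background")
  expect_false(any(m))
})

test_that("excess-green segmentation marks pure green as vegetation", {
  arr <- array(0L, c(4, 4, 3)); arr[, , 2] <- 255L
  m <- segment_vegetation(pixel_grid(arr), "excess-green", threshold = 20)
  expect_true(all(m))
  expect_error(segment_vegetation(pixel_grid(arr), "luminance"))
})

test_that("segmentation recovers the generator's ground-truth leaf mask", {
  for (seed in c(3, 11)) {
    sc <- gen_canopy_image(canopy_image_spec(seed = seed))
    m <- segment_vegetation(sc$grid, "black-background")
    expect_gte(mean(unclass(m) == unclass(sc$mask)), 0.99)
  }
})

test_that("external mask files bypass segmentation", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(c(1, 0, 0, 1), 2, 2), path)
  m <- read_mask(path)
  expect_identical(as.logical(m), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("histograms tally masked pixels and conserve their count", {
  arr <- array(7L, c(2, 2, 3))
  full <- build_histogram(pixel_grid(arr))
  expect_equal(nrow(full), 1L)
  expect_equal(full$count, 4L)
  expect_equal(total_pixels(full), 4L)

  none <- build_histogram(pixel_grid(arr),
                          segmentation_mask(matrix(FALSE, 2, 2)))
  expect_equal(nrow(none), 0L)
  expect_equal(total_pixels(none), 0L)

  expect_error(build_histogram(pixel_grid(arr),
                               segmentation_mask(matrix(TRUE, 3, 3))),
               "dimensions")
})

test_that("histogram counts match a brute-force per-pixel tally", {
  set.seed(99)
  g <- random_grid(64, 64, palette = reference_green_palette())
  mask <- matrix(runif(64 * 64) < 0.7, 64, 64)
  h <- build_histogram(g, segmentation_mask(mask))
  o <- brute_force_histogram(g, mask)
  ord <- function(x) {
    x <- as.data.frame(x)
    x[order(x$r, x$g, x$b), ]
  }
  expect_equal(ord(h), ord(o), ignore_attr = TRUE)
  expect_equal(total_pixels(h), sum(mask))
})

test_that("the green rule keeps strict G dominance only, idempotently", {
  pal <- reference_green_palette()
  h <- color_histogram(data.frame(pal[, c("r", "g", "b")], count = 1L))
  expect_equal(nrow(filter_green(h)), 12L)           # all palette codes pass
  mixed <- hist_of(c(r = 102, g = 128, b = 0, count = 5),
                   c(r = 255, g = 255, b = 255, count = 3),  # tie: excluded
                   c(r = 50, g = 50, b = 50, count = 2),
                   c(r = 10, g = 200, b = 10, count = 7))
  f <- filter_green(mixed)
  expect_setequal(f$g, c(128L, 200L))
  expect_equal(sort(f$count), c(5L, 7L))
  expect_identical(filter_green(f), f)
})

test_that("histograms round-trip through delimited text", {
  h <- hist_of(c(r = 0, g = 85, b = 0, count = 30),
               c(r = 102, g = 170, b = 51, count = 70))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_histogram(h, path)
  expect_identical(read_histogram(path), h)
})
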