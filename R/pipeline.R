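#' Pipeline configuration
#'
#' Bundles every tunable of the photo-to-report workflow. Images are expected
#' as `<plant_id>_<device>.png/.jpg` with device `a` (Samsung-class) and `b`
#' (Apple-class); an optional mask `<plant_id>_<device>_mask.png` (nonzero =
#' vegetation) bypasses the built-in segmentation for that image.
#'
#' @param image_dir directory of canopy photographs.
#' @param metadata path to a CSV with columns `plant_id`, `treatment`,
#'   `fresh_weight` and optionally `experiment_id`, `leaf_count`.
#' @param output_dir where result tables are written; `NULL` keeps results
#'   in memory only.
#' @param segmentation `"black-background"` or `"excess-green"`; see
#'   [segment_vegetation()].
#' @param seg_threshold segmentation threshold override (`NULL` = mode
#'   default).
#' @param quantize apply GIF-style palette reduction before tallying.
#' @param max_colors palette budget when `quantize` is `TRUE`.
#' @param dark_mode `"threshold"` or `"codeset"`; see
#'   [dark_green_proportion()].
#' @param denominator `"green"` or `"all"`; see [compute_metrics()].
#' @param adjust pairwise p-adjustment method; see [anova_oneway()].
#' @param seed seed recorded for provenance (analysis itself is
#'   deterministic).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(image_dir, metadata, output_dir = NULL,
                            segmentation = "black-background",
                            seg_threshold = NULL,
                            quantize = TRUE, max_colors = 256L,
                            dark_mode = "threshold", denominator = "green",
                            adjust = "none", seed = 1L) {
  structure(list(image_dir = image_dir, metadata = metadata,
                 output_dir = output_dir, segmentation = segmentation,
                 seg_threshold = seg_threshold, quantize = quantize,
                 max_colors = as.integer(max_colors), dark_mode = dark_mode,
                 denominator = denominator, adjust = adjust, seed = seed),
            class = "pipeline_config")
}

analyze_one_image <- function(path, config, mask_path = NULL) {
  grid <- read_image(path)
  if (isTRUE(config$quantize)) grid <- quantize_palette(grid,
                                                        config$max_colors)
  mask <- if (!is.null(mask_path) && file.exists(mask_path))
    read_mask(mask_path)
  else segment_vegetation(grid, config$segmentation, config$seg_threshold)
  compute_metrics(build_histogram(grid, mask), mode = config$dark_mode,
                  denominator = config$denominator)
}

#' Run the full photo-to-report pipeline
#'
#' Stages: per-image color metrics (quantize, segment, tally, filter,
#' index); Bland-Altman device agreement per color parameter; device
#' averaging; join with plant metadata; treatment ANOVA, pairwise contrasts
#' and the weight-color fits. Deterministic given the configuration. Images
#' that fail to process are skipped and counted; missing essential inputs
#' fail immediately.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return a list of class `pipeline_result`: `metrics` (per image),
#'   `agreement` (per parameter), `records` (device-averaged, joined),
#'   `report` ([experiment_report()]), `errors` (character vector of
#'   skipped-image messages).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  if (!dir.exists(config$image_dir))
    stop("image directory not found: ", config$image_dir, call. = FALSE)
  if (!file.exists(config$metadata))
    stop("metadata file not found: ", config$metadata, call. = FALSE)
  files <- list.files(config$image_dir,
                      pattern = "_[ab]\\.(png|jpg|jpeg|tif|tiff)$",
                      ignore.case = TRUE)
  if (!length(files))
    stop("no device images (*_a.* / *_b.*) in ", config$image_dir,
         call. = FALSE)
  meta <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)

  errors <- character()
  rows <- list()
  for (f in files) {
    stem <- sub("\\.[^.]+$", "", f)
    device <- sub(".*_", "", stem)
    plant_id <- sub("_[ab]$", "", stem)
    mask_path <- file.path(config$image_dir, paste0(stem, "_mask.png"))
    mm <- tryCatch(
      analyze_one_image(file.path(config$image_dir, f), config, mask_path),
      error = function(e) {
        errors <<- c(errors, paste0(f, ": ", conditionMessage(e)))
        NULL
      })
    if (is.null(mm)) next
    rows[[length(rows) + 1L]] <- data.frame(
      plant_id = plant_id, device = device, mode = mm$mode,
      n_green_pixels = mm$n_green_pixels, intensity = mm$intensity,
      dark_green_proportion = mm$dark_green_proportion,
      p_dark = mm$band_proportions[["dark"]],
      p_medium = mm$band_proportions[["medium"]],
      p_light = mm$band_proportions[["light"]])
  }
  metrics <- do.call(rbind, rows)
  if (is.null(metrics))
    stop("every image failed to process:\n",
         paste(errors, collapse = "\n"), call. = FALSE)
  say(sprintf("analyzed %d image(s), skipped %d", nrow(metrics),
              length(errors)))

  # device agreement on plants measured by both devices
  a <- metrics[metrics$device == "a", ]
  b <- metrics[metrics$device == "b", ]
  common <- intersect(a$plant_id, b$plant_id)
  agreement <- NULL
  if (length(common) >= 2L) {
    ia <- match(common, a$plant_id); ib <- match(common, b$plant_id)
    long <- rbind(
      data.frame(target_id = common, parameter = "intensity",
                 device_a_value = a$intensity[ia],
                 device_b_value = b$intensity[ib]),
      data.frame(target_id = common, parameter = "dark_green_proportion",
                 device_a_value = a$dark_green_proportion[ia],
                 device_b_value = b$dark_green_proportion[ib]))
    agreement <- agreement_table(long)
    say(sprintf("agreement over %d paired plant(s)", length(common)))
  }

  # device-averaged metrics joined with metadata
  avg <- stats::aggregate(
    metrics[, c("intensity", "dark_green_proportion")],
    by = list(plant_id = metrics$plant_id), FUN = mean)
  records <- merge(meta, avg, by = "plant_id")
  dropped <- setdiff(meta$plant_id, records$plant_id)
  if (length(dropped))
    say(sprintf("dropped %d plant(s) without image metrics", length(dropped)))
  records <- plant_records(records)
  report <- experiment_report(records, agreement)

  result <- structure(list(metrics = metrics, agreement = agreement,
                           records = records, report = report,
                           errors = errors, config = config),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_result(result)
  result
}

write_pipeline_result <- function(result) {
  out <- result$config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metrics, file.path(out, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(result$agreement))
    utils::write.csv(result$agreement, file.path(out, "agreement.csv"),
                     row.names = FALSE)
  utils::write.csv(result$records, file.path(out, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$treatment_summary,
                   file.path(out, "treatment_summary.csv"),
                   row.names = FALSE)
  con <- file(file.path(out, "summary.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(result$report)
  if (length(result$errors))
    cat("Skipped images:\n", paste(" -", result$errors, collapse = "\n"),
        "\n")
  invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d image metric row(s), %d skipped\n",
              nrow(x$metrics), length(x$errors)))
  print(x$report)
  invisible(x)
}
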