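TREATMENTS <- c("C", "N", "LV", "I")

#' Validate a plant-record table
#'
#' One row per plant: identifiers, fertilizer treatment (C = untreated
#' control, N = nitrogen, LV = leafy-vegetable compound, I = microelement),
#' fresh weight in grams (above-ground mass at harvest), leaf count (leaves
#' at least 2 cm on the longest side), and the device-averaged color indices.
#'
#' @param data data.frame with columns `plant_id`, `treatment`,
#'   `fresh_weight`, and optionally `experiment_id`, `leaf_count`,
#'   `intensity`, `dark_green_proportion`.
#' @return the validated data.frame, `treatment` as a factor with levels
#'   C, N, LV, I.
#' @export
plant_records <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("plant_id", "treatment", "fresh_weight")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("plant records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(as.character(data$treatment)), TREATMENTS)
  if (length(bad))
    stop("unknown treatment code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  data$treatment <- factor(as.character(data$treatment), levels = TREATMENTS)
  if (any(data$fresh_weight <= 0, na.rm = TRUE))
    stop("fresh_weight must be positive (grams)", call. = FALSE)
  data
}

check_groups <- function(records, response) {
  if (!response %in% names(records))
    stop("no column '", response, "' in records", call. = FALSE)
  counts <- table(droplevels(records$treatment))
  if (sum(counts >= 2L) < 2L)
    stop("insufficient data: need >= 2 treatment groups with >= 2 records",
         call. = FALSE)
  invisible(counts)
}

#' One-way ANOVA across fertilizer treatments
#'
#' Compares a response (fresh weight, leaf count, or a color index) between
#' the treatment groups with a standard one-way F test, and attaches
#' unadjusted pairwise Welch contrasts.
#'
#' @param records a [plant_records()] table.
#' @param response column name of the response.
#' @param adjust p-adjustment method for the pairwise contrasts
#'   (`"none"`, the default, or any [stats::p.adjust.methods] value such as
#'   `"holm"`).
#' @return class `treatment_comparison`: list with `response`, `F`, `p`,
#'   `df`, `group_means`, `pairwise` (data.frame `group1`, `group2`, `p`).
#' @export
anova_oneway <- function(records, response, adjust = "none") {
  records <- plant_records(records)
  check_groups(records, response)
  records <- droplevels(records[!is.na(records[[response]]), ])
  fit <- stats::aov(stats::reformulate("treatment", response), data = records)
  tab <- summary(fit)[[1]]
  structure(list(
    response = response,
    F = tab[["F value"]][1],
    p = tab[["Pr(>F)"]][1],
    df = c(tab[["Df"]][1], tab[["Df"]][2]),
    group_means = tapply(records[[response]], records$treatment, mean),
    pairwise = pairwise_treatment_tests(records, response, adjust = adjust)
  ), class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("<treatment_comparison> %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$response, x$df[1], x$df[2], x$F, x$p))
  cat("  group means:",
      paste(sprintf("%s = %.2f", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise Welch t-tests between treatments
#'
#' @inheritParams anova_oneway
#' @return data.frame with columns `group1`, `group2`, `p`.
#' @export
pairwise_treatment_tests <- function(records, response, adjust = "none") {
  records <- plant_records(records)
  check_groups(records, response)
  records <- droplevels(records[!is.na(records[[response]]), ])
  pw <- stats::pairwise.t.test(records[[response]], records$treatment,
                               p.adjust.method = adjust, pool.sd = FALSE)
  m <- pw$p.value
  out <- expand.grid(group1 = colnames(m), group2 = rownames(m),
                     stringsAsFactors = FALSE)
  out$p <- as.vector(t(m))
  out[!is.na(out$p), , drop = FALSE]
}

#' Fresh weight as a function of leaf color within treatments
#'
#' Fits the ANCOVA `fresh_weight ~ treatment + predictor`: per-treatment
#' intercepts with a common color slope, so the slope measures the
#' weight-color relationship after accounting for treatment effects. With
#' one endpoint observation per plant there is no identifiable plant-level
#' random effect; for records pooled over several experiments a
#' random-intercept-by-experiment variant is available.
#'
#' @param records a [plant_records()] table with the predictor column and
#'   `fresh_weight` present.
#' @param predictor `"intensity"` or `"dark_green_proportion"`.
#' @param random_experiment if `TRUE`, fit a random intercept per
#'   `experiment_id` (requires \pkg{lme4} and >= 2 experiments) instead of
#'   purely fixed effects.
#' @return class `weight_color_fit`: list with `predictor`, `slope` (g per
#'   unit predictor), `slope_se`, `slope_ci` (95%), `p_slope`, `r_squared`
#'   (squared correlation of fitted vs observed weights), `r_squared_marginal`
#'   (squared weight-predictor correlation, ignoring treatment),
#'   `per_treatment_intercepts`, `n`, and the underlying `model`.
#' @export
fit_weight_model <- function(records,
                             predictor = c("intensity",
                                           "dark_green_proportion"),
                             random_experiment = FALSE) {
  predictor <- match.arg(predictor)
  records <- plant_records(records)
  if (!predictor %in% names(records))
    stop("no column '", predictor, "' in records", call. = FALSE)
  records <- droplevels(records[stats::complete.cases(
    records[, c("fresh_weight", "treatment", predictor)]), ])
  if (length(unique(records[[predictor]])) < 3L)
    stop("model is rank deficient: predictor '", predictor,
         "' takes fewer than 3 distinct values", call. = FALSE)
  if (nlevels(records$treatment) < 2L)
    stop("insufficient data: need >= 2 treatments represented",
         call. = FALSE)

  if (random_experiment) {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("random_experiment = TRUE requires the 'lme4' package",
           call. = FALSE)
    if (!"experiment_id" %in% names(records) ||
        length(unique(records$experiment_id)) < 2L)
      stop("random_experiment = TRUE needs >= 2 distinct experiment_id",
           call. = FALSE)
    fml <- stats::as.formula(paste("fresh_weight ~ 0 + treatment +",
                                   predictor, "+ (1 | experiment_id)"))
    fit <- lme4::lmer(fml, data = records)
    co <- summary(fit)$coefficients
    slope <- co[predictor, "Estimate"]
    se <- co[predictor, "Std. Error"]
    p_slope <- 2 * stats::pnorm(-abs(co[predictor, "t value"]))
    ints <- co[grep("^treatment", rownames(co)), "Estimate"]
    fitted_w <- stats::fitted(fit)
  } else {
    fml <- stats::reformulate(c("0", "treatment", predictor), "fresh_weight")
    fit <- stats::lm(fml, data = records)
    co <- summary(fit)$coefficients
    slope <- co[predictor, "Estimate"]
    se <- co[predictor, "Std. Error"]
    p_slope <- co[predictor, "Pr(>|t|)"]
    ints <- co[grep("^treatment", rownames(co)), "Estimate"]
    fitted_w <- stats::fitted(fit)
  }
  names(ints) <- sub("^treatment", "", names(ints))
  tq <- stats::qt(0.975, nrow(records) - length(ints) - 1L)
  structure(list(
    predictor = predictor,
    slope = unname(slope), slope_se = unname(se),
    slope_ci = c(lower = slope - tq * se, upper = slope + tq * se),
    p_slope = unname(p_slope),
    r_squared = stats::cor(fitted_w, records$fresh_weight)^2,
    r_squared_marginal = stats::cor(records[[predictor]],
                                    records$fresh_weight)^2,
    per_treatment_intercepts = ints,
    n = nrow(records),
    model = fit
  ), class = "weight_color_fit")
}

#' @export
print.weight_color_fit <- function(x, ...) {
  cat(sprintf("<weight_color_fit> fresh_weight ~ treatment + %s (n = %d)\n",
              x$predictor, x$n))
  cat(sprintf("  slope = %.2f g/unit (se %.2f), p = %.4g, R2 = %.3f (marginal %.3f)\n",
              x$slope, x$slope_se, x$p_slope, x$r_squared,
              x$r_squared_marginal))
  invisible(x)
}

#' Assemble the per-experiment result tables
#'
#' Bundles treatment summaries, ANOVA and pairwise p-values for fresh weight
#' and leaf count, and the weight-color fits for both color indices.
#'
#' @param records a [plant_records()] table (possibly empty).
#' @param agreement optional [agreement_table()] output to carry along.
#' @return class `experiment_report`: list with `treatment_summary`,
#'   `comparisons` (per response), `fits` (per predictor), `agreement`.
#' @export
experiment_report <- function(records, agreement = NULL) {
  if (is.null(records) || nrow(records) == 0L)
    return(structure(list(treatment_summary = data.frame(),
                          comparisons = list(), fits = list(),
                          agreement = agreement),
                     class = "experiment_report"))
  records <- plant_records(records)
  num_cols <- intersect(c("fresh_weight", "leaf_count", "intensity",
                          "dark_green_proportion"), names(records))
  summ <- do.call(rbind, lapply(split(records, droplevels(records$treatment)),
    function(dd) {
      row <- data.frame(treatment = as.character(dd$treatment[1]),
                        n = nrow(dd))
      for (cc in num_cols) row[[paste0("mean_", cc)]] <- mean(dd[[cc]])
      row
    }))
  rownames(summ) <- NULL

  responses <- intersect(c("fresh_weight", "leaf_count"), names(records))
  comparisons <- lapply(responses, function(rs)
    tryCatch(anova_oneway(records, rs), error = function(e) NULL))
  names(comparisons) <- responses

  predictors <- intersect(c("intensity", "dark_green_proportion"),
                          names(records))
  fits <- lapply(predictors, function(pp)
    tryCatch(fit_weight_model(records, pp), error = function(e) NULL))
  names(fits) <- predictors

  structure(list(treatment_summary = summ,
                 comparisons = Filter(Negate(is.null), comparisons),
                 fits = Filter(Negate(is.null), fits),
                 agreement = agreement),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  if (nrow(x$treatment_summary)) {
    cat("Treatment summary:\n")
    print(x$treatment_summary)
  } else cat("  (no records)\n")
  for (cmp in x$comparisons) print(cmp)
  for (fit in x$fits) print(fit)
  if (!is.null(x$agreement)) {
    cat("Device agreement:\n")
    print(x$agreement)
  }
  invisible(x)
}
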