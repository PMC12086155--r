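#' Paired device measurements
#'
#' Measurements of the same targets by two cameras: `x` from device A
#' (Samsung-class in the study design), `y` from device B (Apple-class).
#' Pairs with a missing value on either device are dropped with a message.
#'
#' @param x,y numeric vectors of equal length on a common scale (both
#'   intensities or both proportions).
#' @param parameter optional label (`"intensity"` or
#'   `"dark_green_proportion"`).
#' @return a data.frame of class `paired_sample` with columns `x`, `y`.
#' @export
paired_sample <- function(x, y, parameter = NULL) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  if (any(!ok))
    message("dropping ", sum(!ok), " pair(s) with a missing device value")
  out <- data.frame(x = x[ok], y = y[ok])
  attr(out, "parameter") <- parameter
  class(out) <- c("paired_sample", "data.frame")
  out
}

#' Bland-Altman agreement analysis
#'
#' Quantifies the agreement between two measurement devices from paired
#' differences d = y - x: their mean `m`, sample standard deviation `s`
#' (n - 1 denominator), the 95% limits of agreement m +/- 1.96 s (the range
#' individual differences fall in), and the 95% confidence interval of the
#' mean difference m +/- 1.96 s / sqrt(n) (systematic bias if it excludes
#' zero).
#'
#' @param x a [paired_sample()], or device-A values if `y` is given.
#' @param y device-B values (optional, see `x`).
#' @return an object of class `bland_altman`: list with `n`, `m`, `s`,
#'   `loa` and `ci` (each `c(lower, upper)`).
#' @export
bland_altman <- function(x, y = NULL) {
  s <- if (inherits(x, "paired_sample")) x else paired_sample(x, y)
  n <- nrow(s)
  if (n < 2L)
    stop("Bland-Altman analysis needs at least 2 complete pairs",
         call. = FALSE)
  d <- s$y - s$x
  m <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(n = n, m = m, s = sd_d,
                 loa = c(lower = m - 1.96 * sd_d, upper = m + 1.96 * sd_d),
                 ci = c(lower = m - 1.96 * sd_d / sqrt(n),
                        upper = m + 1.96 * sd_d / sqrt(n)),
                 parameter = attr(s, "parameter")),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman>%s n = %d\n",
              if (is.null(x$parameter)) "" else paste0(" ", x$parameter),
              x$n))
  cat(sprintf("  mean difference m = %.4f, sd s = %.4f\n", x$m, x$s))
  cat(sprintf("  95%% LOA (%.4f, %.4f)   95%% CI (%.4f, %.4f)%s\n",
              x$loa[1], x$loa[2], x$ci[1], x$ci[2],
              if (x$ci[1] > 0 || x$ci[2] < 0) "  [systematic bias]" else ""))
  invisible(x)
}

#' Reconstruct the 95% CI of the mean difference from printed LOA
#'
#' The limits of agreement and the confidence interval share the midpoint m
#' and differ only by the factor sqrt(n) in half-width, so a published LOA
#' interval plus n determines the CI exactly: an internal-consistency check
#' for reported agreement tables.
#'
#' @param loa numeric `c(lower, upper)` with `lower <= upper`.
#' @param n number of paired observations, >= 1.
#' @return `c(lower, upper)` of the implied 95% CI.
#' @export
reconstruct_ci_from_loa <- function(loa, n) {
  if (length(loa) != 2L || any(is.na(loa)) || loa[1] > loa[2])
    stop("loa must be c(lower, upper) with lower <= upper", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  m <- mean(loa)
  half <- diff(range(loa)) / 2
  c(lower = m - half / sqrt(n), upper = m + half / sqrt(n))
}

#' Data behind a Bland-Altman plot
#'
#' @param sample a [paired_sample()].
#' @param result the matching [bland_altman()] fit; computed if omitted.
#' @return list with `points` (data.frame `mean` = (x+y)/2, `difference`
#'   = y - x) and `levels` (named horizontal reference lines: zero, m, LOA
#'   and CI bounds).
#' @export
agreement_plot_data <- function(sample, result = bland_altman(sample)) {
  stopifnot(inherits(sample, "paired_sample"),
            inherits(result, "bland_altman"))
  if (nrow(sample) != result$n)
    stop("sample and result sizes disagree", call. = FALSE)
  list(points = data.frame(mean = (sample$x + sample$y) / 2,
                           difference = sample$y - sample$x),
       levels = c(zero = 0, m = result$m,
                  loa_lower = unname(result$loa[1]),
                  loa_upper = unname(result$loa[2]),
                  ci_lower = unname(result$ci[1]),
                  ci_upper = unname(result$ci[2])))
}

#' Agreement summary table across color parameters
#'
#' @param data data.frame with columns `target_id`, `parameter`,
#'   `device_a_value`, `device_b_value` (one row per photographed target and
#'   parameter).
#' @return data.frame with one row per parameter: `parameter`, `n`, `m`,
#'   `s`, `loa_lower`, `loa_upper`, `ci_lower`, `ci_upper`.
#' @export
agreement_table <- function(data) {
  need <- c("target_id", "parameter", "device_a_value", "device_b_value")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  do.call(rbind, lapply(split(data, data$parameter), function(dd) {
    ba <- bland_altman(paired_sample(dd$device_a_value, dd$device_b_value,
                                     parameter = dd$parameter[1]))
    data.frame(parameter = dd$parameter[1], n = ba$n, m = ba$m, s = ba$s,
               loa_lower = unname(ba$loa[1]), loa_upper = unname(ba$loa[2]),
               ci_lower = unname(ba$ci[1]), ci_upper = unname(ba$ci[2]),
               row.names = NULL)
  }))
}
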