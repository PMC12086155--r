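make_records <- function(weights, treatments, ...) {
  plant_records(data.frame(plant_id = seq_along(weights),
                           treatment = treatments, fresh_weight = weights,
                           ...))
}

test_that("plant records validate treatment codes and weights", {
  expect_error(make_records(c(10, 20), c("C", "Z")), "unknown treatment")
  expect_error(make_records(c(10, -5), c("C", "N")), "positive")
  rec <- make_records(c(10, 20), c("N", "C"))
  expect_equal(levels(rec$treatment), c("C", "N", "LV", "I"))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(1)
  rec <- make_records(c(rnorm(8, 50, 5), rnorm(8, 60, 5)),
                      rep(c("C", "N"), each = 8))
  cmp <- anova_oneway(rec, "fresh_weight")
  tt <- t.test(fresh_weight ~ treatment, data = rec, var.equal = TRUE)
  expect_equal(cmp$F, unname(tt$statistic)^2)
  expect_equal(cmp$p, tt$p.value)
})

test_that("identical group means give a zero F statistic", {
  rec <- make_records(rep(c(40, 50, 60), 4),
                      rep(c("C", "N", "LV", "I"), each = 3))
  cmp <- anova_oneway(rec, "fresh_weight")
  expect_equal(cmp$F, 0)
  expect_equal(cmp$p, 1)
  expect_error(anova_oneway(make_records(c(1, 2), c("C", "N")),
                            "fresh_weight"), "insufficient")
})

test_that("ANOVA p agrees with a permutation oracle on a small instance", {
  set.seed(31)
  y <- c(rnorm(5, 50, 8), rnorm(5, 57, 8), rnorm(5, 52, 8))
  g <- rep(c("C", "N", "LV"), each = 5)
  rec <- make_records(y, g)
  p_f <- anova_oneway(rec, "fresh_weight")$p

  # permutation distribution of F via group sums (total SS is invariant)
  B <- 1e5
  gf <- factor(g)
  ng <- as.vector(table(gf))
  n <- length(y); k <- nlevels(gf)
  tot <- sum(y); sst <- sum(y^2) - tot^2 / n
  f_of <- function(yy) {
    s <- rowsum(yy, gf)
    ssb <- sum(s^2 / ng) - tot^2 / n
    (ssb / (k - 1)) / ((sst - ssb) / (n - k))
  }
  set.seed(99)
  perm <- vapply(seq_len(B), function(i) f_of(sample(y)), numeric(1))
  p_perm <- mean(perm >= f_of(y))
  expect_lt(abs(p_f - p_perm), 0.01)
})

test_that("pairwise Welch tests detect shifted groups and not identical ones", {
  set.seed(5)
  base <- rnorm(10, 50, 4)
  rec <- make_records(c(base, base, base + 40), # last group shifted 10 sd
                      rep(c("C", "N", "LV"), each = 10))
  pw <- pairwise_treatment_tests(rec, "fresh_weight")
  p_cn <- pw$p[(pw$group1 == "C" & pw$group2 == "N") |
                 (pw$group1 == "N" & pw$group2 == "C")]
  p_clv <- pw$p[(pw$group1 == "C" & pw$group2 == "LV") |
                  (pw$group1 == "LV" & pw$group2 == "C")]
  expect_gt(p_cn, 0.99)   # identical samples
  expect_lt(p_clv, 0.001)
  # Holm adjustment is monotone non-decreasing in p
  pw_h <- pairwise_treatment_tests(rec, "fresh_weight", adjust = "holm")
  expect_true(all(pw_h$p >= pw$p - 1e-12))
})

test_that("the nitrogen effect is flagged at the configured effect size", {
  flagged <- 0L
  for (seed in 1:40) {
    rec <- gen_experiment(synthetic_experiment_config(seed = seed))
    pw <- pairwise_treatment_tests(rec, "fresh_weight")
    p_nc <- pw$p[(pw$group1 == "C" & pw$group2 == "N") |
                   (pw$group1 == "N" & pw$group2 == "C")]
    flagged <- flagged + (p_nc < 0.05)
  }
  expect_gte(flagged / 40, 0.9)
})

test_that("a noiseless linear weight-color link is recovered exactly", {
  set.seed(8)
  dark <- runif(24, 0.1, 0.8)
  a_t <- c(C = 30, N = 50, LV = 45, I = 35)
  tr <- rep(c("C", "N", "LV", "I"), each = 6)
  rec <- make_records(a_t[tr] + 120 * dark, tr,
                      dark_green_proportion = dark)
  # suppress summary.lm's perfect-fit warning: the zero-noise line is the point
  fit <- suppressWarnings(fit_weight_model(rec, "dark_green_proportion"))
  expect_equal(fit$slope, 120)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$per_treatment_intercepts[c("C", "N", "LV", "I")],
               a_t, tolerance = 1e-8)
  expect_lt(fit$p_slope, 1e-12)
})

test_that("a constant predictor is reported as rank deficiency", {
  rec <- make_records(c(10, 20, 30, 40), rep(c("C", "N"), 2),
                      intensity = rep(0.3, 4))
  expect_error(fit_weight_model(rec, "intensity"), "rank deficient")
})

test_that("slopes are invariant to per-treatment weight shifts", {
  rec <- gen_experiment(synthetic_experiment_config(seed = 4))
  f0 <- fit_weight_model(rec, "dark_green_proportion")
  rec2 <- rec
  shift <- c(C = 100, N = -50, LV = 30, I = 0)[as.character(rec2$treatment)]
  rec2$fresh_weight <- rec2$fresh_weight + shift
  f1 <- fit_weight_model(rec2, "dark_green_proportion")
  expect_equal(f1$slope, f0$slope)
  expect_equal(f1$per_treatment_intercepts - f0$per_treatment_intercepts,
               c(C = 100, N = -50, LV = 30, I = 0))
})

test_that("the random-intercept variant fits pooled experiments", {
  skip_if_not_installed("lme4")
  rec <- rbind(gen_experiment(synthetic_experiment_config(seed = 21),
                              experiment_id = "e1"),
               gen_experiment(synthetic_experiment_config(seed = 22),
                              experiment_id = "e2"))
  fit <- fit_weight_model(rec, "dark_green_proportion",
                          random_experiment = TRUE)
  expect_gt(fit$slope, 0)
  expect_lt(fit$p_slope, 0.01)
  expect_error(fit_weight_model(gen_experiment(), "dark_green_proportion",
                                random_experiment = TRUE), "experiment_id")
})

test_that("experiment reports assemble treatment rows, tests and fits", {
  empty <- experiment_report(data.frame())
  expect_s3_class(empty, "experiment_report")
  expect_equal(nrow(empty$treatment_summary), 0L)

  rec <- gen_experiment(synthetic_experiment_config(seed = 13))
  rep13 <- experiment_report(rec)
  expect_equal(nrow(rep13$treatment_summary), 4L)
  expect_length(rep13$fits, 2L)
  direct <- fit_weight_model(rec, "intensity")
  expect_equal(rep13$fits$intensity$slope, direct$slope)
  expect_equal(rep13$fits$intensity$r_squared, direct$r_squared)
  expect_named(rep13$comparisons, c("fresh_weight", "leaf_count"))
})
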