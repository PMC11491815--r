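test_that("arcsine square-root transform has the right fixed points", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.25), pi / 6)
  p <- seq(0, 1, 0.05)
  expect_true(all(diff(arcsine_sqrt(p)) > 0))   # monotone increasing
  expect_error(arcsine_sqrt(1.1), "\\[0, 1\\]")
})

test_that("sex comparison uses the Welch form with fractional df", {
  s <- make_summaries(13, seed = 2)
  res <- compare_sexes(s, "r_flight", transform = "arcsine")
  expect_s3_class(res, "comparison_result")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_gt(res$df, 0)
  # identical groups: statistic 0, p = 1
  s2 <- s
  s2$r_flight <- rep(s$r_flight[1:13], 2)
  res2 <- compare_sexes(s2, "r_flight")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  # equal variances and sizes: Welch df reduces to pooled df (2n - 2)
  expect_equal(res2$df, 24)
  # record order is irrelevant
  res3 <- compare_sexes(s[sample(nrow(s)), ], "r_flight", transform = "arcsine")
  expect_equal(res3$statistic, res$statistic)
  expect_error(compare_sexes(s[s$sex == "male", ], "r_flight"), "both sexes")
})

test_that("paired comparison reports n - 1 df and flags degenerate pairs", {
  set.seed(3)
  pairs <- data.frame(female = rnorm(6, 0.13, 0.03), male = rnorm(6, 0.14, 0.03))
  res <- compare_pairs(pairs, transform = "arcsine")
  expect_equal(res$df, 5)                       # six breeding pairs
  # identical members: statistic 0
  same <- data.frame(female = c(0.1, 0.2, 0.3), male = c(0.1, 0.2, 0.3))
  res2 <- compare_pairs(same)
  expect_equal(res2$statistic, 0)
  expect_true(res2$degenerate)
  # constant nonzero difference: flagged, not a fake p-value
  res3 <- compare_pairs(data.frame(female = c(0.2, 0.3, 0.4), male = c(0.1, 0.2, 0.3)))
  expect_true(res3$degenerate)
  expect_true(is.na(res3$p_value))
  expect_error(compare_pairs(data.frame(female = c(0.1, NA), male = c(0.1, 0.2))),
               "unpaired")
})

test_that("brood-size ANOVA reduces to the squared pooled t with two levels", {
  set.seed(4)
  s <- data.frame(brood_size = rep(c(5, 6), each = 10), r_flight = rnorm(20, 0.13, 0.04))
  res <- brood_size_anova(s, "r_flight")
  tt <- t.test(r_flight ~ brood_size, data = s, var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  expect_error(brood_size_anova(data.frame(brood_size = rep(5, 8),
                                           r_flight = rnorm(8)), "r_flight"),
               "2 brood-size levels")
})

test_that("morphology-effort correlation reports r^2 and the regression line", {
  # perfectly linear: R^2 = 1
  d <- data.frame(Sstar = seq(0.06, 0.08, length.out = 10))
  d$vedba_mean_bird_g <- 0.2 + 7 * d$Sstar
  res <- suppressWarnings(morphology_effort_correlation(d))  # exact fit warns in summary.lm
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 7)
  expect_equal(res$intercept, 0.2)
  d$vedba_mean_bird_g <- rep(0.7, 10)
  expect_error(morphology_effort_correlation(d), "zero variance")
  expect_error(morphology_effort_correlation(d[1:2, ]), "at least 3")
})

test_that("regression coverage: the recovered slope is within 2 SEs of truth ~95% of the time", {
  set.seed(5)
  hits <- 0
  reps <- 300
  for (r in seq_len(reps)) {
    d <- data.frame(Sstar = rnorm(19, 0.068, 0.004))
    d$vedba_mean_bird_g <- 0.3 + 7 * d$Sstar + rnorm(19, 0, 0.05)
    res <- morphology_effort_correlation(d)
    if (abs(res$slope - 7) <= 2 * res$slope_se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})

test_that("the time-of-day smooth recovers structure", {
  # constant metric: flat curve at that value
  s <- data.frame(tag_hour = seq(5, 20, length.out = 12), r_flight = rep(0.13, 12))
  tr <- time_of_day_trend(s)
  expect_equal(tr$fit, rep(0.13, length(tr$hour)), tolerance = 1e-8)
  # U-shaped daily pattern: fitted minimum falls in the generated trough
  set.seed(6)
  h <- seq(5, 20, length.out = 40)
  y <- 0.15 - 0.07 * exp(-(h - 13)^2 / 8) + rnorm(40, 0, 0.005)
  tr2 <- time_of_day_trend(data.frame(tag_hour = h, r_flight = y))
  expect_true(tr2$hour[which.min(tr2$fit)] > 11 && tr2$hour[which.min(tr2$fit)] < 15)
  # band widens where data are sparse
  h3 <- c(seq(5, 10, length.out = 30), 16, 20)
  y3 <- 0.1 + 0.002 * h3 + rnorm(32, 0, 0.01)
  tr3 <- time_of_day_trend(data.frame(tag_hour = h3, r_flight = y3),
                           grid = c(7.5, 18))
  expect_gt(tr3$se[2], tr3$se[1])
  expect_error(time_of_day_trend(data.frame(tag_hour = rep(9, 10),
                                            r_flight = rnorm(10))), "identical")
  expect_error(time_of_day_trend(s[1:5, ]), "at least 8")
})
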