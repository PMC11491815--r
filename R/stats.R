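#' Arcsine square-root transform for proportions
#'
#' `asin(sqrt(p))`, the classical variance-stabilising transform for
#' proportion data; monotone increasing on `[0, 1]` with range `[0, pi/2]`.
#'
#' @param p proportions in `[0, 1]`.
#' @return transformed values in radians.
#' @export
arcsine_sqrt <- function(p) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  asin(sqrt(p))
}

.resolve_transform <- function(transform) {
  if (is.null(transform)) return(identity)
  if (is.function(transform)) return(transform)
  if (identical(transform, "arcsine")) return(arcsine_sqrt)
  stop("unknown transform: ", transform)
}

.comparison_result <- function(test_name, statistic, df, p_value, group_summaries,
                               extra = list()) {
  structure(c(list(test_name = test_name, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value),
                   group_summaries = group_summaries), extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, d.f. = %.4g, P = %.4g\n",
              x$test_name, x$statistic, x$df, x$p_value))
  if (!is.null(x$group_summaries)) print(x$group_summaries)
  invisible(x)
}

.group_summaries <- function(values, groups) {
  agg <- stats::aggregate(values, list(group = groups),
                          function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  data.frame(group = agg$group, mean = agg$x[, "mean"], sd = agg$x[, "sd"],
             n = agg$x[, "n"])
}

#' Two-sample sex comparison of a per-bird metric
#'
#' Welch's unequal-variance t-test (the default; pooled variance available)
#' on an optionally transformed metric, reporting the fractional degrees of
#' freedom of the Welch form. Group summaries are on the untransformed scale.
#'
#' @param summaries data frame of bird summaries with a `sex` column.
#' @param metric name of the metric column (e.g. `"r_flight"`).
#' @param transform `NULL`, `"arcsine"` or a function applied before testing.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return a `comparison_result` (statistic, fractional df, p, group means).
#' @export
compare_sexes <- function(summaries, metric, transform = NULL, var_equal = FALSE) {
  if (!metric %in% names(summaries)) stop("no column `", metric, "`")
  sexes <- unique(summaries$sex)
  if (!all(c("female", "male") %in% sexes))
    stop("both sexes must be present")
  f <- summaries[[metric]][summaries$sex == "female"]
  m <- summaries[[metric]][summaries$sex == "male"]
  if (length(f) < 2 || length(m) < 2) stop("each group needs at least 2 birds")
  tf <- .resolve_transform(transform)
  tt <- stats::t.test(tf(f), tf(m), var.equal = var_equal)
  .comparison_result(if (var_equal) "pooled t-test" else "Welch t-test",
                     tt$statistic, tt$parameter, tt$p.value,
                     .group_summaries(summaries[[metric]], summaries$sex))
}

#' Paired sex comparison within breeding pairs
#'
#' One-sample t-test on within-pair (female - male) differences of an
#' optionally transformed metric; df = number of pairs - 1. A zero-variance
#' difference vector is a degenerate case: flagged (`degenerate = TRUE`,
#' statistic 0 if the constant difference is 0, `NA` p-value otherwise).
#'
#' @param pairs data frame with one row per pair and columns `female` and
#'   `male` holding the two members' metric values.
#' @param transform `NULL`, `"arcsine"` or a function.
#' @return a `comparison_result`.
#' @export
compare_pairs <- function(pairs, transform = NULL) {
  if (!all(c("female", "male") %in% names(pairs)))
    stop("`pairs` needs `female` and `male` columns (unpaired record)")
  if (any(is.na(pairs$female)) || any(is.na(pairs$male)))
    stop("unpaired record: missing member value")
  n <- nrow(pairs)
  if (n < 2) stop("at least 2 complete pairs are required")
  tf <- .resolve_transform(transform)
  d <- tf(pairs$female) - tf(pairs$male)
  gs <- data.frame(group = c("female", "male"),
                   mean = c(mean(pairs$female), mean(pairs$male)),
                   sd = c(stats::sd(pairs$female), stats::sd(pairs$male)), n = n)
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {  # constant up to rounding
    return(.comparison_result("paired t-test", if (all(d == 0)) 0 else NA_real_,
                              n - 1, NA_real_, gs, extra = list(degenerate = TRUE)))
  }
  tt <- stats::t.test(d)
  .comparison_result("paired t-test", tt$statistic, tt$parameter, tt$p.value, gs,
                     extra = list(degenerate = FALSE))
}

#' One-way ANOVA of a metric across brood sizes
#'
#' Brood size is treated as a categorical factor; classical (pooled
#' variance) one-way ANOVA, so with two levels F equals the square of the
#' pooled t statistic.
#'
#' @param summaries data frame with `brood_size` and the metric column.
#' @param metric metric column name.
#' @param transform `NULL`, `"arcsine"` or a function.
#' @return a `comparison_result` with the F statistic, numerator df and p
#'   (denominator df in `df_resid`).
#' @export
brood_size_anova <- function(summaries, metric, transform = NULL) {
  if (!metric %in% names(summaries)) stop("no column `", metric, "`")
  g <- factor(summaries$brood_size)
  if (nlevels(g) < 2) stop("at least 2 brood-size levels are required")
  if (any(table(g) < 2)) stop("every brood-size level needs at least 2 birds")
  tf <- .resolve_transform(transform)
  y <- tf(summaries[[metric]])
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  .comparison_result("one-way ANOVA", s$`F value`[1], s$Df[1], s$`Pr(>F)`[1],
                     .group_summaries(summaries[[metric]], g),
                     extra = list(df_resid = s$Df[2]))
}

#' Pearson correlation of flight effort against wing morphology
#'
#' Correlates a per-bird effort metric (default `vedba_mean_bird_g`) with the
#' weight-normalized wing area `S*` (default `Sstar`), reporting Pearson r,
#' `R^2 = r^2`, the two-sided p-value and the least-squares line.
#'
#' @param data data frame of bird summaries joined to derived morphology.
#' @param x,y column names of the predictor and response.
#' @return a `comparison_result` with extras `r`, `r_squared`, `slope`,
#'   `intercept`.
#' @export
morphology_effort_correlation <- function(data, x = "Sstar", y = "vedba_mean_bird_g") {
  for (col in c(x, y)) if (!col %in% names(data)) stop("no column `", col, "`")
  keep <- stats::complete.cases(data[[x]], data[[y]])
  xv <- data[[x]][keep]; yv <- data[[y]][keep]
  if (length(xv) < 3) stop("at least 3 birds with both variables are required")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in `", if (stats::sd(xv) == 0) x else y, "`")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  fit <- stats::lm(yv ~ xv)
  .comparison_result("Pearson correlation", ct$statistic, ct$parameter, ct$p.value,
                     NULL,
                     extra = list(r = unname(ct$estimate),
                                  r_squared = unname(ct$estimate)^2,
                                  slope = unname(stats::coef(fit)[2]),
                                  intercept = unname(stats::coef(fit)[1]),
                                  slope_se = summary(fit)$coefficients[2, 2]))
}

#' Smooth time-of-day trend of a per-bird metric
#'
#' Locally weighted (tricube) local-linear regression of the metric on
#' tagging hour — the standard loess smooth — evaluated with a pointwise
#' ~95% band (fit +/- 1.96 standard errors) on a fixed hour grid.
#'
#' @param summaries data frame with `tag_hour` and the metric column;
#'   at least 8 birds.
#' @param metric metric column name (default `"r_flight"`).
#' @param span loess span (default 0.75).
#' @param grid evaluation grid in hours (default 25 points over the data
#'   range).
#' @return list with `hour`, `fit`, `se`, `lower`, `upper` and the loess
#'   `model`.
#' @export
time_of_day_trend <- function(summaries, metric = "r_flight", span = 0.75,
                              grid = NULL) {
  if (!metric %in% names(summaries)) stop("no column `", metric, "`")
  h <- summaries$tag_hour
  y <- summaries[[metric]]
  if (length(h) < 8) stop("at least 8 birds are required")
  if (stats::sd(h) == 0) stop("all tagging times are identical")
  if (is.null(grid)) grid <- seq(min(h), max(h), length.out = 25)
  model <- stats::loess(y ~ h, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(model, newdata = data.frame(h = grid), se = TRUE)
  list(hour = grid, fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
       lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
       upper = as.numeric(pr$fit + 1.96 * pr$se.fit),
       model = model)
}
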