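#' Split a trace into fixed-length classification windows
#'
#' Consecutive, non-overlapping, half-open windows of `window_samples`
#' samples; a trailing partial window is dropped. The default of 16 samples
#' gives ~0.7 s windows at 23 Hz — long enough to span ~14 wingbeat cycles
#' of a 20 Hz flapper, short enough that most windows hold one behaviour.
#'
#' @param trace an `accel_trace`, or an integer sample count.
#' @param window_samples window length in samples (>= 2).
#' @return data frame with 1-based inclusive sample index columns
#'   `start`, `end`; zero rows if the trace is shorter than one window.
#' @export
make_windows <- function(trace, window_samples = 16) {
  n <- if (inherits(trace, "accel_trace")) n_samples(trace) else as.integer(trace)
  w <- window_samples
  if (w != round(w) || w < 2) stop("`window_samples` must be an integer >= 2")
  k <- floor(n / w)
  data.frame(start = (seq_len(k) - 1L) * w + 1L, end = seq_len(k) * w)[seq_len(k), ]
}

#' Majority ground-truth label per window
#'
#' Collapses per-sample truth labels to one label per complete window (the
#' most frequent label; ties go to the label occurring first in the window).
#'
#' @param labels character vector of per-sample labels.
#' @param window_samples window length in samples.
#' @return character vector, one label per complete window.
#' @export
window_majority_labels <- function(labels, window_samples = 16) {
  k <- floor(length(labels) / window_samples)
  vapply(seq_len(k), function(i) {
    win <- labels[((i - 1) * window_samples + 1):(i * window_samples)]
    tab <- table(factor(win, levels = unique(win)))  # unique() preserves first-seen order
    names(tab)[which.max(tab)]
  }, character(1))
}

# central moments with the documented degenerate conventions:
# sd == 0 -> skewness 0 and excess kurtosis 0
.skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}
.kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}
.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Extract per-window classification features
#'
#' For every window: per axis mean, standard deviation, min, max, skewness
#' and excess kurtosis; the three pairwise axis correlations; mean and max
#' of a window-local VeDBA (5-sample running mean); and the dominant
#' frequency bin of the z-axis discrete Fourier spectrum (excluding DC) with
#' its power. Degenerate (constant) windows get correlations, skewness and
#' kurtosis of 0 and VeDBA features of 0. Deterministic given the trace.
#'
#' @param trace an `accel_trace`.
#' @param windows window index frame from [make_windows()] on this trace;
#'   built with `window_samples` if omitted.
#' @param window_samples window length used when `windows` is `NULL`.
#' @param labels optional per-sample truth labels; when given, a `class`
#'   column with the window-majority label is appended.
#' @return data frame of named numeric features, one row per window.
#' @export
extract_features <- function(trace, windows = NULL, window_samples = 16,
                             labels = NULL) {
  stopifnot(inherits(trace, "accel_trace"))
  if (is.null(windows)) windows <- make_windows(trace, window_samples)
  k <- nrow(windows)
  rate <- trace$sample_rate
  axes <- c("ax", "ay", "az")
  feat <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- windows$start[i]:windows$end[i]
    s <- trace$samples[idx, , drop = FALSE]
    row <- numeric(0)
    for (a in axes) {
      x <- s[, a]
      row <- c(row, mean(x), stats::sd(x), min(x), max(x), .skewness(x), .kurtosis(x))
    }
    names(row) <- as.vector(outer(c("mean", "sd", "min", "max", "skew", "kurt"),
                                  axes, function(f, a) paste(a, f, sep = "_")))
    row <- c(row,
             corr_xy = .safe_cor(s[, 1], s[, 2]),
             corr_xz = .safe_cor(s[, 1], s[, 3]),
             corr_yz = .safe_cor(s[, 2], s[, 3]))
    wtr <- accel_trace(s[, 1], s[, 2], s[, 3], rate)
    v <- vedba(wtr, min(5, length(idx) - (1 - length(idx) %% 2)))$values
    row <- c(row, vedba_mean = mean(v), vedba_max = max(v))
    # dominant non-DC bin of the z-axis spectrum
    z <- s[, 3] - mean(s[, 3])
    nw <- length(z)
    if (nw >= 4 && any(z != 0)) {
      p <- Mod(stats::fft(z))^2
      half <- 2:(floor(nw / 2) + 1)
      j <- half[which.max(p[half])]
      row <- c(row, zfreq_hz = (j - 1) * rate / nw, zfreq_power = p[j] / nw)
    } else {
      row <- c(row, zfreq_hz = 0, zfreq_power = 0)
    }
    feat[[i]] <- row
  }
  out <- as.data.frame(do.call(rbind, feat))
  if (!is.null(labels)) {
    wl <- window_majority_labels(labels, windows$end[1] - windows$start[1] + 1L)
    out$class <- wl[seq_len(k)]
  }
  out
}

#' Train a gradient-boosted behaviour classifier
#'
#' Fits an XGBoost multi-class model on a feature table with a true `class`
#' column. Class imbalance (flight and perching dominate; maintenance
#' behaviours are rare) is handled with per-row weights inversely
#' proportional to class frequency. Defaults: 200 trees, depth 4, learning
#' rate 0.1, single thread, fixed seed — small, fast, reproducible.
#'
#' @param features data frame from [extract_features()] including `class`.
#' @param hyperparams optional overrides: `nrounds`, `max_depth`, `eta`.
#' @param seed integer seed for the boosting RNG.
#' @return a `behavior_classifier`: list with the fitted booster, the class
#'   levels, the feature names and the hyperparameters used.
#' @export
train_classifier <- function(features, hyperparams = list(), seed = 1) {
  if (is.null(features$class)) stop("`features` must contain a `class` column")
  classes <- sort(unique(features$class))
  if (length(classes) < 2) stop("training needs at least 2 classes")
  tab <- table(features$class)
  if (any(tab < 10))
    stop("every present class needs >= 10 rows; short: ",
         paste(names(tab)[tab < 10], collapse = ", "))
  feat_names <- setdiff(names(features), "class")
  X <- as.matrix(features[, feat_names, drop = FALSE])
  y <- match(features$class, classes) - 1L
  wt <- as.numeric(length(y) / (length(classes) * tab[features$class]))
  hp <- utils::modifyList(list(nrounds = 200, max_depth = 4, eta = 0.1), hyperparams)
  set.seed(seed)
  dm <- xgboost::xgb.DMatrix(X, label = y, weight = wt, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  max_depth = hp$max_depth, eta = hp$eta, nthread = 1,
                  seed = as.integer(seed)),
    data = dm, nrounds = hp$nrounds, verbose = 0)
  structure(list(booster = booster, classes = classes,
                 feature_names = feat_names, hyperparams = hp),
            class = "behavior_classifier")
}

#' Predict window behaviours
#'
#' @param model a `behavior_classifier`.
#' @param features feature table with the columns the model was trained on.
#' @return character vector of predicted classes, one per row (window).
#' @export
predict_behaviors <- function(model, features) {
  stopifnot(inherits(model, "behavior_classifier"))
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols) > 0)
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
  model$classes[max.col(p, ties.method = "first")]
}

#' Save / load a behaviour classifier
#'
#' The booster is written in XGBoost's native serialized format; class
#' levels, feature names and hyperparameters go to a JSON sidecar
#' (`<path>.meta.json`). A reloaded model yields identical predictions.
#'
#' @param model a `behavior_classifier`.
#' @param path file path for the booster (e.g. `model.ubj` or `model.json`).
#' @return `path` (save) or the reloaded `behavior_classifier` (load).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "behavior_classifier"))
  xgboost::xgb.save(model$booster, path)
  meta <- list(classes = model$classes, feature_names = model$feature_names,
               hyperparams = model$hyperparams)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  booster <- xgboost::xgb.load(path)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  structure(list(booster = booster, classes = meta$classes,
                 feature_names = meta$feature_names,
                 hyperparams = as.list(meta$hyperparams)),
            class = "behavior_classifier")
}

#' Confusion matrix with per-class precision and recall
#'
#' @param true,predicted equal-length class label vectors.
#' @return a `confusion_matrix`: list with `counts` (true classes in rows,
#'   predictions in columns), and per-class `recall_pct` and `precision_pct`
#'   (percentages; `NaN` where a class was never true / never predicted).
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop("`true` and `predicted` must have equal length")
  lev <- sort(unique(c(true, predicted)))
  counts <- table(true = factor(true, lev), predicted = factor(predicted, lev))
  counts <- unclass(counts)
  recall <- 100 * diag(counts) / rowSums(counts)
  precision <- 100 * diag(counts) / colSums(counts)
  structure(list(counts = counts, recall_pct = recall, precision_pct = precision),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>\n")
  print(x$counts)
  cat("\nrecall (%):\n"); print(round(x$recall_pct, 2))
  cat("precision (%):\n"); print(round(x$precision_pct, 2))
  invisible(x)
}
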