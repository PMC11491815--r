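#' Collapse behaviour labels to flying / non-flying
#'
#' @param labels nonempty character vector of window labels.
#' @param flying_class the label counted as flight (default `"flying"`).
#' @param known_classes the admissible label set; anything else errors.
#' @return character vector over `"F"` / `"N"`, same length as `labels`.
#' @export
binarize_labels <- function(labels, flying_class = "flying",
                            known_classes = c("flying", "inactive", "food_shaking",
                                              "preening", "swallowing", "bill_wiping")) {
  if (length(labels) == 0) stop("`labels` must be nonempty")
  bad <- setdiff(unique(labels), known_classes)
  if (length(bad) > 0)
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  ifelse(labels == flying_class, "F", "N")
}

#' Fill single non-flying windows between two flying ones
#'
#' Every `N` whose neighbours in the *original* sequence are both `F`
#' becomes `F` (a one-window pause inside a flight bout is part of the same
#' continuous flight). The rule is applied in a single pass conditioned on
#' the input, so in `F,N,F,N,F` both single gaps flip; runs of two or more
#' `N` are untouched, and a leading or trailing `N` is never filled. The
#' operation never decreases the `F` count and is idempotent.
#'
#' @param x character vector over `"F"` / `"N"`.
#' @return the filled sequence.
#' @export
fill_single_gaps <- function(x) {
  if (!all(x %in% c("F", "N"))) stop("sequence must be over {F, N}")
  n <- length(x)
  if (n < 3) return(x)
  mid <- 2:(n - 1)
  flip <- x[mid] == "N" & x[mid - 1] == "F" & x[mid + 1] == "F"
  x[mid][flip] <- "F"
  x
}

#' Segment a binary flight sequence into flight bouts
#'
#' Maximal runs of `F` become segments with
#' `start = first_window_index * window_duration` (0-based) and
#' `duration = run_length * window_duration`.
#'
#' @param x character vector over `"F"` / `"N"` (typically gap-filled).
#' @param window_duration duration of one window in seconds (> 0), e.g.
#'   `16 / 23` for 16-sample windows at 23 Hz.
#' @return data frame of disjoint, sorted segments with columns `start_s`,
#'   `duration_s` (and `vedba_mean_g`, initialised `NA`, filled by the
#'   metrics layer); zero rows when there is no `F`.
#' @export
segment_flights <- function(x, window_duration) {
  if (!all(x %in% c("F", "N"))) stop("sequence must be over {F, N}")
  if (window_duration <= 0) stop("`window_duration` must be positive")
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based first window index of each run
  f <- r$values == "F"
  data.frame(start_s = starts[f] * window_duration,
             duration_s = r$lengths[f] * window_duration,
             vedba_mean_g = rep(NA_real_, sum(f)))
}

#' Rebuild a binary sequence from flight segments
#'
#' Inverse of [segment_flights()]: given the segments, the window duration
#' and the total number of windows, reconstructs the `"F"`/`"N"` sequence.
#'
#' @param segments data frame with `start_s` and `duration_s`.
#' @param window_duration window duration in seconds.
#' @param n_windows total sequence length in windows.
#' @return character vector over `"F"` / `"N"`.
#' @export
binary_from_segments <- function(segments, window_duration, n_windows) {
  x <- rep("N", n_windows)
  for (i in seq_len(nrow(segments))) {
    w0 <- round(segments$start_s[i] / window_duration)
    k <- round(segments$duration_s[i] / window_duration)
    x[(w0 + 1):(w0 + k)] <- "F"
  }
  x
}
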