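#' Construct a tri-axial acceleration trace
#'
#' A trace holds a fixed-rate tri-axial acceleration time series in g-units
#' (1 g = 9.81 m s^-2), with the x-axis lateral, the y-axis longitudinal and
#' the z-axis vertical, plus optional sensor metadata describing the
#' quantization grid the values live on. Timestamps are implicit:
#' sample i (1-based in R) occurs at (i - 1) / sample_rate seconds.
#'
#' @param ax,ay,az numeric vectors of equal length, accelerations in g.
#' @param sample_rate sampling frequency in Hz (> 0).
#' @param sensor_range half-range of the sensor in g (e.g. 8 for a +/-8 g
#'   device), or `NA` if the trace is not quantized.
#' @param sensor_bits output resolution in bits, or `NA`.
#' @return An object of class `accel_trace`: a list with elements `samples`
#'   (an n x 3 matrix with columns `ax`, `ay`, `az`), `sample_rate`,
#'   `sensor_range` and `sensor_bits`.
#' @examples
#' tr <- accel_trace(ax = rnorm(46, 0, 0.05), ay = rnorm(46, 0, 0.05),
#'                   az = 1 + rnorm(46, 0, 0.05), sample_rate = 23)
#' tr
#' @export
accel_trace <- function(ax, ay, az, sample_rate,
                        sensor_range = NA_real_, sensor_bits = NA_integer_) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  n <- length(ax)
  if (length(ay) != n || length(az) != n)
    stop("`ax`, `ay`, `az` must have equal length")
  samples <- cbind(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az))
  if (n > 0 && !all(is.finite(samples)))
    stop("acceleration values must all be finite")
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         sensor_range = as.numeric(sensor_range),
         sensor_bits = as.integer(sensor_bits)),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<accel_trace> %d samples at %g Hz (%.1f s)", n,
              x$sample_rate, n / x$sample_rate))
  if (is.finite(x$sensor_range))
    cat(sprintf(", quantized +/-%g g / %d bit", x$sensor_range, x$sensor_bits))
  cat("\n")
  invisible(x)
}

#' Number of samples in a trace
#' @param trace an `accel_trace`.
#' @return integer sample count.
#' @export
n_samples <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  nrow(trace$samples)
}

#' Sample timestamps of a trace
#'
#' @param trace an `accel_trace`.
#' @return numeric vector of timestamps in seconds, `(i - 1) / sample_rate`.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  (seq_len(nrow(trace$samples)) - 1) / trace$sample_rate
}

#' @export
as.data.frame.accel_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x),
             ax_g = x$samples[, "ax"],
             ay_g = x$samples[, "ay"],
             az_g = x$samples[, "az"])
}

#' Write a trace (and optional labels) to CSV
#'
#' The dialect is `time_s,ax_g,ay_g,az_g[,label]` with a decimal point,
#' comma separator, UTF-8 and LF newlines. Values are serialized with enough
#' precision that quantized sensor levels round-trip exactly.
#'
#' @param trace an `accel_trace`.
#' @param path output file path.
#' @param labels optional character vector of per-sample behaviour labels
#'   (same length as the trace), e.g. `truth$labels` from [generate_trace()].
#' @return `path`, invisibly.
#' @seealso [read_trace_csv()]
#' @export
write_trace_csv <- function(trace, path, labels = NULL) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- as.data.frame(trace)
  # full double precision so that read . write is the identity on samples
  for (col in c("time_s", "ax_g", "ay_g", "az_g"))
    df[[col]] <- formatC(df[[col]], format = "g", digits = 17)
  if (!is.null(labels)) {
    if (length(labels) != n_samples(trace))
      stop("`labels` must have one entry per sample")
    df$label <- as.character(labels)
  }
  con <- file(path, open = "wb")  # binary mode forces LF newlines
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path input file path.
#' @param sensor_range,sensor_bits optional sensor metadata to attach.
#' @return a list with elements `trace` (an `accel_trace`) and `labels`
#'   (character vector, or `NULL` if the file has no label column).
#' @export
read_trace_csv <- function(path, sensor_range = NA_real_, sensor_bits = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  if (nrow(raw) == 0L)
    stop("parse error in ", path, ": no data rows (empty file is not an empty trace)")
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  num <- lapply(raw[need], function(col) suppressWarnings(as.numeric(col)))
  for (col in need) {
    bad <- which(is.na(num[[col]]))
    if (length(bad) > 0)
      stop(sprintf("parse error in %s: non-numeric value in column %s at line %d",
                   path, col, bad[1] + 1L))  # +1 for the header line
  }
  t <- num$time_s
  n <- length(t)
  rate <- if (n >= 2) (n - 1) / (t[n] - t[1]) else 1
  trace <- accel_trace(num$ax_g, num$ay_g, num$az_g, sample_rate = rate,
                       sensor_range = sensor_range, sensor_bits = sensor_bits)
  labels <- if ("label" %in% names(raw)) raw$label else NULL
  list(trace = trace, labels = labels)
}
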