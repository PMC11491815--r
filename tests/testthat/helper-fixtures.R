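# small fixtures shared across test files; everything is built in code

# a short field-style config (23 Hz) with a fixed seed
quick_config <- function(duration = 120, seed = 101, ...) {
  synthetic_config(sample_rate = 23, session_duration = duration, seed = seed, ...)
}

# a trace of pure sensor noise around perching (for degenerate-path tests)
constant_trace <- function(n = 50, rate = 23, ax = 0, ay = 0, az = 1) {
  accel_trace(rep(ax, n), rep(ay, n), rep(az, n), rate)
}

# brute-force single-gap fill: literal per-position scan of the original
# sequence (oracle for fill_single_gaps)
brute_fill <- function(x) {
  out <- x
  if (length(x) >= 3) {
    for (i in 2:(length(x) - 1)) {
      if (x[i] == "N" && x[i - 1] == "F" && x[i + 1] == "F") out[i] <- "F"
    }
  }
  out
}

# brute-force run enumeration (oracle for segment_flights)
brute_segments <- function(x, wdur) {
  starts <- c(); lens <- c()
  i <- 1
  while (i <= length(x)) {
    if (x[i] == "F") {
      j <- i
      while (j < length(x) && x[j + 1] == "F") j <- j + 1
      starts <- c(starts, i - 1); lens <- c(lens, j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  data.frame(start_s = starts * wdur, duration_s = lens * wdur)
}

# synthetic per-bird summary table for the statistics layer
make_summaries <- function(n_per_sex = 13, seed = 1, shift_male = 0) {
  set.seed(seed)
  data.frame(
    bird_id = sprintf("b%02d", seq_len(2 * n_per_sex)),
    sex = rep(c("female", "male"), each = n_per_sex),
    brood_size = sample(4:7, 2 * n_per_sex, replace = TRUE),
    tag_hour = runif(2 * n_per_sex, 5, 20),
    r_flight = pmin(pmax(c(rnorm(n_per_sex, 0.13, 0.06),
                           rnorm(n_per_sex, 0.13 + shift_male, 0.06)), 0.01), 0.9),
    vedba_mean_bird_g = rnorm(2 * n_per_sex, 0.77, 0.06)
  )
}
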