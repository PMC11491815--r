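#' Behaviour signal model
#'
#' Describes how one behaviour class moves the logger: a dominant body
#' oscillation (e.g. the wingbeat) at `carrier_frequency` on the vertical
#' axis, with amplitude `amplitude`, white measurement/posture noise, a
#' gravitational bias on the z-axis, and a law for bout durations.
#'
#' @param name one of `"flying"`, `"inactive"`, `"food_shaking"`,
#'   `"preening"`, `"swallowing"`, `"bill_wiping"`.
#' @param carrier_frequency oscillation frequency in Hz (>= 0; 0 = no
#'   oscillation).
#' @param amplitude oscillation amplitude in g (>= 0). For `"flying"` this is
#'   a nominal value: the generator rescales each bout so its measured mean
#'   VeDBA follows the configured effort law.
#' @param amplitude_noise_sd per-axis white noise s.d. in g (>= 0).
#' @param gravity_axis_bias gravitational component on the z-axis in g
#'   (1 for an upright bird).
#' @param duration_law bout-duration distribution: a list with element `dist`
#'   equal to `"lognormal"` (`meanlog`, `sdlog`, optional `max`),
#'   `"exponential"` (`mean`) or `"fixed"` (`value`). Durations are strictly
#'   positive.
#' @return a `behavior_model` list.
#' @export
behavior_model <- function(name, carrier_frequency, amplitude, amplitude_noise_sd,
                           gravity_axis_bias = 1,
                           duration_law = list(dist = "exponential", mean = 5)) {
  classes <- c("flying", "inactive", "food_shaking", "preening",
               "swallowing", "bill_wiping")
  name <- match.arg(name, classes)
  if (carrier_frequency < 0) stop("`carrier_frequency` must be >= 0")
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (amplitude_noise_sd < 0) stop("`amplitude_noise_sd` must be >= 0")
  .law_mean(duration_law)  # validates
  structure(list(name = name, carrier_frequency = carrier_frequency,
                 amplitude = amplitude, amplitude_noise_sd = amplitude_noise_sd,
                 gravity_axis_bias = gravity_axis_bias,
                 duration_law = duration_law),
            class = "behavior_model")
}

# mean of a duration law (lognormal laws truncated at `max` via the
# conditional expectation of the truncated lognormal)
.law_mean <- function(law) {
  if (!is.list(law) || is.null(law$dist)) stop("invalid duration law")
  switch(law$dist,
    lognormal = {
      if (is.null(law$meanlog) || is.null(law$sdlog) || law$sdlog < 0)
        stop("invalid lognormal duration law")
      mu <- law$meanlog; s <- law$sdlog
      if (is.null(law$max)) return(exp(mu + s^2 / 2))
      if (law$max <= 0) stop("invalid truncation bound")
      if (s == 0) return(min(exp(mu), law$max))
      z <- (log(law$max) - mu) / s
      exp(mu + s^2 / 2) * stats::pnorm(z - s) / stats::pnorm(z)
    },
    exponential = {
      if (is.null(law$mean) || law$mean <= 0) stop("invalid exponential duration law")
      law$mean
    },
    fixed = {
      if (is.null(law$value) || law$value <= 0) stop("invalid fixed duration law")
      law$value
    },
    stop("unknown duration law: ", law$dist)
  )
}

# sample n strictly positive durations from a law (inverse-CDF truncation
# for bounded lognormals, so no rejection loop is needed)
.sample_durations <- function(law, n) {
  switch(law$dist,
    lognormal = {
      if (is.null(law$max)) {
        stats::rlnorm(n, law$meanlog, law$sdlog)
      } else if (law$sdlog == 0) {
        rep(min(exp(law$meanlog), law$max), n)
      } else {
        u <- stats::runif(n, 0, stats::plnorm(law$max, law$meanlog, law$sdlog))
        stats::qlnorm(u, law$meanlog, law$sdlog)
      }
    },
    exponential = stats::rexp(n, rate = 1 / law$mean),
    fixed = rep(law$value, n)
  )
}

#' Default behaviour models for a small flycatcher-like songbird
#'
#' Six classes: flying (20 Hz wingbeat carrier), inactive (perching: gravity
#' plus sensor noise), and four maintenance behaviours (food shaking,
#' preening, swallowing, bill wiping) distinguished by carrier-frequency and
#' amplitude tiers. Flight bout durations are log-normal with median 1.9 s
#' and log-s.d. 0.68, truncated at 60 s, so that the mean bout is ~2.4 s and
#' ~99.3% of bouts are shorter than 10 s.
#'
#' @return named list of six [behavior_model()] objects.
#' @export
default_behavior_models <- function() {
  list(
    flying = behavior_model("flying", carrier_frequency = 20, amplitude = 1,
      amplitude_noise_sd = 0.05, gravity_axis_bias = 1,
      duration_law = list(dist = "lognormal", meanlog = log(1.9), sdlog = 0.68, max = 60)),
    inactive = behavior_model("inactive", carrier_frequency = 0, amplitude = 0,
      amplitude_noise_sd = 0.02, gravity_axis_bias = 1,
      duration_law = list(dist = "lognormal", meanlog = log(15), sdlog = 0.7, max = 300)),
    food_shaking = behavior_model("food_shaking", carrier_frequency = 8, amplitude = 0.5,
      amplitude_noise_sd = 0.05, gravity_axis_bias = 1,
      duration_law = list(dist = "lognormal", meanlog = log(1.6), sdlog = 0.5, max = 20)),
    preening = behavior_model("preening", carrier_frequency = 3, amplitude = 0.25,
      amplitude_noise_sd = 0.05, gravity_axis_bias = 1,
      duration_law = list(dist = "lognormal", meanlog = log(6), sdlog = 0.6, max = 60)),
    swallowing = behavior_model("swallowing", carrier_frequency = 5, amplitude = 0.35,
      amplitude_noise_sd = 0.05, gravity_axis_bias = 1,
      duration_law = list(dist = "lognormal", meanlog = log(1.2), sdlog = 0.5, max = 20)),
    bill_wiping = behavior_model("bill_wiping", carrier_frequency = 11, amplitude = 0.45,
      amplitude_noise_sd = 0.05, gravity_axis_bias = 1,
      duration_law = list(dist = "lognormal", meanlog = log(1.2), sdlog = 0.5, max = 20))
  )
}

#' Configuration for the synthetic trace generator
#'
#' The defaults emulate the field deployment the analysis assumes: a 23 Hz,
#' +/-8 g, 8-bit logger recording ~2 h of a chick-rearing songbird whose
#' time budget is ~14% flight, whose flight bouts average ~2.4 s with >99%
#' under 10 s, and whose per-bout mean VeDBA is highly variable for short
#' bouts but converges to ~0.76 g for long (bounding) flights.
#'
#' @param sample_rate sampling frequency in Hz (23 field, 100 aviary).
#' @param session_duration recording length in seconds.
#' @param behavior_models named list of [behavior_model()]s.
#' @param behavior_weights nonnegative bout-transition weights, one per
#'   model; each new bout's class is drawn from these weights, so the
#'   stationary time fraction of class i is
#'   `w_i * E[dur_i] / sum(w_j * E[dur_j])` (see [stationary_fractions()]).
#' @param flight_style_mix probability that a flight bout is bounding
#'   (flap bursts alternating with folded-wing ballistic pauses) rather than
#'   continuous flapping.
#' @param bounding_pause_fraction fraction of a bounding bout spent in the
#'   ballistic pause, during which total acceleration approaches 0 g.
#' @param target_long_flight_vedba asymptotic per-bout mean VeDBA for long
#'   flights, in g.
#' @param short_flight_vedba_sd spread (in g, at zero duration) of per-bout
#'   mean VeDBA around the target; decays with bout duration so long bouts
#'   converge to the target.
#' @param quantize_output quantize the trace onto the sensor grid (default TRUE).
#' @param sensor_range,sensor_bits sensor grid (default +/-8 g, 8 bit).
#' @param seed integer root seed; all generator streams derive from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(sample_rate = 23, session_duration = 7200,
                             behavior_models = default_behavior_models(),
                             behavior_weights = c(flying = 3.2, inactive = 1.2,
                                                  food_shaking = 0.5, preening = 0.25,
                                                  swallowing = 0.4, bill_wiping = 0.3),
                             flight_style_mix = 0.3,
                             bounding_pause_fraction = 0.2,
                             target_long_flight_vedba = 0.76,
                             short_flight_vedba_sd = 0.35,
                             quantize_output = TRUE,
                             sensor_range = 8, sensor_bits = 8,
                             seed = 1) {
  if (sample_rate <= 0) stop("invalid config: `sample_rate` must be positive")
  if (session_duration <= 0) stop("invalid config: `session_duration` must be positive")
  if (length(behavior_models) < 1) stop("invalid config: no behaviour models")
  nm <- vapply(behavior_models, function(m) m$name, character(1))
  names(behavior_models) <- nm
  behavior_weights <- behavior_weights[nm]
  if (any(is.na(behavior_weights)) || any(behavior_weights < 0))
    stop("invalid config: `behavior_weights` must be nonnegative, one per model")
  if (sum(behavior_weights) <= 0) stop("invalid config: transition weights must sum > 0")
  for (f in c(flight_style_mix, bounding_pause_fraction))
    if (f < 0 || f > 1) stop("invalid config: fractions must lie in [0, 1]")
  if (target_long_flight_vedba <= 0) stop("invalid config: target VeDBA must be positive")
  if (short_flight_vedba_sd < 0) stop("invalid config: `short_flight_vedba_sd` must be >= 0")
  structure(list(sample_rate = sample_rate, session_duration = session_duration,
                 behavior_models = behavior_models,
                 behavior_weights = behavior_weights,
                 flight_style_mix = flight_style_mix,
                 bounding_pause_fraction = bounding_pause_fraction,
                 target_long_flight_vedba = target_long_flight_vedba,
                 short_flight_vedba_sd = short_flight_vedba_sd,
                 quantize_output = quantize_output,
                 sensor_range = sensor_range, sensor_bits = sensor_bits,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Stationary time fractions of the behaviour mixture
#'
#' The bout chain draws the next class from the weights of the other classes
#' (no self-transitions), a reversible chain with stationary visit
#' distribution `pi_i` proportional to `w_i * (W - w_i)` where `W = sum(w)`.
#' The long-run fraction of *time* in class i is therefore
#' `pi_i * E[dur_i] / sum_j pi_j * E[dur_j]`.
#'
#' @param config a `synthetic_config`.
#' @return named numeric vector of time fractions summing to 1.
#' @export
stationary_fractions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  means <- vapply(config$behavior_models, function(m) .law_mean(m$duration_law),
                  numeric(1))
  w <- config$behavior_weights
  visit <- if (length(w) > 1) w * (sum(w) - w) else w
  if (sum(visit) == 0) visit <- w  # degenerate single-class mix
  x <- visit * means
  x / sum(x)
}

#' Sample flight-bout durations from the configured law
#'
#' @param n number of bouts.
#' @param config a `synthetic_config` (uses its `flying` duration law).
#' @param seed integer seed.
#' @return numeric vector of strictly positive durations in seconds.
#' @export
sample_flight_durations <- function(n, config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$behavior_models$flying)) stop("config has no flying model")
  set.seed(seed)
  .sample_durations(config$behavior_models$flying$duration_law, n)
}

#' Sample per-bout mean flight efforts (the generator's effort law)
#'
#' Per-bout mean VeDBA is log-normal around `target_long_flight_vedba` with
#' a log-scale spread that decays exponentially with bout duration
#' (time constant 5 s), so short bouts are highly variable (ascents, rapid
#' manoeuvres, descents) while long bouts converge to the target. The mean
#' of the law equals the target at every duration.
#'
#' @param durations bout durations in seconds (> 0).
#' @param config a `synthetic_config`.
#' @param seed integer seed.
#' @return per-bout mean VeDBA values in g.
#' @export
sample_bout_efforts <- function(durations, config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(durations <= 0)) stop("durations must be positive")
  set.seed(seed)
  .draw_efforts(durations, config)
}

.effort_sdlog <- function(durations, config) {
  (config$short_flight_vedba_sd / config$target_long_flight_vedba) *
    exp(-durations / 5)
}

.draw_efforts <- function(durations, config) {
  s <- .effort_sdlog(durations, config)
  config$target_long_flight_vedba * exp(stats::rnorm(length(durations), 0, s) - s^2 / 2)
}

# unit flapping waveform: wingbeat fundamental plus a phase-locked
# half-amplitude first harmonic (phase phi shifts the whole waveform in
# time, so the sampled shape — and hence the bout-mean VeDBA — does not
# depend on it)
.flap_wave <- function(t, carrier, phi = 0) {
  sin(2 * pi * carrier * t + phi) + 0.5 * sin(2 * pi * 2 * carrier * t + 2 * phi)
}

# Numeric gain of the unit flapping waveform through the VeDBA pipeline at a
# given rate: the mean VeDBA produced by unit flap amplitude in continuous
# flapping. Used to scale flap amplitude so a bout's measured mean VeDBA
# matches its drawn effort. Computed from the package's own transforms, so
# generator and pipeline stay consistent by construction.
.flap_gain <- function(rate, carrier = 20, window = 5) {
  n <- max(4L * window, round(20 * rate))
  t <- (seq_len(n) - 1) / rate
  tr <- accel_trace(rep(0, n), rep(0, n), .flap_wave(t, carrier), rate)
  v <- vedba(tr, window)$values
  mean(v[(window + 1):(n - window)])
}

# Secant calibration for bounding bouts. The flap/pause gravity transitions
# add a VeDBA contribution that does not scale with flap amplitude, so the
# bout-mean VeDBA is affine in the amplitude over the working range:
# V(amp) ~= V1 + s * (amp - 1). Evaluated on a long noise-free bounding bout
# at amplitudes 1 and 2; invert for the amplitude that delivers a target
# bout-mean effort.
.bounding_calib <- function(rate, carrier, window, pfrac, cycle) {
  n <- round(35 * rate)
  t <- (seq_len(n) - 1) / rate
  in_pause <- (t %% cycle) >= cycle * (1 - pfrac)
  V <- vapply(c(1, 2), function(amp) {
    z <- amp * .flap_wave(t, carrier) + 1
    z[in_pause] <- 0
    v <- vedba(accel_trace(rep(0, n), rep(0, n), z, rate), window)$values
    mean(v[(window + 1):(n - window)])
  }, numeric(1))
  list(V1 = V[1], slope = V[2] - V[1])
}

#' Generate a labelled synthetic accelerometer trace
#'
#' Simulates a songbird wearing a miniature logger. Behaviour bouts are drawn
#' from the transition weights, bout durations from each behaviour's duration
#' law, and each bout is rendered as a z-axis oscillation (wingbeat carrier
#' plus half-amplitude first harmonic for flight) on top of gravity and
#' white noise, evaluated in continuous time at the requested sampling rate
#' (so a 20 Hz wingbeat aliases at 23 or 25 Hz exactly as a physical sensor
#' would alias it). Bounding flight bouts alternate flap bursts with
#' ballistic pauses during which the acceleration vector magnitude stays
#' below 0.2 g. Per-bout flap amplitude is calibrated so the bout's measured
#' mean VeDBA follows the configured effort law. The output is quantized
#' onto the sensor grid unless `quantize_output` is FALSE.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `trace` (an [accel_trace()]) and `truth`, a
#'   `ground_truth` list carrying `labels` (per-sample behaviour class),
#'   `flight_intervals` (data frame `start_s`, `end_s`, `duration_s` of true
#'   flight bouts) and `pause` (logical, TRUE for ballistic-pause samples).
#'   Identical config + seed reproduces the output bit for bit.
#' @examples
#' out <- generate_trace(synthetic_config(session_duration = 60, seed = 7))
#' table(out$truth$labels)
#' @export
generate_trace <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  rate <- config$sample_rate
  dur <- config$session_duration
  n <- round(rate * dur)
  if (n < 1) stop("invalid config: session too short for one sample")
  models <- config$behavior_models
  nm <- names(models)
  w <- config$behavior_weights

  # --- bout schedule (stream 1) -------------------------------------------
  # first-order Markov chain without self-transitions: the next bout's class
  # is drawn from the weights of the *other* classes, so two bouts of the
  # same behaviour never abut and the realized bout durations follow each
  # class's duration law. (If only one class has positive weight, it simply
  # continues.) Stationary visit law: pi_i proportional to w_i * (W - w_i).
  set.seed(config$seed + 1L)
  cap <- ceiling(dur / 0.2) + 64L  # generous bout capacity
  beh <- character(cap); lens <- numeric(cap)
  total <- 0; nb <- 0L; cur <- NA_character_
  while (total < dur) {
    wnext <- w
    if (!is.na(cur)) wnext[cur] <- 0
    if (sum(wnext) == 0) wnext <- w  # degenerate single-class mix
    cur <- sample(nm, 1L, prob = wnext)
    nb <- nb + 1L
    beh[nb] <- cur
    lens[nb] <- .sample_durations(models[[cur]]$duration_law, 1L)
    total <- total + lens[nb]
  }
  beh <- beh[seq_len(nb)]; lens <- lens[seq_len(nb)]
  starts <- cumsum(c(0, lens[-nb]))
  ends <- pmin(starts + lens, dur)

  # --- per-sample synthesis (stream 2) ------------------------------------
  set.seed(config$seed + 2L)
  t <- (seq_len(n) - 1) / rate
  bout_of <- findInterval(t, starts)
  labels <- beh[bout_of]
  ax <- stats::rnorm(n); ay <- stats::rnorm(n); az <- stats::rnorm(n)  # unit noise, scaled per bout
  zsig <- numeric(n)
  grav <- numeric(n)
  noise_sd <- numeric(n)
  pause <- logical(n)
  pfrac <- config$bounding_pause_fraction
  cycle <- 0.7  # s, flap-pause cycle of bounding flight
  fcarrier <- if (!is.null(models$flying)) models$flying$carrier_frequency else 20
  gain <- .flap_gain(rate, carrier = fcarrier)
  bcal <- if (pfrac > 0) .bounding_calib(rate, fcarrier, 5, pfrac, cycle) else NULL

  for (b in seq_along(starts)) {
    i <- which(bout_of == b)
    if (length(i) == 0) next
    m <- models[[beh[b]]]
    tl <- t[i] - starts[b]
    grav[i] <- m$gravity_axis_bias
    noise_sd[i] <- m$amplitude_noise_sd
    if (m$name == "flying") {
      bounding <- stats::runif(1) < config$flight_style_mix
      eff <- .draw_efforts(ends[b] - starts[b], config)
      phi <- stats::runif(1, 0, 2 * pi)
      if (bounding && pfrac > 0) {
        amp <- max(1 + (eff - bcal$V1) / bcal$slope, 0.05)
        in_pause <- (tl %% cycle) >= cycle * (1 - pfrac)
        flap <- i[!in_pause]; pz <- i[in_pause]
        zsig[flap] <- amp * .flap_wave(tl[!in_pause], m$carrier_frequency, phi)
        # ballistic pause: free fall, |A| ~ 0; clamp so magnitude stays < 0.2 g
        grav[pz] <- 0
        noise_sd[pz] <- 0
        ax[pz] <- pmin(pmax(0.02 * ax[pz], -0.1), 0.1)
        ay[pz] <- pmin(pmax(0.02 * ay[pz], -0.1), 0.1)
        az[pz] <- pmin(pmax(0.02 * az[pz], -0.1), 0.1)
        zsig[pz] <- 0
        pause[pz] <- TRUE
      } else {
        zsig[i] <- (eff / gain) * .flap_wave(tl, m$carrier_frequency, phi)
      }
    } else if (m$carrier_frequency > 0 && m$amplitude > 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      zsig[i] <- m$amplitude * sin(2 * pi * m$carrier_frequency * tl + phi)
    }
  }

  scale_noise <- !pause
  ax[scale_noise] <- ax[scale_noise] * noise_sd[scale_noise]
  ay[scale_noise] <- ay[scale_noise] * noise_sd[scale_noise]
  az[scale_noise] <- az[scale_noise] * noise_sd[scale_noise] + zsig[scale_noise] + grav[scale_noise]

  trace <- accel_trace(ax, ay, az, rate)
  if (isTRUE(config$quantize_output))
    trace <- quantize(trace, config$sensor_range, config$sensor_bits)

  fl <- beh == "flying"
  truth <- structure(list(
    labels = labels,
    flight_intervals = data.frame(start_s = starts[fl], end_s = ends[fl],
                                  duration_s = ends[fl] - starts[fl]),
    pause = pause
  ), class = "ground_truth")
  list(trace = trace, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default per-sex morphology sampling law
#'
#' Group means and standard deviations (field units: g, mm^2, mm) for a
#' pied-flycatcher-like songbird. Wing measures are for a single wing /
#' semi-span, as digitised from wing photos; [derive_morphology()] doubles
#' them. Males: mass 13.0 +/- 0.49 g, wing area 8712 +/- 418 mm^2, span
#' 211 +/- 7 mm. Females: 13.2 +/- 0.63 g, 8196 +/- 625 mm^2, 202 +/- 12 mm.
#'
#' @return nested list `male` / `female`, each with `mass_g`,
#'   `single_wing_area_mm2` and `semi_span_mm` as `c(mean, sd)`.
#' @export
default_morphology_law <- function() {
  list(
    male = list(mass_g = c(13.0, 0.49),
                single_wing_area_mm2 = c(8712, 418) / 2,
                semi_span_mm = c(211, 7) / 2),
    female = list(mass_g = c(13.2, 0.63),
                  single_wing_area_mm2 = c(8196, 625) / 2,
                  semi_span_mm = c(202, 12) / 2)
  )
}

#' Generate a synthetic bird population
#'
#' Draws per-bird morphometrics from sex-specific normal laws (redrawing the
#' rare non-positive values), plus brood size and a tagging time of day.
#'
#' @param n_birds number of birds (>= 1).
#' @param sex_ratio fraction of males in `[0, 1]`; the male count is
#'   `round(n_birds * sex_ratio)`.
#' @param morphology_law per-sex sampling law, see [default_morphology_law()].
#' @param seed integer seed.
#' @return data frame with columns `bird_id`, `sex`, `mass_g`,
#'   `single_wing_area_mm2`, `semi_span_mm`, `brood_size`, `tag_hour`.
#' @export
generate_population <- function(n_birds, sex_ratio = 0.5,
                                morphology_law = default_morphology_law(),
                                seed = 1) {
  if (n_birds < 1) stop("`n_birds` must be >= 1")
  if (sex_ratio < 0 || sex_ratio > 1) stop("`sex_ratio` must lie in [0, 1]")
  for (sx in c("male", "female")) {
    law <- morphology_law[[sx]]
    if (is.null(law)) stop("invalid morphology law: missing ", sx)
    for (p in c("mass_g", "single_wing_area_mm2", "semi_span_mm")) {
      v <- law[[p]]
      if (is.null(v) || length(v) != 2 || v[1] <= 0 || v[2] < 0)
        stop("invalid morphology law: ", sx, "$", p, " must be c(mean > 0, sd >= 0)")
    }
  }
  set.seed(seed)
  n_male <- round(n_birds * sex_ratio)
  sex <- c(rep("male", n_male), rep("female", n_birds - n_male))
  draw_pos <- function(n, mu, sd) {
    x <- stats::rnorm(n, mu, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mu, sd)
    x
  }
  out <- data.frame(bird_id = sprintf("bird%03d", seq_len(n_birds)), sex = sex,
                    mass_g = NA_real_, single_wing_area_mm2 = NA_real_,
                    semi_span_mm = NA_real_)
  for (sx in c("male", "female")) {
    i <- which(sex == sx)
    if (length(i) == 0) next
    law <- morphology_law[[sx]]
    out$mass_g[i] <- draw_pos(length(i), law$mass_g[1], law$mass_g[2])
    out$single_wing_area_mm2[i] <- draw_pos(length(i), law$single_wing_area_mm2[1],
                                            law$single_wing_area_mm2[2])
    out$semi_span_mm[i] <- draw_pos(length(i), law$semi_span_mm[1], law$semi_span_mm[2])
  }
  out$brood_size <- sample(3:8, n_birds, replace = TRUE,
                           prob = c(0.05, 0.10, 0.25, 0.30, 0.20, 0.10))
  out$tag_hour <- round(stats::runif(n_birds, 5, 20), 2)
  out
}
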