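test_that("identical config and seed reproduce the trace bit for bit", {
  a <- generate_trace(quick_config())
  b <- generate_trace(quick_config())
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$truth$flight_intervals, b$truth$flight_intervals)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(sample_rate = 0), "invalid config")
  expect_error(synthetic_config(session_duration = -5), "invalid config")
  expect_error(synthetic_config(bounding_pause_fraction = 1.4), "invalid config")
  expect_error(synthetic_config(behavior_weights = c(flying = 0, inactive = 0,
    food_shaking = 0, preening = 0, swallowing = 0, bill_wiping = 0)),
    "sum")
})

test_that("excluded flight cannot occur; gravity-only config is the (0,0,1) identity", {
  w <- c(flying = 0, inactive = 1, food_shaking = 0.3, preening = 0.2,
         swallowing = 0.2, bill_wiping = 0.2)
  out <- generate_trace(quick_config(duration = 200, behavior_weights = w))
  expect_equal(nrow(out$truth$flight_intervals), 0)
  expect_false(any(out$truth$labels == "flying"))

  bm <- default_behavior_models()
  bm$inactive$amplitude_noise_sd <- 0
  only_inactive <- c(flying = 0, inactive = 1, food_shaking = 0, preening = 0,
                     swallowing = 0, bill_wiping = 0)
  out2 <- generate_trace(quick_config(duration = 30, behavior_models = bm,
                                      behavior_weights = only_inactive))
  expect_true(all(out2$trace$samples[, "ax"] == 0))
  expect_true(all(out2$trace$samples[, "ay"] == 0))
  expect_true(all(out2$trace$samples[, "az"] == 1))
})

test_that("realized flight time matches the stationary fraction of the bout process", {
  cfg <- synthetic_config(sample_rate = 23, session_duration = 600, seed = 42)
  out <- generate_trace(cfg)
  target <- stationary_fractions(cfg)[["flying"]]
  realized <- mean(out$truth$labels == "flying")  # brute-force label count
  expect_lt(abs(realized - target), 0.03)
  expect_equal(n_samples(out$trace), round(23 * 600))
  # labels cover every sample; intervals disjoint, sorted, within session
  expect_equal(length(out$truth$labels), n_samples(out$trace))
  fi <- out$truth$flight_intervals
  expect_true(all(diff(fi$start_s) > 0))
  expect_true(all(fi$start_s >= 0 & fi$end_s <= 600 + 1e-9))
  expect_true(all(fi$end_s[-nrow(fi)] <= fi$start_s[-1] + 1e-9))
})

test_that("perching fluctuates about 1 g and ballistic pauses stay below 0.2 g", {
  cfg <- quick_config(duration = 300, flight_style_mix = 1)
  out <- generate_trace(cfg)
  mag <- sqrt(rowSums(out$trace$samples^2))
  perch <- out$truth$labels == "inactive"
  expect_lt(abs(mean(mag[perch]) - 1), 0.05)
  expect_gt(sum(out$truth$pause), 0)
  expect_true(all(mag[out$truth$pause] < 0.2))
})

test_that("per-bout mean VeDBA of long flights converges to the configured target", {
  bm <- default_behavior_models()
  bm$flying$duration_law <- list(dist = "fixed", value = 15)
  cfg <- synthetic_config(session_duration = 1500, behavior_models = bm,
    behavior_weights = c(flying = 3, inactive = 1, food_shaking = 0.1,
                         preening = 0.1, swallowing = 0.1, bill_wiping = 0.1),
    seed = 5)
  out <- generate_trace(cfg)
  v <- vedba(out$trace, 5)
  fi <- out$truth$flight_intervals
  vm <- vapply(seq_len(nrow(fi)), function(i)
    segment_mean_vedba(v, fi$start_s[i], fi$duration_s[i]), numeric(1))
  expect_gt(nrow(fi), 30)
  expect_lt(abs(mean(vm) - cfg$target_long_flight_vedba), 0.05)
})

test_that("population sampling honours the per-sex morphology law", {
  # degenerate law: zero variances reproduce the configured means exactly
  law <- default_morphology_law()
  for (sx in c("male", "female"))
    for (p in names(law[[sx]])) law[[sx]][[p]][2] <- 0
  one <- generate_population(1, sex_ratio = 1, morphology_law = law, seed = 9)
  expect_equal(one$sex, "male")
  expect_equal(one$mass_g, 13.0)
  expect_equal(one$semi_span_mm, 105.5)

  # law of large numbers: male semi-span mean within 0.5 mm of 105.5 (span within 1 mm of 211)
  pop <- generate_population(2000, sex_ratio = 1, seed = 10)
  expect_true(all(pop$sex == "male"))
  expect_lt(abs(mean(2 * pop$semi_span_mm) - 211), 1)
  expect_true(all(pop$mass_g > 0 & pop$single_wing_area_mm2 > 0 & pop$semi_span_mm > 0))

  expect_error(generate_population(0), ">= 1")
  bad <- default_morphology_law(); bad$male$mass_g <- c(-1, 2)
  expect_error(generate_population(5, morphology_law = bad), "invalid morphology law")
})

test_that("trace CSV round-trips samples and labels exactly", {
  out <- generate_trace(quick_config(duration = 20))
  path <- tempfile(fileext = ".csv")
  write_trace_csv(out$trace, path, labels = out$truth$labels)
  back <- read_trace_csv(path, sensor_range = 8, sensor_bits = 8)
  expect_identical(back$trace$samples, out$trace$samples)
  expect_identical(back$labels, out$truth$labels)
})

test_that("malformed trace CSVs raise parse errors naming the problem", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("time_s,ax_g,ay_g,az_g", "0,0.1,0.2,0.3", "0.043,oops,0.2,0.3"), path)
  expect_error(read_trace_csv(path), "line 3")
  writeLines(c("time_s,ax_g,ay_g", "0,0.1,0.2"), path)
  expect_error(read_trace_csv(path), "missing column")
  writeLines(character(0), path)
  expect_error(read_trace_csv(path), "parse error")
  writeLines("time_s,ax_g,ay_g,az_g", path)  # header only
  expect_error(read_trace_csv(path), "no data rows")
})
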