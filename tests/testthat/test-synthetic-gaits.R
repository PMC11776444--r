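test_that("zero-jitter walk is exactly periodic from 0", {
  rec <- simulate_recording(gait_spec("walk", 0.287, 0, 3), 1, seed = 1)
  expect_equal(rec$onsets, seq(0, 3, by = 0.287)[seq_along(rec$onsets)],
               tolerance = 1e-9)
  expect_gte(length(rec$onsets), 10)
})

test_that("zero-jitter canter repeats short-short-long with ~1.8x long beat", {
  rec <- simulate_recording(gait_spec("canter", c(0.148, 0.148, 0.267), 0, 6),
                            1, seed = 1)
  t <- diff(rec$onsets)
  expect_equal(t, rep_len(c(0.148, 0.148, 0.267), length(t)), tolerance = 1e-9)
  third <- t[seq(3, length(t), by = 3)]
  expect_equal(third / 0.148, rep(1.804, length(third)), tolerance = 0.001)
})

test_that("realized interval CV matches the requested jitter_cv", {
  rec <- simulate_recording(gait_spec("walk", 0.287, 0.05, 60), 1, seed = 42)
  t <- diff(rec$onsets)
  cv <- sd(t) / mean(t)
  expect_gt(cv, 0.05 * 0.7)
  expect_lt(cv, 0.05 * 1.3)
})

test_that("interval sample mean converges to pattern x multiplier", {
  for (mult in c(0.9, 1.2)) {
    rec <- simulate_recording(gait_spec("trot", 0.360, 0.06, 600), mult,
                              seed = 3)
    expect_equal(mean(diff(rec$onsets)), 0.360 * mult, tolerance = 0.02 * 0.36)
  }
})

test_that("onsets are 1 ms-quantized, strictly increasing, within duration", {
  rec <- simulate_recording(gait_spec("canter", c(0.148, 0.148, 0.267), 0.08,
                                      30), 1.1, seed = 9)
  expect_equal(rec$onsets, round(rec$onsets, 3))
  expect_true(all(diff(rec$onsets) > 0))
  expect_lte(max(rec$onsets), 30)
  expect_identical(rec$onsets[1], 0)
})

test_that("population simulation: size, shared multipliers, determinism", {
  pop <- population_spec(19, seed = 5)
  recs <- simulate_population(pop, default_gait_specs(duration_s = 5))
  expect_length(recs, 57)

  mult <- vapply(recs, function(r) r$metadata$tempo_multiplier, 0)
  ids <- vapply(recs, `[[`, "", "individual_id")
  # tempo multiplier is an individual trait, identical across gaits
  expect_true(all(tapply(mult, ids, function(m) length(unique(m))) == 1))

  again <- simulate_population(pop, default_gait_specs(duration_s = 5))
  expect_identical(lapply(recs, `[[`, "onsets"), lapply(again, `[[`, "onsets"))

  other <- simulate_population(population_spec(19, seed = 6),
                               default_gait_specs(duration_s = 5))
  expect_false(identical(lapply(recs, `[[`, "onsets"),
                         lapply(other, `[[`, "onsets")))
})

test_that("degenerate population has unit multiplier", {
  recs <- simulate_population(population_spec(1, individual_tempo_sd = 0,
                                              seed = 1),
                              default_gait_specs(duration_s = 5))
  expect_identical(vapply(recs, function(r) r$metadata$tempo_multiplier, 0),
                   rep(1, 3))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(gait_spec("walk", -0.1), class = "gaitrhythm_invalid_parameter")
  expect_error(gait_spec("canter", c(0.1, 0.2)),
               class = "gaitrhythm_invalid_parameter")
  expect_error(gait_spec("walk", 0.3, duration_s = 0),
               class = "gaitrhythm_invalid_parameter")
  expect_error(simulate_recording(gait_spec("walk", 0.3), -1),
               class = "gaitrhythm_invalid_parameter")
  expect_error(population_spec(0), class = "gaitrhythm_invalid_parameter")
})
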