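test_that("intervals are successive onset differences", {
  expect_equal(compute_intervals(
    footfall_recording("h", "walk", c(0, 0.3, 0.6)))$t, c(0.3, 0.3))
  # canter beat pattern: two short beats then the suspension-spanning interval
  expect_equal(compute_intervals(
    footfall_recording("h", "canter", c(0, 0.148, 0.296, 0.563)))$t,
    c(0.148, 0.148, 0.267))

  set.seed(11)
  for (rep in 1:20) {
    onsets <- cumsum(c(0, runif(sample(2:30, 1), 0.05, 0.6)))
    got <- compute_intervals(footfall_recording("h", "trot", onsets))$t
    want <- vapply(seq_len(length(onsets) - 1),
                   function(k) onsets[k + 1] - onsets[k], 0)
    expect_equal(got, want)
  }
  expect_error(compute_intervals(structure(
    list(individual_id = "h", gait = "walk", onsets = 0),
    class = "footfall_recording")), class = "gaitrhythm_insufficient_data")
})

test_that("rhythmic ratios follow r_k = t_k/(t_k + t_k+1)", {
  iv <- function(t) structure(list(individual_id = "h", gait = "walk", t = t),
                              class = "interval_seq")
  expect_equal(compute_ratios(iv(c(1, 1)))$r, 0.5)
  expect_equal(compute_ratios(iv(c(1, 2, 1)))$r, c(1 / 3, 2 / 3))

  set.seed(12)
  for (rep in 1:20) {
    t <- runif(sample(2:40, 1), 0.05, 0.6)
    got <- compute_ratios(iv(t))$r
    want <- vapply(seq_len(length(t) - 1),
                   function(k) t[k] / (t[k] + t[k + 1]), 0)
    expect_equal(got, want)
    # mirror symmetry: reversing the intervals maps r to rev(1 - r)
    expect_equal(compute_ratios(iv(rev(t)))$r, rev(1 - got))
  }
  expect_error(compute_ratios(iv(0.3)),
               class = "gaitrhythm_insufficient_data")
})

test_that("bin scheme edges are the exact reciprocal-denominator fractions", {
  s <- build_bin_scheme()
  on12 <- s[s$bin == "1:2-on", ]
  expect_identical(on12$lower, 1 / 3.25)
  expect_identical(on12$upper, 1 / 2.75)
  on11 <- s[s$bin == "1:1-on", ]
  expect_identical(on11$lower, 1 / 2.25)
  expect_identical(on11$upper, 1 - 1 / 2.25)
  on21 <- s[s$bin == "2:1-on", ]
  expect_identical(on21$lower, 1 - 1 / 2.75)
  expect_identical(on21$upper, 1 - 1 / 3.25)
  expect_equal(s$center[s$kind == "off"],
               c(1 / 3.5, 1 / 2.5, 1 - 1 / 2.5, 1 - 1 / 3.5))
  # the 1:1 bin is symmetric about 1/2 and the whole scheme tiles the range
  expect_equal(on11$upper - 0.5, 0.5 - on11$lower)
  expect_equal(s$lower[-1], s$upper[-nrow(s)])
  expect_equal(s$lower[1], 1 / 3.75)
  expect_equal(s$upper[nrow(s)], 1 - 1 / 3.75)
  expect_equal(attr(s, "reference"),
               c("1:2" = 1 / 3, "1:1" = 1 / 2, "2:1" = 2 / 3))
})

test_that("ratio classification is half-open with a closed outer edge", {
  s <- build_bin_scheme()
  expect_identical(classify_ratio(0.5, s), "1:1-on")
  expect_identical(classify_ratio(0.35, s), "1:2-on")
  expect_identical(classify_ratio(0.25, s), "outside")
  # shared edges belong to the upper bin; the outermost edge is included
  expect_identical(classify_ratio(1 / 2.75, s), "off-1:2/1:1")
  expect_identical(classify_ratio(1 / 3.75, s), "off-1:2L")
  expect_identical(classify_ratio(1 - 1 / 3.75, s), "off-2:1U")
  expect_identical(classify_ratio(0.74, s), "outside")
})

test_that("count_by_bin matches an independent per-element tally", {
  s <- build_bin_scheme()
  set.seed(13)
  for (rep in 1:10) {
    r <- runif(200, 0.2, 0.8)
    rs <- structure(list(individual_id = "h", gait = "walk", r = r,
                         phase = NULL), class = "ratio_seq")
    counts <- count_by_bin(rs, s)
    want <- table(factor(oracle_bin_tally(r, s), levels = s$bin))
    expect_equal(counts$count, as.integer(want[counts$bin]),
                 ignore_attr = TRUE)
    expect_identical(sum(counts$count), sum(oracle_bin_tally(r, s) != "outside"))
  }
})

test_that("uniform ratios fill bins proportionally to width", {
  s <- build_bin_scheme()
  set.seed(14)
  n <- 1e5
  lo <- s$lower[1]; hi <- s$upper[nrow(s)]
  r <- runif(n, lo, hi)
  rs <- structure(list(individual_id = "h", gait = "walk", r = r,
                       phase = NULL), class = "ratio_seq")
  counts <- count_by_bin(rs, s)
  p <- counts$width / (hi - lo)
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(counts$count / n - p) < 3 * se + 1e-4))
})

test_that("zero-jitter gaits land entirely in their expected bins", {
  recs <- fixture_clean_recordings()
  ivs <- lapply(recs, compute_intervals)
  g <- vapply(ivs, `[[`, "", "gait")
  for (gait in c("walk", "trot")) {
    rr <- lapply(ivs[g == gait], compute_ratios)
    # exact up to the 1 ms annotation quantization of the onsets
    expect_true(all(abs(unlist(lapply(rr, `[[`, "r")) - 0.5) < 1e-9))
  }
  ph <- lapply(ivs[g == "canter"], function(s)
    compute_canter_phase_ratios(segment_canter_cycles(s)))
  r <- unlist(lapply(ph, `[[`, "r"))
  phase <- unlist(lapply(ph, `[[`, "phase"))
  expect_true(all(abs(r[phase == "rk1"] - 0.5) < 1e-9))
  expect_true(all(abs(r[phase == "rk2"] - 0.148 / (0.148 + 0.267)) < 1e-9))
  expect_true(all(abs(r[phase == "rk3"] - 0.267 / (0.267 + 0.148)) < 1e-9))
  lab <- classify_ratio(r, build_bin_scheme())
  expect_true(all(lab[phase == "rk1"] == "1:1-on"))
  expect_true(all(lab[phase == "rk2"] == "1:2-on"))
  expect_true(all(lab[phase == "rk3"] == "2:1-on"))
})

test_that("canter segmentation recovers short-short-long cycles", {
  iv <- function(t) structure(list(individual_id = "h", gait = "canter",
                                   t = t), class = "interval_seq")
  cy <- segment_canter_cycles(iv(rep(c(0.148, 0.148, 0.267), 5)))
  expect_equal(nrow(cy$t), 5)
  expect_true(all(apply(cy$t, 1, function(x)
    isTRUE(all.equal(x, c(0.148, 0.148, 0.267), check.names = FALSE)))))

  # sequence starting mid-cycle: the leading fragment is dropped
  cy2 <- segment_canter_cycles(iv(c(0.267, 0.148, 0.148, 0.267)))
  expect_equal(nrow(cy2$t), 1)
  expect_equal(unname(cy2$t[1, ]), c(0.148, 0.148, 0.267))

  # jittered synthetic canter: every cycle's t3 exceeds both short beats
  rec <- simulate_recording(gait_spec("canter", c(0.148, 0.148, 0.267), 0.05,
                                      60), 1, seed = 21)
  cy3 <- segment_canter_cycles(compute_intervals(rec))
  expect_true(all(cy3$t[, 3] > pmax(cy3$t[, 1], cy3$t[, 2])))
  n_long <- sum(abs(diff(rec$onsets)) > 0.2)
  expect_lte(nrow(cy3$t), n_long)

  expect_error(segment_canter_cycles(iv(rep(0.3, 12))),
               class = "gaitrhythm_segmentation_failure")
  expect_error(segment_canter_cycles(structure(
    list(individual_id = "h", gait = "walk", t = rep(0.3, 12)),
    class = "interval_seq")), class = "gaitrhythm_invalid_parameter")
})

test_that("canter phase ratios use the next cycle's first beat for rk3", {
  cycles <- structure(list(individual_id = "h",
                           t = rbind(c(1, 1, 2), c(1, 1, 2)),
                           start = c(1L, 4L),
                           diagnostics = list()),
                      class = "canter_cycles")
  pr <- compute_canter_phase_ratios(cycles)
  expect_equal(pr$r[pr$phase == "rk1"], c(0.5, 0.5))
  expect_equal(pr$r[pr$phase == "rk2"], c(1 / 3, 1 / 3))
  expect_equal(pr$r[pr$phase == "rk3"], 2 / 3)  # last cycle yields no rk3

  one <- structure(list(individual_id = "h", t = rbind(c(1, 1, 2)),
                        start = 1L, diagnostics = list()),
                   class = "canter_cycles")
  pr1 <- compute_canter_phase_ratios(one)
  expect_identical(pr1$phase, c("rk1", "rk2"))

  # non-adjacent cycles (a dropped fragment between them) yield no rk3
  gap <- structure(list(individual_id = "h",
                        t = rbind(c(1, 1, 2), c(1, 1, 2)),
                        start = c(1L, 7L), diagnostics = list()),
                   class = "canter_cycles")
  expect_false("rk3" %in% compute_canter_phase_ratios(gap)$phase)
})

test_that("triplets slide with stride 1 and normalize to 100", {
  iv <- function(t, g = "walk") structure(
    list(individual_id = "h", gait = g, t = t), class = "interval_seq")
  tt <- make_triplets(iv(c(1, 1, 1)), normalize = TRUE)
  expect_equal(unlist(tt[1, c("t1", "t2", "t3")]), rep(100 / 3, 3),
               ignore_attr = TRUE)
  tt2 <- make_triplets(iv(c(1, 1, 2)), normalize = TRUE)
  expect_equal(unlist(tt2[1, c("t1", "t2", "t3")]), c(25, 25, 50),
               ignore_attr = TRUE)
  t <- runif(20, 0.1, 0.5)
  expect_identical(nrow(make_triplets(iv(t))), 18L)
  norm <- make_triplets(iv(t), normalize = TRUE)
  expect_true(all(abs(rowSums(norm[, c("t1", "t2", "t3")]) - 100) < 1e-9))
  expect_error(make_triplets(iv(c(1, 2))),
               class = "gaitrhythm_insufficient_data")
})

test_that("density peaks find the modes of ratio distributions", {
  set.seed(15)
  tight <- structure(list(individual_id = "h", gait = "trot",
                          r = rnorm(500, 0.5, 0.005), phase = NULL),
                     class = "ratio_seq")
  pk <- find_density_peaks(tight)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$position - 0.5), 0.01)

  bim <- structure(list(individual_id = "h", gait = "walk",
                        r = c(rnorm(400, 0.4, 0.01), rnorm(400, 0.6, 0.01)),
                        phase = NULL), class = "ratio_seq")
  pk2 <- find_density_peaks(bim)
  expect_identical(nrow(pk2), 2L)
  expect_equal(pk2$position, c(0.4, 0.6), tolerance = 0.02)

  # zero-noise canter phase ratios pooled: one peak per phase value
  recs <- fixture_clean_recordings()
  ivs <- lapply(recs, compute_intervals)
  g <- vapply(ivs, `[[`, "", "gait")
  ph <- lapply(ivs[g == "canter"], function(s)
    compute_canter_phase_ratios(segment_canter_cycles(s)))
  pooled <- structure(list(individual_id = "all", gait = "canter",
                           r = unlist(lapply(ph, `[[`, "r")), phase = NULL),
                      class = "ratio_seq")
  pk3 <- find_density_peaks(pooled)
  want <- sort(c(0.5, 0.148 / 0.415, 0.267 / 0.415))
  expect_identical(nrow(pk3), 3L)
  expect_equal(pk3$position, want, tolerance = 0.02)

  expect_warning(empty <- find_density_peaks(tight$r[1:5]), "empty peak set")
  expect_identical(nrow(empty), 0L)
})
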