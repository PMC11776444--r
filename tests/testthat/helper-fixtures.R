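# Shared fixtures, all generated in code under fixed seeds.

# small jitter-free population: 3 individuals x 3 gaits, 20 s each
fixture_clean_recordings <- function() {
  specs <- default_gait_specs(duration_s = 20,
                              jitter_cv = c(walk = 0, trot = 0, canter = 0))
  simulate_population(population_spec(3, individual_tempo_sd = 0, seed = 7),
                      specs)
}

# small realistic population for model smoke tests
fixture_noisy_recordings <- function(n = 6, duration_s = 40, seed = 42) {
  simulate_population(population_spec(n, seed = seed),
                      default_gait_specs(duration_s = duration_s))
}

intervals_by_gait <- function(recordings) {
  ivs <- lapply(recordings, compute_intervals)
  split(ivs, vapply(ivs, `[[`, "", "gait"))
}

# independent oracle for bin tallies: per-element loop over the scheme rows
oracle_bin_tally <- function(r, scheme) {
  labs <- character(length(r))
  for (i in seq_along(r)) {
    labs[i] <- "outside"
    for (j in seq_len(nrow(scheme))) {
      closed <- j == nrow(scheme)
      if (r[i] >= scheme$lower[j] &&
          (r[i] < scheme$upper[j] || (closed && r[i] <= scheme$upper[j]))) {
        labs[i] <- scheme$bin[j]
        break
      }
    }
  }
  labs
}

# long-format TextGrid content as emitted by Praat, built line by line
make_long_textgrid <- function(times, tier = "steps") {
  c('File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0 ",
    sprintf("xmax = %.6f ", max(times) + 0.5),
    "tiers? <exists> ",
    "size = 2 ",
    "item []: ",
    "    item [1]:",
    '        class = "IntervalTier" ',
    '        name = "notes" ',
    "        xmin = 0 ",
    sprintf("        xmax = %.6f ", max(times) + 0.5),
    "        intervals: size = 1 ",
    "        intervals [1]:",
    "            xmin = 0 ",
    sprintf("            xmax = %.6f ", max(times) + 0.5),
    '            text = "" ',
    "    item [2]:",
    '        class = "TextTier" ',
    sprintf('        name = "%s" ', tier),
    "        xmin = 0 ",
    sprintf("        xmax = %.6f ", max(times) + 0.5),
    sprintf("        points: size = %d ", length(times)),
    unlist(lapply(seq_along(times), function(i) c(
      sprintf("        points [%d]:", i),
      sprintf("            number = %.6f ", times[i]),
      '            mark = "x" '
    ))))
}

# equivalent short-format TextGrid
make_short_textgrid <- function(times, tier = "steps") {
  c('File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "0",
    sprintf("%.6f", max(times) + 0.5),
    "<exists>",
    "2",
    '"IntervalTier"',
    '"notes"',
    "0",
    sprintf("%.6f", max(times) + 0.5),
    "1",
    "0",
    sprintf("%.6f", max(times) + 0.5),
    '""',
    '"TextTier"',
    sprintf('"%s"', tier),
    "0",
    sprintf("%.6f", max(times) + 0.5),
    sprintf("%d", length(times)),
    unlist(lapply(times, function(t) c(sprintf("%.6f", t), '"x"'))))
}
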