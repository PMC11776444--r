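#' Simulate one footfall recording
#'
#' Realizes a gait's repeating interval pattern as a strictly increasing onset
#' sequence starting at 0. Each realized interval is the pattern value times
#' the individual's tempo multiplier times mean-one multiplicative log-normal
#' noise whose coefficient of variation equals `spec$jitter_cv`. Onsets are
#' rounded to 1 ms, mimicking manual annotation granularity, and the sequence
#' is truncated at `spec$duration_s`.
#'
#' @param spec A [gait_spec()].
#' @param tempo_multiplier Positive scalar scaling all intervals of this
#'   individual (an individual trait shared across gaits).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param individual_id Identifier stored in the returned recording.
#'
#' @return A [footfall_recording()].
#' @export
#' @examples
#' simulate_recording(gait_spec("walk", 0.287, 0, 3), 1, seed = 1)
simulate_recording <- function(spec, tempo_multiplier = 1, seed = NULL,
                               individual_id = "sim") {
  stopifnot(inherits(spec, "gait_spec"))
  if (!is.numeric(tempo_multiplier) || length(tempo_multiplier) != 1L ||
      !is.finite(tempo_multiplier) || tempo_multiplier <= 0) {
    stop_gr("tempo_multiplier must be a positive scalar",
            class = "gaitrhythm_invalid_parameter")
  }
  with_seed(seed, {
    base <- spec$base_intervals * tempo_multiplier
    # upper bound on how many intervals fit, with slack for downward jitter
    n_max <- ceiling(spec$duration_s / min(base)) + length(base) + 8L
    pattern <- rep_len(base, n_max)
    if (spec$jitter_cv > 0) {
      sigma <- sqrt(log(1 + spec$jitter_cv^2))
      # mean-one log-normal factor: E[interval] = pattern value exactly
      noise <- exp(rnorm(n_max, -sigma^2 / 2, sigma))
      pattern <- pattern * noise
    }
    onsets <- c(0, cumsum(pattern))
    onsets <- round(onsets[onsets <= spec$duration_s], 3)
    footfall_recording(individual_id, spec$gait, onsets,
                       metadata = list(tempo_multiplier = tempo_multiplier,
                                       jitter_cv = spec$jitter_cv))
  })
}

#' Simulate a population of individuals across gaits
#'
#' Draws one log-normal (median 1) tempo multiplier per individual and
#' simulates every individual x gait combination. The multiplier is shared
#' across an individual's gaits, so tempo is an individual trait. Output is
#' bit-identical under a fixed `pop$seed`.
#'
#' @param pop A [population_spec()].
#' @param specs List of [gait_spec()] objects (default [default_gait_specs()]).
#'
#' @return List of [footfall_recording()]s, one per individual x gait,
#'   ordered individual-major.
#' @export
#' @examples
#' recs <- simulate_population(population_spec(2, seed = 7),
#'                             default_gait_specs(duration_s = 10))
#' length(recs)  # 2 individuals x 3 gaits
simulate_population <- function(pop, specs = default_gait_specs()) {
  stopifnot(inherits(pop, "population_spec"))
  if (length(specs) == 0) {
    stop_gr("specs must be a nonempty list of gait_spec objects",
            class = "gaitrhythm_invalid_parameter")
  }
  lapply(specs, function(s) stopifnot(inherits(s, "gait_spec")))
  with_seed(pop$seed, {
    mult <- if (pop$individual_tempo_sd > 0) {
      rlnorm(pop$n_individuals, 0, pop$individual_tempo_sd)
    } else {
      rep(1, pop$n_individuals)
    }
    ids <- sprintf("ind%02d", seq_len(pop$n_individuals))
    out <- vector("list", pop$n_individuals * length(specs))
    k <- 0L
    for (i in seq_len(pop$n_individuals)) {
      for (s in specs) {
        k <- k + 1L
        out[[k]] <- simulate_recording(s, mult[i], seed = NULL,
                                       individual_id = ids[i])
      }
    }
    out
  })
}
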