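#' Specify the timing template of one gait
#'
#' A `gait_spec` describes the repeating motion-cycle pattern of a gait as a
#' vector of base inter-onset intervals plus a multiplicative timing jitter.
#' Walk and trot are (near-)isochronous, so their pattern is a single interval;
#' canter has a three-beat cycle whose last interval spans the suspension
#' phase, so its pattern is three intervals (short, short, long).
#'
#' @param gait One of `"walk"`, `"trot"`, `"canter"`.
#' @param base_intervals Base interval durations in seconds for one motion
#'   cycle: length 1 for walk/trot, length 3 for canter. All must be positive.
#' @param jitter_cv Coefficient of variation of the multiplicative log-normal
#'   timing noise applied independently to each realized interval
#'   (dimensionless, `>= 0`).
#' @param duration_s Total simulated duration in seconds.
#'
#' @return An object of class `gait_spec`.
#' @seealso [default_gait_specs()], [simulate_recording()]
#' @export
#' @examples
#' gait_spec("canter", c(0.148, 0.148, 0.267), jitter_cv = 0.05)
gait_spec <- function(gait, base_intervals, jitter_cv = 0, duration_s = 60) {
  gait <- match.arg(gait, GAITS)
  if (!is.numeric(base_intervals) || any(!is.finite(base_intervals)) ||
      any(base_intervals <= 0)) {
    stop_gr("base_intervals must be positive finite numbers",
            class = "gaitrhythm_invalid_parameter")
  }
  n_expect <- if (gait == "canter") 3L else 1L
  if (length(base_intervals) != n_expect) {
    stop_gr(sprintf("gait '%s' requires %d base interval(s), got %d",
                    gait, n_expect, length(base_intervals)),
            class = "gaitrhythm_invalid_parameter")
  }
  if (!is.numeric(jitter_cv) || length(jitter_cv) != 1L || jitter_cv < 0) {
    stop_gr("jitter_cv must be a single non-negative number",
            class = "gaitrhythm_invalid_parameter")
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop_gr("duration_s must be a single positive number",
            class = "gaitrhythm_invalid_parameter")
  }
  structure(
    list(gait = gait, base_intervals = as.numeric(base_intervals),
         jitter_cv = as.numeric(jitter_cv), duration_s = as.numeric(duration_s)),
    class = "gait_spec"
  )
}

#' Default gait timing templates
#'
#' The default templates reproduce the modal interval durations of ridden
#' horses on a firm surface: walk 0.287 s, trot 0.360 s, and a canter cycle of
#' 0.148, 0.148, 0.267 s (two short beats, then the suspension-spanning
#' interval). Default jitter CVs encode the precision ordering trot < canter <
#' walk (trot, with its mirrored two-beat limb pattern, is the most
#' metronome-like gait); they are calibration defaults, tunable per spec.
#'
#' @param duration_s Simulated duration per recording in seconds (default 60,
#'   one minute per gait).
#' @param jitter_cv Named numeric vector of per-gait jitter CVs overriding the
#'   defaults `c(walk = 0.06, trot = 0.03, canter = 0.05)`.
#'
#' @return Named list of three [gait_spec()] objects (walk, trot, canter).
#' @export
default_gait_specs <- function(duration_s = 60,
                               jitter_cv = c(walk = 0.06, trot = 0.03,
                                             canter = 0.05)) {
  cv <- c(walk = 0.06, trot = 0.03, canter = 0.05)
  cv[names(jitter_cv)] <- jitter_cv
  list(
    walk   = gait_spec("walk", 0.287, cv[["walk"]], duration_s),
    trot   = gait_spec("trot", 0.360, cv[["trot"]], duration_s),
    canter = gait_spec("canter", c(0.148, 0.148, 0.267), cv[["canter"]],
                       duration_s)
  )
}

#' Specify a simulated population of individuals
#'
#' Each simulated individual carries a tempo multiplier, shared across all of
#' its gaits, drawn from a log-normal distribution with median 1. This
#' emulates morphology-driven between-individual tempo differences: a large
#' horse walks, trots and canters with proportionally longer intervals.
#'
#' @param n_individuals Number of individuals (`>= 1`); default 19.
#' @param individual_tempo_sd Standard deviation, on the log scale, of the
#'   per-individual tempo multiplier (default 0.15, giving a realistic ~16%
#'   between-individual tempo spread).
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_individuals = 19, individual_tempo_sd = 0.15,
                            seed = 1) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 1) {
    stop_gr("n_individuals must be >= 1", class = "gaitrhythm_invalid_parameter")
  }
  if (!is.numeric(individual_tempo_sd) || individual_tempo_sd < 0) {
    stop_gr("individual_tempo_sd must be >= 0",
            class = "gaitrhythm_invalid_parameter")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         individual_tempo_sd = as.numeric(individual_tempo_sd),
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' @export
print.gait_spec <- function(x, ...) {
  cat(sprintf("<gait_spec> %s: pattern [%s] s, jitter CV %.3f, %.0f s\n",
              x$gait, paste(format(x$base_intervals), collapse = ", "),
              x$jitter_cv, x$duration_s))
  invisible(x)
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %d individuals, tempo SD %.3f (log scale), seed %d\n",
              x$n_individuals, x$individual_tempo_sd, x$seed))
  invisible(x)
}
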