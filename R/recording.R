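#' Construct a footfall recording
#'
#' A `footfall_recording` is one individual x gait sequence of footfall onset
#' times (seconds from the start of the annotated segment). Onsets must be
#' strictly increasing; gait transitions are assumed pre-excised so each
#' recording is a single-gait segment.
#'
#' @param individual_id Character scalar identifying the animal.
#' @param gait One of `"walk"`, `"trot"`, `"canter"`.
#' @param onsets Strictly increasing numeric vector of onset times in seconds,
#'   length >= 2.
#' @param metadata Optional named list (sex, age, breed, withers height, ...).
#'
#' @return An object of class `footfall_recording`.
#' @export
#' @examples
#' footfall_recording("h01", "walk", c(0, 0.29, 0.58, 0.86))
footfall_recording <- function(individual_id, gait, onsets, metadata = list()) {
  gait <- match.arg(gait, GAITS)
  individual_id <- as.character(individual_id)
  onsets <- as.numeric(onsets)
  if (length(onsets) < 2L) {
    stop_gr("a recording needs at least 2 onsets to yield an interval",
            class = "gaitrhythm_insufficient_data")
  }
  if (any(!is.finite(onsets)) || any(onsets < 0)) {
    stop_gr("onsets must be finite and non-negative",
            class = "gaitrhythm_validation")
  }
  d <- diff(onsets)
  if (any(d <= 0)) {
    bad <- onsets[which(d <= 0) + 1L]
    stop_gr("onsets not strictly increasing at: ",
            paste(format(bad), collapse = ", "),
            class = "gaitrhythm_validation")
  }
  structure(
    list(individual_id = individual_id, gait = gait, onsets = onsets,
         metadata = metadata),
    class = "footfall_recording"
  )
}

#' @export
print.footfall_recording <- function(x, ...) {
  cat(sprintf("<footfall_recording> %s / %s: %d onsets over %.2f s\n",
              x$individual_id, x$gait, length(x$onsets),
              x$onsets[length(x$onsets)] - x$onsets[1]))
  invisible(x)
}
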