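#' Inter-onset intervals of a recording
#'
#' The inter-onset interval t_k is the time between two successive footfall
#' onsets, the elementary quantity of the rhythm analysis.
#'
#' @param rec A [footfall_recording()] with at least 2 onsets.
#' @return An object of class `interval_seq`: list with `individual_id`,
#'   `gait`, and `t`, the vector of intervals in seconds.
#' @export
#' @examples
#' compute_intervals(footfall_recording("h", "walk", c(0, 0.3, 0.6)))$t
compute_intervals <- function(rec) {
  stopifnot(inherits(rec, "footfall_recording"))
  if (length(rec$onsets) < 2L) {
    stop_gr("need >= 2 onsets", class = "gaitrhythm_insufficient_data")
  }
  structure(
    list(individual_id = rec$individual_id, gait = rec$gait,
         t = diff(rec$onsets)),
    class = "interval_seq"
  )
}

#' Rhythmic ratios of adjacent intervals
#'
#' The rhythmic ratio r_k = t_k / (t_k + t_k+1) normalizes each pair of
#' adjacent intervals onto (0, 1): 0.5 marks isochrony (1:1), 1/3 a short-long
#' (1:2) relationship and 2/3 a long-short (2:1) relationship. Ratios are
#' computed over sliding adjacent pairs (stride 1).
#'
#' @param seq An `interval_seq` with at least 2 intervals.
#' @return An object of class `ratio_seq`: list with `individual_id`, `gait`,
#'   `r` (ratios in (0,1)) and `phase` (`NULL` here; see
#'   [compute_canter_phase_ratios()]).
#' @export
#' @examples
#' s <- compute_intervals(footfall_recording("h", "walk", c(0, 1, 3, 4)))
#' compute_ratios(s)$r  # 1/3, 2/3
compute_ratios <- function(seq) {
  stopifnot(inherits(seq, "interval_seq"))
  n <- length(seq$t)
  if (n < 2L) stop_gr("need >= 2 intervals", class = "gaitrhythm_insufficient_data")
  r <- seq$t[-n] / (seq$t[-n] + seq$t[-1])
  structure(
    list(individual_id = seq$individual_id, gait = seq$gait, r = r,
         phase = NULL),
    class = "ratio_seq"
  )
}

ratio_seq <- function(individual_id, gait, r, phase = NULL) {
  structure(list(individual_id = individual_id, gait = gait, r = r,
                 phase = phase),
            class = "ratio_seq")
}

#' Adjacent-interval triplets
#'
#' Slides a window of three adjacent intervals (stride 1) over the sequence.
#' With `normalize = TRUE` each triplet is rescaled to proportions summing to
#' 100, the coordinates used by ternary plots; raw durations are what the
#' gait/individual classifier embeds (tempo is diagnostic of gait, so it is
#' not normalized away there).
#'
#' @param seq An `interval_seq` (>= 3 intervals) or a list of them.
#' @param normalize Logical; return proportions summing to 100 instead of raw
#'   durations.
#' @return A data frame of class `triplet_table` with columns `individual_id`,
#'   `gait`, `t1`, `t2`, `t3` (n-2 rows per sequence of n intervals).
#' @export
make_triplets <- function(seq, normalize = FALSE) {
  if (inherits(seq, "interval_seq")) seq <- list(seq)
  out <- lapply(seq, function(s) {
    stopifnot(inherits(s, "interval_seq"))
    n <- length(s$t)
    if (n < 3L) stop_gr("need >= 3 intervals for triplets",
                        class = "gaitrhythm_insufficient_data")
    m <- cbind(t1 = s$t[1:(n - 2)], t2 = s$t[2:(n - 1)], t3 = s$t[3:n])
    if (normalize) m <- 100 * m / rowSums(m)
    data.frame(individual_id = s$individual_id, gait = s$gait, m,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("triplet_table", "data.frame")
  attr(res, "normalized") <- normalize
  res
}
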