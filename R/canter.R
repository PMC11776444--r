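# Canter motion-cycle handling. A canter stride is three footfalls plus a
# suspension phase; in the interval sequence this appears as a repeating
# short-short-long pattern, the long interval spanning the suspension.

#' Segment a canter interval sequence into motion cycles
#'
#' Partitions the intervals of a canter recording into (short, short, long)
#' motion cycles. Long (suspension-spanning) intervals are identified by a
#' two-cluster partition of log t_k; the runs between consecutive long
#' intervals that consist of exactly two short intervals form valid cycles.
#' Leading/trailing fragments and runs not matching short-short-long are
#' dropped and reported in the diagnostics.
#'
#' @param seq An `interval_seq` with `gait == "canter"` and >= 3 intervals.
#' @param min_separation Minimum ratio between the geometric means of the long
#'   and short clusters for the bimodal structure to count as detected
#'   (default 1.2).
#' @return An object of class `canter_cycles`: list with `individual_id`,
#'   `t` (n_cycles x 3 matrix, columns t1 t2 t3), `start` (index of each
#'   cycle's first interval in the original sequence), and `diagnostics`
#'   (dropped fragment count, cluster means).
#' @export
segment_canter_cycles <- function(seq, min_separation = 1.2) {
  stopifnot(inherits(seq, "interval_seq"))
  if (seq$gait != "canter") {
    stop_gr("cycle segmentation applies to canter sequences",
            class = "gaitrhythm_invalid_parameter")
  }
  t <- seq$t
  if (length(t) < 3L) stop_gr("need >= 3 intervals",
                              class = "gaitrhythm_insufficient_data")
  lt <- log(t)
  # deterministic 2-means on log intervals, centers seeded at the quartiles
  init <- matrix(quantile(lt, c(0.25, 0.75), names = FALSE), ncol = 1)
  if (diff(init[, 1]) < 1e-12) init[2, 1] <- init[2, 1] + 1e-6
  km <- tryCatch(
    suppressWarnings(kmeans(matrix(lt, ncol = 1), centers = init)),
    error = function(e) stop_gr(
      "no bimodal short/long structure detected (", conditionMessage(e), ")",
      class = "gaitrhythm_segmentation_failure"))
  long_cluster <- which.max(km$centers)
  sep <- exp(abs(diff(km$centers[, 1])))
  is_long <- km$cluster == long_cluster
  if (sep < min_separation || all(is_long) || !any(is_long)) {
    stop_gr(sprintf(
      "no bimodal short/long structure detected (cluster separation %.3f < %.3f)",
      sep, min_separation), class = "gaitrhythm_segmentation_failure")
  }
  long_idx <- which(is_long)
  cycles <- list(); starts <- integer(0); dropped <- 0L
  prev_end <- 0L  # index of previous long interval (0 = sequence start)
  for (p in long_idx) {
    n_short <- p - prev_end - 1L
    if (n_short == 2L) {
      cycles[[length(cycles) + 1L]] <- t[(p - 2L):p]
      starts <- c(starts, p - 2L)
    } else {
      dropped <- dropped + 1L
    }
    prev_end <- p
  }
  if (prev_end < length(t)) dropped <- dropped + 1L  # trailing shorts
  if (!length(cycles)) {
    stop_gr("no complete short-short-long cycle found",
            class = "gaitrhythm_segmentation_failure")
  }
  structure(
    list(individual_id = seq$individual_id,
         t = do.call(rbind, cycles),
         start = starts,
         diagnostics = list(n_dropped_fragments = dropped,
                            short_mean = exp(min(km$centers)),
                            long_mean = exp(max(km$centers)),
                            separation = sep)),
    class = "canter_cycles"
  )
}

#' Per-phase rhythmic ratios of canter motion cycles
#'
#' For each cycle (t1, t2, t3): r_k1 = t1/(t1+t2) relates the two short
#' beats (expected near 1:1), r_k2 = t2/(t2+t3) relates the second beat to
#' the suspension-spanning interval (expected near 1:2), and r_k3 =
#' t3/(t3+t1') relates the suspension interval to the first beat of the next
#' cycle (expected near 2:1). r_k3 is only defined when the next cycle starts
#' immediately after this one; the last cycle yields no r_k3.
#'
#' @param cycles A `canter_cycles` object from [segment_canter_cycles()].
#' @return A `ratio_seq` with `phase` labels in `{"rk1","rk2","rk3"}`.
#' @export
compute_canter_phase_ratios <- function(cycles) {
  stopifnot(inherits(cycles, "canter_cycles"))
  tm <- cycles$t
  n <- nrow(tm)
  r <- numeric(0); phase <- character(0)
  for (i in seq_len(n)) {
    t1 <- tm[i, 1]; t2 <- tm[i, 2]; t3 <- tm[i, 3]
    r <- c(r, t1 / (t1 + t2), t2 / (t2 + t3))
    phase <- c(phase, "rk1", "rk2")
    if (i < n && cycles$start[i + 1L] == cycles$start[i] + 3L) {
      t1n <- tm[i + 1L, 1]
      r <- c(r, t3 / (t3 + t1n))
      phase <- c(phase, "rk3")
    }
  }
  ratio_seq(cycles$individual_id, "canter", r, phase)
}

#' @export
print.canter_cycles <- function(x, ...) {
  cat(sprintf("<canter_cycles> %s: %d cycles (%d fragment(s) dropped), short ~%.3f s, long ~%.3f s\n",
              x$individual_id, nrow(x$t), x$diagnostics$n_dropped_fragments,
              x$diagnostics$short_mean, x$diagnostics$long_mean))
  invisible(x)
}
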