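#' Peaks of the within-individual ratio density
#'
#' Estimates a Gaussian kernel density of the ratios on a 512-point grid over
#' (0, 1) (Silverman's bandwidth rule by default) and returns the strict local
#' maxima whose height exceeds `min_prominence` times the maximum density.
#' Used for the per-individual peak ("lollipop") summaries: walk and trot
#' individuals typically show one peak near 1/2, canter individuals two or
#' three peaks near 1/3, 1/2 and 2/3.
#'
#' @param ratios A `ratio_seq` (one individual x gait) or numeric vector of
#'   ratios.
#' @param bw Bandwidth rule or value passed to [stats::density()] (default
#'   `"nrd0"`, Silverman).
#' @param min_prominence Minimum peak height as a fraction of the maximum
#'   density (default 0.05).
#' @param min_n Below this many ratios an empty peak set is returned with a
#'   warning (default 10).
#' @return An object of class `peak_set`: data frame with columns `position`
#'   and `height`, sorted by position, plus attributes `individual_id`, `gait`.
#' @export
find_density_peaks <- function(ratios, bw = "nrd0", min_prominence = 0.05,
                               min_n = 10) {
  if (inherits(ratios, "ratio_seq")) {
    id <- ratios$individual_id; gait <- ratios$gait; r <- ratios$r
  } else {
    id <- NA_character_; gait <- NA_character_; r <- as.numeric(ratios)
  }
  empty <- data.frame(position = numeric(0), height = numeric(0))
  if (length(r) < min_n) {
    warning(sprintf("only %d ratios (< %d); returning empty peak set",
                    length(r), min_n))
    return(structure(empty, class = c("peak_set", "data.frame"),
                     individual_id = id, gait = gait))
  }
  if (is.character(bw) && stats::sd(r) < 1e-12) {
    bw <- 0.005  # zero-variance input: fixed grid-scale bandwidth
  }
  d <- density(r, bw = bw, n = 512, from = 0, to = 1)
  pk <- pracma::findpeaks(d$y, nups = 1, ndowns = 1,
                          minpeakheight = min_prominence * max(d$y))
  out <- if (is.null(pk)) empty else {
    idx <- pk[, 2]
    data.frame(position = d$x[idx], height = d$y[idx])
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_set", "data.frame"),
            individual_id = id, gait = gait)
}
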