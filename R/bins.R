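# On-/off-integer ratio bin scheme. On-integer bins are acceptance ranges
# around the small-integer reference ratios 1/3 (1:2), 1/2 (1:1) and 2/3
# (2:1); off-integer bins are the flanking control ranges. All edges are
# reciprocals of denominators offset in steps of 0.25 from the integer-ratio
# denominators (3, 2, 1.5), mirrored around 1/2; exact fractions are used
# internally (printed decimals like 0.555 or 0.285 are display roundings).

#' Build the on-/off-integer ratio bin scheme
#'
#' Seven contiguous half-open bins tile the interval `[1/3.75, 1-1/3.75]`:
#' off, 1:2-on, off, 1:1-on, off, 2:1-on, off. On-bin edges are
#' `1/3.25`-`1/2.75` (1:2), `1/2.25`-`1-1/2.25` (1:1) and
#' `1-1/2.75`-`1-1/3.25` (2:1); off bins are centered at `1/3.5`, `1/2.5`,
#' `1-1/2.5` and `1-1/3.5`. Ratios outside the outermost edges belong to no
#' category.
#'
#' @return An object of class `bin_scheme`: a data frame with columns `bin`
#'   (label), `kind` (`"on"`/`"off"`), `category` (`"1:2"`, `"1:1"`, `"2:1"`
#'   or `NA` for off bins), `lower`, `upper`, `center`, `width`, plus
#'   attribute `reference` (the reference ratios 1/3, 1/2, 2/3).
#' @export
#' @examples
#' build_bin_scheme()
build_bin_scheme <- function() {
  lo <- function(d) 1 / d        # edges left of 1/2
  hi <- function(d) 1 - 1 / d    # mirrored edges right of 1/2
  edges <- c(lo(3.75), lo(3.25), lo(2.75), lo(2.25),
             hi(2.25), hi(2.75), hi(3.25), hi(3.75))
  centers <- c(lo(3.5), 1 / 3, lo(2.5), 1 / 2, hi(2.5), 2 / 3, hi(3.5))
  scheme <- data.frame(
    bin = c("off-1:2L", "1:2-on", "off-1:2/1:1", "1:1-on",
            "off-1:1/2:1", "2:1-on", "off-2:1U"),
    kind = c("off", "on", "off", "on", "off", "on", "off"),
    category = c(NA, "1:2", NA, "1:1", NA, "2:1", NA),
    lower = edges[1:7],
    upper = edges[2:8],
    center = centers,
    stringsAsFactors = FALSE
  )
  scheme$width <- scheme$upper - scheme$lower
  attr(scheme, "reference") <- c("1:2" = 1 / 3, "1:1" = 1 / 2, "2:1" = 2 / 3)
  class(scheme) <- c("bin_scheme", "data.frame")
  scheme
}

#' Classify ratios into scheme bins
#'
#' Bins are half-open `[lower, upper)`; only the final off bin is
#' upper-closed, so the bins tile the covered range with deterministic
#' tie-breaking at shared edges. Values outside the outermost edges map to
#' `"outside"`.
#'
#' @param r Numeric vector of ratios in (0, 1).
#' @param scheme A [build_bin_scheme()] result.
#' @return Character vector of bin labels (or `"outside"`), same length as `r`.
#' @export
#' @examples
#' classify_ratio(c(0.5, 0.35, 0.25), build_bin_scheme())
classify_ratio <- function(r, scheme = build_bin_scheme()) {
  stopifnot(is.numeric(r), all(r > 0 & r < 1))
  edges <- c(scheme$lower, scheme$upper[nrow(scheme)])
  idx <- findInterval(r, edges, rightmost.closed = TRUE, left.open = FALSE)
  out <- rep("outside", length(r))
  inside <- idx >= 1 & idx <= nrow(scheme)
  out[inside] <- scheme$bin[idx[inside]]
  out
}

#' Count ratios per individual and bin
#'
#' Tallies how many ratios of each sequence fall in each scheme bin,
#' carrying the bin widths needed as the count-model offset. Ratios outside
#' the covered range are excluded from the counts (they belong to no
#' category) but reported in the attribute `n_outside`.
#'
#' @param ratios A `ratio_seq` or a list of them.
#' @param scheme A [build_bin_scheme()] result.
#' @param by_phase Logical; additionally split canter counts by motion-cycle
#'   phase (`rk1`/`rk2`/`rk3`) when phase labels are present.
#' @return Data frame with columns `individual_id`, `gait`, (`phase`,) `bin`,
#'   `kind`, `count`, `width`; every individual x bin (x phase) combination is
#'   present, zero counts included.
#' @export
count_by_bin <- function(ratios, scheme = build_bin_scheme(), by_phase = FALSE) {
  if (inherits(ratios, "ratio_seq")) ratios <- list(ratios)
  if (!length(ratios)) stop_gr("empty ratio set",
                               class = "gaitrhythm_invalid_parameter")
  rows <- list(); n_outside <- 0L
  for (s in ratios) {
    stopifnot(inherits(s, "ratio_seq"))
    lab <- classify_ratio(s$r, scheme)
    n_outside <- n_outside + sum(lab == "outside")
    phase <- if (by_phase && !is.null(s$phase)) s$phase else
      rep(NA_character_, length(s$r))
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = s$individual_id, gait = s$gait, phase = phase,
      bin = lab, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[df$bin != "outside", , drop = FALSE]
  use_phase <- by_phase && any(!is.na(df$phase))
  tab_one <- function(d) {
    bins <- factor(d$bin, levels = scheme$bin)
    inds <- factor(d$individual_id, levels = unique(d$individual_id))
    if (use_phase) {
      ph <- factor(d$phase, levels = c("rk1", "rk2", "rk3"))
      out <- as.data.frame(table(individual_id = inds, phase = ph, bin = bins),
                           stringsAsFactors = FALSE)
    } else {
      out <- as.data.frame(table(individual_id = inds, bin = bins),
                           stringsAsFactors = FALSE)
      out$phase <- NA_character_
    }
    out$gait <- d$gait[1]
    out
  }
  tab <- do.call(rbind, lapply(split(df, df$gait), tab_one))
  rownames(tab) <- NULL
  names(tab)[names(tab) == "Freq"] <- "count"
  m <- match(tab$bin, scheme$bin)
  tab$kind <- scheme$kind[m]
  tab$width <- scheme$width[m]
  tab <- tab[, c("individual_id", "gait", "phase", "bin", "kind", "count",
                 "width")]
  attr(tab, "n_outside") <- n_outside
  attr(tab, "scheme") <- scheme
  tab
}

#' Export a bin scheme as JSON
#'
#' @param scheme A [build_bin_scheme()] result.
#' @param path Output path for a JSON audit dump.
#' @return `path`, invisibly.
#' @export
write_bin_scheme_json <- function(scheme, path) {
  x <- list(bins = as.data.frame(scheme),
            reference = as.list(attr(scheme, "reference")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
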