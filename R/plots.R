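# Base-graphics figures mirroring the standard presentations of footfall
# rhythm data: per-gait interval and ratio densities, ternary triplet plots,
# per-individual peak lollipops, and the 2-D embedding scatter.

gait_colors <- function() {
  setNames(hcl.colors(3, "Dark 3"), GAITS)
}

#' Density of inter-onset intervals per gait
#'
#' @param intervals List of `interval_seq` objects.
#' @param main Plot title.
#' @return Invisibly, the per-gait density objects.
#' @export
plot_interval_density <- function(intervals, main = "Inter-onset intervals") {
  gait_of <- vapply(intervals, `[[`, "", "gait")
  cols <- gait_colors()
  dens <- lapply(split(intervals, gait_of), function(xs) {
    density(unlist(lapply(xs, `[[`, "t")))
  })
  xl <- range(unlist(lapply(dens, `[[`, "x")))
  yl <- c(0, max(unlist(lapply(dens, `[[`, "y"))))
  plot(NA, xlim = xl, ylim = yl, xlab = expression(t[k] ~ "(s)"),
       ylab = "density", main = main)
  for (g in names(dens)) lines(dens[[g]], col = cols[[g]], lwd = 2)
  legend("topright", legend = names(dens), col = cols[names(dens)], lwd = 2,
         bty = "n")
  invisible(dens)
}

#' Density of rhythmic ratios per gait
#'
#' Vertical reference lines mark the small-integer ratios 1/3, 1/2, 2/3.
#'
#' @param ratios List of `ratio_seq` objects.
#' @param main Plot title.
#' @return Invisibly, the per-gait density objects.
#' @export
plot_ratio_density <- function(ratios, main = "Rhythmic ratios") {
  gait_of <- vapply(ratios, `[[`, "", "gait")
  cols <- gait_colors()
  dens <- lapply(split(ratios, gait_of), function(xs) {
    density(unlist(lapply(xs, `[[`, "r")), from = 0, to = 1, n = 512)
  })
  plot(NA, xlim = c(0.2, 0.8),
       ylim = c(0, max(unlist(lapply(dens, `[[`, "y")))),
       xlab = expression(r[k]), ylab = "density", main = main)
  abline(v = c(1 / 3, 1 / 2, 2 / 3), lty = 3, col = "grey50")
  for (g in names(dens)) lines(dens[[g]], col = cols[[g]], lwd = 2)
  legend("topright", legend = names(dens), col = cols[names(dens)], lwd = 2,
         bty = "n")
  invisible(dens)
}

ternary_xy <- function(p) {
  # p: matrix of proportions (rows sum to 100); axis order t1, t2, t3
  s <- p / rowSums(p)
  cbind(x = s[, 2] + s[, 3] / 2, y = s[, 3] * sqrt(3) / 2)
}

#' Ternary plot of adjacent-interval triplets
#'
#' Plots the relative proportions of three adjacent intervals on the
#' 2-simplex with reference points at 1:1:1, 1:1:2, 1:2:1 and 2:1:1.
#'
#' @param triplets A `triplet_table` (raw or normalized).
#' @param cex Point size.
#' @param main Plot title.
#' @return Invisibly, the plotted xy coordinates.
#' @export
plot_ternary <- function(triplets, cex = 0.3, main = "Interval triplets") {
  p <- as.matrix(triplets[, c("t1", "t2", "t3")])
  xy <- ternary_xy(p)
  cols <- gait_colors()[triplets$gait]
  plot(NA, xlim = c(0, 1), ylim = c(0, sqrt(3) / 2), asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = main)
  polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  refs <- rbind("1:1:1" = c(1, 1, 1), "1:1:2" = c(1, 1, 2),
                "1:2:1" = c(1, 2, 1), "2:1:1" = c(2, 1, 1))
  rxy <- ternary_xy(refs)
  points(xy, pch = 16, cex = cex, col = cols)
  points(rxy, pch = 3, col = "black")
  text(rxy, labels = rownames(refs), pos = 3, cex = 0.8)
  text(c(0, 1, 0.5), c(-0.03, -0.03, sqrt(3) / 2 + 0.03),
       labels = c(expression(t[k]), expression(t[k + 1]),
                  expression(t[k + 2])))
  invisible(xy)
}

#' Lollipop plot of per-individual ratio-density peaks
#'
#' One horizontal line per individual with a lollipop at each density peak;
#' dotted verticals mark 1/3, 1/2 and 2/3.
#'
#' @param peaks List of `peak_set` objects (one per individual x gait).
#' @param main Plot title.
#' @export
plot_peak_lollipop <- function(peaks, main = "Per-individual ratio peaks") {
  ids <- vapply(peaks, function(p) attr(p, "individual_id"), "")
  gaits <- vapply(peaks, function(p) attr(p, "gait"), "")
  cols <- gait_colors()
  yy <- seq_along(peaks)
  plot(NA, xlim = c(0.2, 0.8), ylim = range(yy) + c(-0.5, 0.5),
       xlab = expression(r[k] ~ "peak position"), ylab = "",
       yaxt = "n", main = main)
  axis(2, at = yy, labels = paste(ids, gaits), las = 1, cex.axis = 0.6)
  abline(v = c(1 / 3, 1 / 2, 2 / 3), lty = 3, col = "grey50")
  for (i in seq_along(peaks)) {
    pk <- peaks[[i]]
    if (!nrow(pk)) next
    segments(pk$position, i, pk$position, i + 0.3, col = cols[gaits[i]])
    points(pk$position, rep(i + 0.3, nrow(pk)), pch = 16,
           col = cols[gaits[i]])
  }
  invisible(NULL)
}

#' Scatter of the 2-D embedding colored by label
#'
#' @param embedding A [embed_triplets()] result.
#' @param color_by `"gait"` or `"individual"`.
#' @param cex Point size.
#' @export
plot_embedding <- function(embedding, color_by = c("gait", "individual"),
                           cex = 0.3) {
  color_by <- match.arg(color_by)
  lab <- factor(if (color_by == "gait") embedding$gait else
    embedding$individual_id)
  cols <- if (color_by == "gait") gait_colors()[levels(lab)] else
    setNames(hcl.colors(nlevels(lab), "Spectral"), levels(lab))
  plot(embedding$V1, embedding$V2, col = cols[as.character(lab)], pch = 16,
       cex = cex, xlab = "V1", ylab = "V2",
       main = paste("Embedding by", color_by))
  if (nlevels(lab) <= 6) {
    legend("topright", legend = levels(lab), col = cols, pch = 16, bty = "n")
  }
  invisible(NULL)
}

#' ROC curves of a classifier report
#'
#' @param report A [train_classifier()] result.
#' @export
plot_roc <- function(report) {
  rc <- roc_curves(report)
  cols <- hcl.colors(length(rc), "Dark 3")
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
       ylab = "True positive rate",
       main = paste("One-vs-rest ROC,", report$label_type))
  abline(0, 1, lty = 3, col = "grey50")
  for (i in seq_along(rc)) {
    lines(rc[[i]]$curve$fpr, rc[[i]]$curve$tpr, col = cols[i], lwd = 2)
  }
  legend("bottomright",
         legend = sprintf("%s (AUC %.3f)", names(rc),
                          vapply(rc, `[[`, 0, "auc")),
         col = cols, lwd = 2, bty = "n", cex = 0.8)
  invisible(NULL)
}
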