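# Accuracy and precision around isochrony. Accuracy is the per-ratio
# deviance |r_k - 0.5| of ratios inside the open isochrony window (0.4, 0.6);
# precision is the interquartile range of those in-window ratios per
# individual and gait (type-7 quantiles). Smaller is better for both.

#' Accuracy and precision of ratios around isochrony
#'
#' @param ratios A `ratio_seq` for one individual x gait.
#' @param window Open isochrony window (default `c(0.4, 0.6)`, endpoints
#'   excluded).
#' @return An object of class `isochrony_metrics`: list with
#'   `individual_id`, `gait`, `n_in_window`, `accuracy` (vector of
#'   |r - 0.5|), `precision` (scalar IQR, `NA` with a flag when fewer than 4
#'   in-window ratios), `window`.
#' @export
#' @examples
#' r <- compute_ratios(compute_intervals(
#'   footfall_recording("h", "trot", cumsum(c(0, rep(0.36, 9))))))
#' compute_isochrony_metrics(r)
compute_isochrony_metrics <- function(ratios, window = c(0.4, 0.6)) {
  stopifnot(inherits(ratios, "ratio_seq"))
  r_in <- ratios$r[ratios$r > window[1] & ratios$r < window[2]]
  if (!length(r_in)) {
    warning(sprintf("no ratios inside (%.2f, %.2f) for %s/%s",
                    window[1], window[2], ratios$individual_id, ratios$gait))
  }
  precision <- if (length(r_in) >= 4L) {
    IQR(r_in, type = 7)
  } else NA_real_
  structure(
    list(individual_id = ratios$individual_id, gait = ratios$gait,
         n_in_window = length(r_in), r_in_window = r_in,
         accuracy = abs(r_in - 0.5), precision = precision,
         precision_defined = length(r_in) >= 4L, window = window),
    class = "isochrony_metrics"
  )
}

# AIC screen over candidate response families; infeasible candidates (e.g.
# gamma/log-normal when zeros are present) are excluded
screen_family <- function(x) {
  cand <- list()
  fd <- function(d) tryCatch(suppressWarnings(fitdistrplus::fitdist(x, d)),
                             error = function(e) NULL)
  cand$gaussian <- fd("norm")
  if (all(x > 0)) {
    cand$gamma <- fd("gamma")
    cand$lognormal <- fd("lnorm")
  }
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) return("gaussian")
  aics <- vapply(cand, function(f) f$aic, 0)
  names(which.min(aics))
}

#' Compare isochrony accuracy or precision across gaits
#'
#' Fits a hierarchical model with gait as fixed factor and individual random
#' intercept to either the per-ratio accuracy values or the per-individual
#' precision (IQR) values, after choosing the response family by an AIC
#' screen over feasible candidates (Gaussian; Gamma with log link and
#' Gaussian-on-log when the response is strictly positive). Returns the
#' full-vs-null LRT and Tukey-adjusted pairwise gait contrasts; the selected
#' family is recorded in the result.
#'
#' @param metrics List of [compute_isochrony_metrics()] results covering >= 2
#'   gaits and >= 2 individuals.
#' @param response `"accuracy"` or `"precision"`.
#' @return A `category_test` whose `label` names the response; positive
#'   `gaitA - gaitB` contrast estimates mean gait A has the larger (worse)
#'   response.
#' @export
compare_metrics_across_gaits <- function(metrics,
                                         response = c("accuracy", "precision")) {
  response <- match.arg(response)
  rows <- lapply(metrics, function(m) {
    stopifnot(inherits(m, "isochrony_metrics"))
    if (response == "accuracy") {
      if (!m$n_in_window) return(NULL)
      data.frame(individual_id = m$individual_id, gait = m$gait,
                 y = m$accuracy, stringsAsFactors = FALSE)
    } else {
      if (!m$precision_defined) return(NULL)
      data.frame(individual_id = m$individual_id, gait = m$gait,
                 y = m$precision, stringsAsFactors = FALSE)
    }
  })
  d <- do.call(rbind, Filter(Negate(is.null), rows))
  if (length(unique(d$gait)) < 2L || length(unique(d$individual_id)) < 2L) {
    stop_gr("need >= 2 gaits and >= 2 individuals",
            class = "gaitrhythm_invalid_parameter")
  }
  d$gait <- factor(d$gait, levels = intersect(GAITS, unique(d$gait)))
  d$individual_id <- factor(d$individual_id)
  fam_name <- screen_family(d$y)
  notes <- sprintf("family screen selected '%s' for %s", fam_name, response)
  if (fam_name == "lognormal") {
    d$y <- log(d$y)
    fam <- stats::gaussian()
    notes <- c(notes, "modeled on the log scale")
  } else if (fam_name == "gamma") {
    fam <- stats::Gamma(link = "log")
  } else {
    fam <- stats::gaussian()
  }
  fit_one <- function(fml) tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(fml, data = d, family = fam)),
    error = function(e) stop_gr("model fit failed: ", conditionMessage(e),
                                class = "gaitrhythm_fit"))
  full <- fit_one(y ~ gait + (1 | individual_id))
  null <- fit_one(y ~ 1 + (1 | individual_id))
  lrt <- lrt_vs_null(full, null)
  ctr <- tukey_contrasts(full, ~gait, d)
  category_test(response, fam_name, lrt, ctr, ctr, notes, full, null)
}

#' Tabulate isochrony metrics
#'
#' @param metrics List of [compute_isochrony_metrics()] results.
#' @return Data frame with one row per individual x gait: `individual_id`,
#'   `gait`, `n_in_window`, `mean_accuracy`, `precision`.
#' @export
isochrony_metrics_table <- function(metrics) {
  do.call(rbind, lapply(metrics, function(m) data.frame(
    individual_id = m$individual_id, gait = m$gait,
    n_in_window = m$n_in_window,
    mean_accuracy = if (m$n_in_window) mean(m$accuracy) else NA_real_,
    precision = m$precision, stringsAsFactors = FALSE)))
}

#' @export
print.isochrony_metrics <- function(x, ...) {
  cat(sprintf("<isochrony_metrics> %s / %s: %d in-window ratios, mean |r-0.5| = %s, IQR = %s\n",
              x$individual_id, x$gait, x$n_in_window,
              if (x$n_in_window) sprintf("%.4f", mean(x$accuracy)) else "NA",
              if (x$precision_defined) sprintf("%.4f", x$precision) else "NA"))
  invisible(x)
}
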