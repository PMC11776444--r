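# Tests of small-integer rhythmic categories: hierarchical count models over
# the on-/off-integer bins with a log bin-width offset, likelihood-ratio
# tests of the full model against a null with only the random intercept and
# offset, and Tukey-adjusted pairwise bin contrasts.

# pool each category's two flanking off bins into its "off" factor level
pool_onoff_counts <- function(counts, scheme = attr(counts, "scheme") %||%
                                build_bin_scheme()) {
  pooling <- list(
    "12" = list(on = "1:2-on", off = c("off-1:2L", "off-1:2/1:1")),
    "11" = list(on = "1:1-on", off = c("off-1:2/1:1", "off-1:1/2:1")),
    "21" = list(on = "2:1-on", off = c("off-1:1/2:1", "off-2:1U"))
  )
  rows <- list()
  for (cat in names(pooling)) {
    p <- pooling[[cat]]
    for (lev in c("off", "on")) {
      sel <- counts[counts$bin %in% p[[lev]], , drop = FALSE]
      agg <- aggregate(count ~ individual_id, data = sel, FUN = sum)
      agg$bin <- paste0(lev, cat)
      agg$width <- sum(scheme$width[match(p[[lev]], scheme$bin)])
      rows[[length(rows) + 1L]] <- agg
    }
  }
  out <- do.call(rbind, rows)
  out$bin <- factor(out$bin, levels = c("off12", "on12", "off11", "on11",
                                        "off21", "on21"))
  out$individual_id <- factor(out$individual_id)
  out
}

# glmmTMB fit with graceful degradation: a boundary negative-binomial fit
# (non-PD Hessian, typical when counts are equidispersed) is refit as
# Poisson, and a failing mixed fit falls back to a fixed-effects glm
fit_count_glmm <- function(formula_mixed, formula_fixed, data, family, notes) {
  fam_obj <- function(f) if (f == "nbinom") glmmTMB::nbinom2() else stats::poisson()
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(formula_mixed, data = data,
                                      family = fam_obj(family))),
    error = function(e) e
  )
  if (!inherits(fit, "error") && family == "nbinom" &&
      !isTRUE(fit$sdr$pdHess)) {
    notes <- c(notes, "negative-binomial fit hit the dispersion boundary; refit as Poisson")
    family <- "poisson"
    fit <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(formula_mixed, data = data,
                                        family = fam_obj(family))),
      error = function(e) e
    )
  }
  if (inherits(fit, "error") || !isTRUE(fit$sdr$pdHess)) {
    notes <- c(notes,
               "mixed fit unavailable; degraded to fixed-effects count model")
    glm_fam <- if (family == "nbinom") stats::poisson() else fam_obj(family)
    fit <- stats::glm(formula_fixed, data = data, family = glm_fam)
  }
  list(fit = fit, family = family, notes = notes)
}

lrt_vs_null <- function(full, null) {
  df <- as.integer(abs(attr(logLik(full), "df") - attr(logLik(null), "df")))
  chisq <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

tukey_contrasts <- function(fit, spec, data) {
  emm <- suppressMessages(emmeans::emmeans(fit, spec, data = data,
                                           nesting = NULL))
  ctr <- suppressMessages(suppressWarnings(tryCatch(
    summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey")),
    error = function(e)
      summary(emmeans::contrast(emm, method = "pairwise", adjust = "holm"))
  )))
  data.frame(contrast = as.character(ctr$contrast), estimate = ctr$estimate,
             SE = ctr$SE, z_ratio = ctr$estimate / ctr$SE,
             p_adj = ctr$p.value, stringsAsFactors = FALSE)
}

# Wald machinery breaks down under complete (or near-complete) separation:
# a bin level with no counts anywhere sends its coefficient and SE to
# infinity, so the Tukey z-test returns NaN or p ~ 1 even when the evidence
# is overwhelming. For any key on-vs-off contrast whose Wald summary is
# degenerate, fall back to the exact conditional rate test: given the two
# cells' total count n, the off-cell count is Binomial(n, w_off/(w_off+w_on))
# under equal rates. Bonferroni-adjusted over the contrast family; the
# estimate is the observed log rate ratio (floored at one pseudo-event).
rescue_degenerate_contrasts <- function(key, ctr, d, fit, family, lev_var,
                                        notes) {
  degen <- !is.finite(key$SE) | !is.finite(key$p_adj) | key$SE > 50
  if (!any(degen)) return(list(key = key, notes = notes))
  for (i in which(degen)) {
    levs <- trimws(strsplit(key$contrast[i], " - ", fixed = TRUE)[[1]])
    cell <- function(lv) {
      sel <- as.character(d[[lev_var]]) == lv
      c(count = sum(d$count[sel]), width = d$width[sel][1])
    }
    a <- cell(levs[1]); b <- cell(levs[2])
    n <- a["count"] + b["count"]
    p <- if (n == 0) 1 else {
      stats::binom.test(a["count"], n,
                        a["width"] / (a["width"] + b["width"]))$p.value
    }
    key$p_adj[i] <- min(1, p * nrow(ctr))
    rate_a <- max(a["count"], 0.5) / a["width"]
    rate_b <- max(b["count"], 0.5) / b["width"]
    key$estimate[i] <- if (n == 0) 0 else unname(log(rate_a / rate_b))
    key$SE[i] <- NA_real_
    key$z_ratio[i] <- NA_real_
    notes <- c(notes, sprintf(
      "contrast '%s' degenerate under Wald (empty cell); exact conditional rate test, Bonferroni x%d",
      key$contrast[i], nrow(ctr)))
  }
  list(key = key, notes = notes)
}

category_test <- function(label, family, lrt, contrasts, key, notes,
                          model, null_model, dispersion = NA_real_) {
  structure(
    list(label = label, family = family, chisq = lrt$chisq, df = lrt$df,
         p_value = lrt$p, contrasts = contrasts, key_contrasts = key,
         notes = notes, dispersion_ratio = dispersion,
         model = model, null_model = null_model),
    class = "category_test"
  )
}

#' Test rhythmic categories from on/off bin counts (walk / trot)
#'
#' Fits a hierarchical count model to per-individual bin counts with the
#' six-level bin factor (on and off levels for the 1:2, 1:1 and 2:1
#' categories; each off level pools the category's two flanking off bins),
#' an individual random intercept and a log bin-width offset. Significance of
#' the category structure is the likelihood-ratio test of this full model
#' against a null with only the random intercept and offset; bin contrasts
#' are Tukey-adjusted. A category is supported when its on level holds
#' significantly more ratios than its off level (negative `off - on`
#' estimate).
#'
#' @param counts Atomic-bin counts from [count_by_bin()] for one gait.
#' @param family `"nbinom"` (default, walk/trot) or `"poisson"`.
#' @return An object of class `category_test` with fields `chisq`, `df`,
#'   `p_value` (full vs null LRT), `contrasts` (all pairwise bin contrasts),
#'   `key_contrasts` (the three within-category `off - on` rows), `family`,
#'   `notes`, `dispersion_ratio` and the fitted models.
#' @export
fit_onoff_count_model <- function(counts, family = c("nbinom", "poisson")) {
  family <- match.arg(family)
  if (length(unique(counts$individual_id)) < 2L) {
    stop_gr("need >= 2 individuals", class = "gaitrhythm_invalid_parameter")
  }
  d <- pool_onoff_counts(counts)
  notes <- character(0)
  full <- fit_count_glmm(count ~ bin + (1 | individual_id) + offset(log(width)),
                         count ~ bin + offset(log(width)), d, family, notes)
  null <- fit_count_glmm(count ~ 1 + (1 | individual_id) + offset(log(width)),
                         count ~ 1 + offset(log(width)), d, full$family,
                         full$notes)
  notes <- unique(null$notes)
  # keep both routes comparable if either degraded to a fixed-effects glm
  if (inherits(full$fit, "glm") != inherits(null$fit, "glm")) {
    full <- fit_count_glmm(NULL, count ~ bin + offset(log(width)), d,
                           full$family, notes)
    null <- fit_count_glmm(NULL, count ~ 1 + offset(log(width)), d,
                           full$family, notes)
    notes <- unique(c(notes, full$notes))
  }
  lrt <- lrt_vs_null(full$fit, null$fit)
  ctr <- tukey_contrasts(full$fit, ~bin, d)
  key <- ctr[ctr$contrast %in% c("off12 - on12", "off11 - on11",
                                 "off21 - on21"), , drop = FALSE]
  resc <- rescue_degenerate_contrasts(key, ctr, d, full$fit, full$family,
                                      "bin", notes)
  key <- resc$key; notes <- resc$notes
  disp <- if (full$family == "poisson") {
    sum(stats::residuals(full$fit, type = "pearson")^2) /
      stats::df.residual(full$fit)
  } else NA_real_
  category_test(unique(counts$gait)[1], full$family, lrt, ctr, key, notes,
                full$fit, null$fit, disp)
}

#' Test one rhythmic category across canter motion-cycle phases
#'
#' For a single category (1:2, 1:1 or 2:1), models the per-individual,
#' per-phase counts in the category's on bin and pooled flanking off bins
#' with bin, phase and their interaction as fixed factors, an individual
#' random intercept and a log-width offset (Poisson family). Returns the
#' full-vs-null LRT and the Tukey-adjusted `off - on` contrast.
#'
#' @param counts Phase-split counts from `count_by_bin(..., by_phase = TRUE)`
#'   on canter phase ratios.
#' @param category `"1:1"`, `"1:2"` or `"2:1"`.
#' @param family Count family (default `"poisson"`).
#' @return A `category_test`; `label` records the category.
#' @export
fit_canter_phase_model <- function(counts, category = c("1:1", "1:2", "2:1"),
                                   family = "poisson") {
  category <- match.arg(category)
  if (!any(!is.na(counts$phase))) {
    stop_gr("counts lack phase labels; use count_by_bin(..., by_phase = TRUE)",
            class = "gaitrhythm_invalid_parameter")
  }
  scheme <- attr(counts, "scheme") %||% build_bin_scheme()
  on_bin <- scheme$bin[match(category, scheme$category)]
  flank <- list("1:2" = c("off-1:2L", "off-1:2/1:1"),
                "1:1" = c("off-1:2/1:1", "off-1:1/2:1"),
                "2:1" = c("off-1:1/2:1", "off-2:1U"))[[category]]
  sel_on <- counts[counts$bin == on_bin, , drop = FALSE]
  sel_on$lev <- "on"; sel_on$w <- scheme$width[match(on_bin, scheme$bin)]
  sel_off <- counts[counts$bin %in% flank, , drop = FALSE]
  sel_off$lev <- "off"; sel_off$w <- sum(scheme$width[match(flank, scheme$bin)])
  d <- rbind(sel_on, sel_off)
  d <- aggregate(count ~ individual_id + phase + lev + w, data = d, FUN = sum)
  d$bin <- factor(d$lev, levels = c("off", "on"))
  d$phase <- factor(d$phase, levels = c("rk1", "rk2", "rk3"))
  d$individual_id <- factor(d$individual_id)
  d$width <- d$w
  notes <- character(0)
  full <- fit_count_glmm(
    count ~ bin * phase + (1 | individual_id) + offset(log(width)),
    count ~ bin * phase + offset(log(width)), d, family, notes)
  null <- fit_count_glmm(
    count ~ 1 + (1 | individual_id) + offset(log(width)),
    count ~ 1 + offset(log(width)), d, full$family, full$notes)
  notes <- unique(null$notes)
  if (inherits(full$fit, "glm") != inherits(null$fit, "glm")) {
    full <- fit_count_glmm(NULL, count ~ bin * phase + offset(log(width)), d,
                           full$family, notes)
    null <- fit_count_glmm(NULL, count ~ 1 + offset(log(width)), d,
                           full$family, notes)
    notes <- unique(c(notes, full$notes))
  }
  lrt <- lrt_vs_null(full$fit, null$fit)
  ctr <- tukey_contrasts(full$fit, ~bin, d)
  key <- ctr[ctr$contrast == "off - on", , drop = FALSE]
  resc <- rescue_degenerate_contrasts(key, ctr, d, full$fit, full$family,
                                      "bin", notes)
  key <- resc$key; notes <- resc$notes
  disp <- sum(stats::residuals(full$fit, type = "pearson")^2) /
    stats::df.residual(full$fit)
  category_test(paste0("canter ", category), full$family, lrt, ctr, key,
                notes, full$fit, null$fit, disp)
}

#' Compare per-individual median interval durations of two gaits
#'
#' Computes each individual's median inter-onset interval in both gaits and
#' compares them with a paired t-test (df = n - 1); Shapiro-Wilk statistics
#' for each gait's set of medians assess the normality assumption.
#'
#' @param walk,trot Lists of `interval_seq` objects covering the same
#'   individuals (argument names reflect the canonical comparison; any two
#'   gaits may be passed).
#' @return An object of class `duration_comparison` with per-individual
#'   medians, `t`, `df`, `p_value`, mean difference, and the two Shapiro-Wilk
#'   tests.
#' @export
compare_median_intervals <- function(walk, trot) {
  if (inherits(walk, "interval_seq")) walk <- list(walk)
  if (inherits(trot, "interval_seq")) trot <- list(trot)
  med <- function(xs) {
    v <- vapply(xs, function(s) median(s$t), 0)
    names(v) <- vapply(xs, `[[`, "", "individual_id")
    v
  }
  m1 <- med(walk); m2 <- med(trot)
  unpaired <- union(setdiff(names(m1), names(m2)), setdiff(names(m2), names(m1)))
  if (length(unpaired)) {
    stop_gr("individuals present in only one gait: ",
            paste(unpaired, collapse = ", "), class = "gaitrhythm_pairing")
  }
  m2 <- m2[names(m1)]
  d <- m1 - m2
  tt <- if (sd(d) == 0) {
    # zero-variance differences: t pinned to 0 (or +-Inf if offset)
    dbar <- mean(d)
    list(statistic = c(t = if (dbar == 0) 0 else sign(dbar) * Inf),
         parameter = c(df = length(m1) - 1L),
         p.value = if (dbar == 0) 1 else 0, estimate = dbar)
  } else {
    t.test(m1, m2, paired = TRUE)
  }
  structure(
    list(gaits = c(walk[[1]]$gait, trot[[1]]$gait),
         medians = data.frame(individual_id = names(m1), gait1 = unname(m1),
                              gait2 = unname(m2)),
         t = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
         p_value = tt$p.value, mean_difference = unname(tt$estimate),
         shapiro = list(
           gait1 = tryCatch(shapiro.test(m1), error = function(e) NULL),
           gait2 = tryCatch(shapiro.test(m2), error = function(e) NULL))),
    class = "duration_comparison"
  )
}

#' @export
print.category_test <- function(x, ...) {
  cat(sprintf("<category_test> %s (%s family)\n", x$label, x$family))
  cat(sprintf("  full vs null: Chisq = %.3f, df = %d, p = %.3g\n",
              x$chisq, x$df, x$p_value))
  if (nrow(x$key_contrasts)) {
    cat("  key contrasts:\n")
    print(format(x$key_contrasts, digits = 4), row.names = FALSE)
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.duration_comparison <- function(x, ...) {
  cat(sprintf("<duration_comparison> %s vs %s: t = %.3f, df = %d, p = %.3g\n",
              x$gaits[1], x$gaits[2], x$t, x$df, x$p_value))
  cat(sprintf("  mean median difference = %.4f s\n", x$mean_difference))
  invisible(x)
}
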