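# End-to-end analysis: from a set of footfall recordings to interval/ratio
# tables, bin counts, category tests, isochrony metrics and contrasts, and
# classifier reports. Stages fail independently: an error in one stage is
# recorded and the remaining stages still run.

#' Run the full rhythm analysis on a set of recordings
#'
#' Orchestrates the whole pipeline: inter-onset intervals and sliding
#' rhythmic ratios per recording; canter motion-cycle segmentation and phase
#' ratios; on/off-integer bin counts and the five category tests (walk, trot,
#' and canter per category across phases); the paired walk-trot median
#' interval comparison; per-individual isochrony accuracy/precision and their
#' across-gait contrasts; per-individual ratio density peaks; and (optionally)
#' the UMAP + random-forest gait and individual classifiers.
#'
#' @param recordings List of [footfall_recording()]s.
#' @param seed Integer seed governing the split/embedding randomness.
#' @param scheme Ratio bin scheme (default [build_bin_scheme()]).
#' @param run_classifier Logical; train the embedding + forests (the most
#'   expensive stage; default `TRUE`).
#' @param n_neighbors,min_dist UMAP parameters passed to [embed_triplets()].
#' @param n_trees Forest size passed to [train_classifier()].
#' @return An object of class `rhythm_report`; stage failures are collected
#'   in `$errors` instead of aborting the run.
#' @export
analyze_recordings <- function(recordings, seed = 1,
                               scheme = build_bin_scheme(),
                               run_classifier = TRUE, n_neighbors = 15,
                               min_dist = 0.1, n_trees = 1000) {
  stopifnot(length(recordings) > 0)
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  intervals <- lapply(recordings, compute_intervals)
  ratios <- lapply(intervals, compute_ratios)
  gait_of <- vapply(intervals, `[[`, "", "gait")

  canter_phase <- stage("canter_segmentation", {
    lapply(intervals[gait_of == "canter"], function(s)
      compute_canter_phase_ratios(segment_canter_cycles(s)))
  })

  counts <- list()
  tests <- list()
  for (g in c("walk", "trot")) {
    if (!any(gait_of == g)) next
    counts[[g]] <- count_by_bin(ratios[gait_of == g], scheme)
    tests[[g]] <- stage(paste0("category_", g),
                        fit_onoff_count_model(counts[[g]], family = "nbinom"))
  }
  if (!is.null(canter_phase) && length(canter_phase)) {
    counts$canter <- count_by_bin(canter_phase, scheme, by_phase = TRUE)
    for (cat in c("1:1", "1:2", "2:1")) {
      nm <- paste0("canter_", sub(":", "to", cat))
      tests[[nm]] <- stage(paste0("category_", nm),
                           fit_canter_phase_model(counts$canter, cat))
    }
  }

  duration <- stage("duration_comparison", {
    if (any(gait_of == "walk") && any(gait_of == "trot")) {
      compare_median_intervals(intervals[gait_of == "walk"],
                               intervals[gait_of == "trot"])
    } else NULL
  })

  # canter isochrony metrics use the sliding ratios, like the other gaits
  metrics <- stage("isochrony_metrics",
                   lapply(ratios, compute_isochrony_metrics))
  metric_tests <- list()
  if (!is.null(metrics)) {
    metric_tests$accuracy <- stage("metrics_accuracy",
      compare_metrics_across_gaits(metrics, "accuracy"))
    metric_tests$precision <- stage("metrics_precision",
      compare_metrics_across_gaits(metrics, "precision"))
  }

  peaks <- stage("density_peaks",
                 suppressWarnings(lapply(ratios, find_density_peaks)))

  embedding <- NULL; classifiers <- list()
  if (run_classifier) {
    embedding <- stage("embedding", {
      trip <- make_triplets(intervals)
      embed_triplets(trip, n_neighbors = n_neighbors, min_dist = min_dist,
                     seed = seed)
    })
    if (!is.null(embedding)) {
      classifiers$gait <- stage("classifier_gait",
        train_classifier(embedding, "gait", n_trees = n_trees, seed = seed))
      classifiers$individual <- stage("classifier_individual",
        train_classifier(embedding, "individual", n_trees = n_trees,
                         seed = seed))
    }
  }

  structure(
    list(seed = seed, scheme = scheme, intervals = intervals, ratios = ratios,
         canter_phase_ratios = canter_phase, counts = counts,
         category_tests = tests, duration_comparison = duration,
         isochrony = metrics, metric_tests = metric_tests, peaks = peaks,
         embedding = embedding, classifiers = classifiers, errors = errors),
    class = "rhythm_report"
  )
}

#' @export
print.rhythm_report <- function(x, ...) {
  cat(sprintf("<rhythm_report> %d recordings, seed %d\n", length(x$intervals),
              x$seed))
  for (t in x$category_tests) if (!is.null(t)) print(t)
  if (!is.null(x$duration_comparison)) print(x$duration_comparison)
  for (t in x$metric_tests) if (!is.null(t)) print(t)
  for (cl in x$classifiers) if (!is.null(cl)) print(cl)
  if (length(x$errors)) {
    cat("stage errors:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

#' Write the tables of a rhythm report to disk
#'
#' Serializes the report's contrast tables, bin counts, isochrony metrics and
#' classifier summaries as CSV/JSON under `outdir`, together with a manifest
#' recording the seed.
#'
#' @param report A [analyze_recordings()] result.
#' @param outdir Output directory (created if missing).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "rhythm_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  ctr_rows <- do.call(rbind, lapply(names(report$category_tests), function(nm) {
    t <- report$category_tests[[nm]]
    if (is.null(t)) return(NULL)
    cbind(model = nm, chisq = t$chisq, df = t$df, p = t$p_value,
          t$key_contrasts)
  }))
  if (!is.null(ctr_rows)) put_csv(ctr_rows, "category_tests.csv")
  for (nm in names(report$counts)) {
    put_csv(report$counts[[nm]], paste0("bin_counts_", nm, ".csv"))
  }
  if (!is.null(report$isochrony)) {
    put_csv(isochrony_metrics_table(report$isochrony), "isochrony_metrics.csv")
  }
  mt <- do.call(rbind, lapply(names(report$metric_tests), function(nm) {
    t <- report$metric_tests[[nm]]
    if (is.null(t)) return(NULL)
    cbind(model = nm, chisq = t$chisq, df = t$df, p = t$p_value, t$contrasts)
  }))
  if (!is.null(mt)) put_csv(mt, "metric_tests.csv")
  if (!is.null(report$embedding)) {
    put_csv(as.data.frame(report$embedding), "embedding.csv")
  }
  cls <- lapply(report$classifiers, function(cl) {
    if (is.null(cl)) return(NULL)
    list(label_type = cl$label_type, oob_error = cl$oob_error,
         accuracy = cl$accuracy, accuracy_test = cl$accuracy_test,
         auc = as.list(cl$auc),
         confusion = as.data.frame(cl$confusion))
  })
  p <- file.path(outdir, "classifiers.json")
  jsonlite::write_json(Filter(Negate(is.null), cls), p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, p)
  p <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(seed = report$seed, n_recordings = length(report$intervals),
         errors = report$errors, files = basename(written)),
    p, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, p)
  invisible(written)
}
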