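#' Write recordings to a long-format onset CSV
#'
#' One row per onset with columns `individual_id`, `gait`, `onset_s` (in that
#' order), the dialect consumed by [read_timeseries_csv()].
#'
#' @param recordings Nonempty list of [footfall_recording()]s (a single
#'   recording is accepted).
#' @param path Output path.
#' @return Number of data rows written, invisibly.
#' @export
write_timeseries_csv <- function(recordings, path) {
  if (inherits(recordings, "footfall_recording")) recordings <- list(recordings)
  if (!length(recordings)) {
    stop_gr("recordings must be nonempty", class = "gaitrhythm_invalid_parameter")
  }
  lapply(recordings, function(r) stopifnot(inherits(r, "footfall_recording")))
  df <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(individual_id = r$individual_id, gait = r$gait,
               onset_s = r$onsets, stringsAsFactors = FALSE)
  }))
  tryCatch(
    write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_gr("cannot write '", path, "': ",
                                conditionMessage(e), class = "gaitrhythm_io")
  )
  invisible(nrow(df))
}

#' Read recordings from a long-format onset CSV
#'
#' Expects a header `individual_id,gait,onset_s`. Rows are grouped by
#' (individual, gait) preserving first-appearance group order, and each
#' group's onsets are sorted ascending.
#'
#' @param path Input CSV path.
#' @return List of [footfall_recording()]s.
#' @export
read_timeseries_csv <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_gr("cannot read '", path, "': ",
                                             conditionMessage(e),
                                             class = "gaitrhythm_io"))
  need <- c("individual_id", "gait", "onset_s")
  if (!all(need %in% names(df))) {
    stop_gr("CSV must have columns ", paste(need, collapse = ", "),
            class = "gaitrhythm_format")
  }
  if (!nrow(df)) stop_gr("no data rows in '", path, "'",
                         class = "gaitrhythm_format")
  onset <- suppressWarnings(as.numeric(df$onset_s))
  bad <- which(!is.finite(onset) | onset < 0)
  if (length(bad)) {
    stop_gr("malformed onset_s at data line(s): ",
            paste(bad, collapse = ", "), class = "gaitrhythm_format")
  }
  key <- paste(df$individual_id, df$gait, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    footfall_recording(df$individual_id[idx[1]], df$gait[idx[1]],
                       sort(onset[idx]))
  })
}
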