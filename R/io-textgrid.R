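# Praat TextGrid point-tier IO. Both text dialects ("long" with `key = value`
# lines and the bare "short" format) are supported, as is UTF-8 / UTF-16
# byte-order-mark detection, since Praat emits all of these in the wild.

read_textgrid_lines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bom <- readBin(con, "raw", 2)
  close(con)
  on.exit()
  enc <- if (length(bom) == 2 &&
             ((bom[1] == as.raw(0xFE) && bom[2] == as.raw(0xFF)) ||
              (bom[1] == as.raw(0xFF) && bom[2] == as.raw(0xFE)))) {
    "UTF-16"
  } else {
    "UTF-8"
  }
  lines <- tryCatch(
    readLines(con <- file(path, encoding = enc), warn = FALSE),
    error = function(e) stop_gr("cannot decode TextGrid '", path, "': ",
                                conditionMessage(e),
                                class = "gaitrhythm_format"),
    finally = close(con)
  )
  # strip UTF-8 BOM if present
  if (length(lines) && startsWith(lines[1], "\ufeff")) {
    lines[1] <- sub("^\ufeff", "", lines[1])
  }
  lines
}

# parse all tiers out of a TextGrid, returning list(name=, class=, times=)
parse_textgrid <- function(lines) {
  if (!length(lines) || !grepl("ooTextFile", lines[1])) {
    stop_gr("not a Praat TextGrid text file", class = "gaitrhythm_format")
  }
  long <- any(grepl("^\\s*item\\s*\\[", lines))
  if (long) parse_textgrid_long(lines) else parse_textgrid_short(lines)
}

tg_num <- function(x) as.numeric(sub("^\\s*[^=]*=\\s*", "", x))
tg_str <- function(x) {
  m <- regmatches(x, regexpr('"[^"]*"', x))
  if (!length(m)) return("")
  substr(m, 2, nchar(m) - 1)
}

parse_textgrid_long <- function(lines) {
  item_at <- grep("^\\s*item\\s*\\[\\s*[0-9]+\\s*\\]", lines)
  if (!length(item_at)) return(list())
  bounds <- c(item_at, length(lines) + 1L)
  tiers <- list()
  for (i in seq_along(item_at)) {
    chunk <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    cls <- tg_str(chunk[grep("^\\s*class\\s*=", chunk)[1]])
    name <- tg_str(chunk[grep("^\\s*name\\s*=", chunk)[1]])
    times <- numeric(0)
    if (cls == "TextTier") {
      times <- tg_num(chunk[grep("^\\s*(number|time)\\s*=", chunk)])
    }
    tiers[[i]] <- list(name = name, class = cls, times = times)
  }
  tiers
}

parse_textgrid_short <- function(lines) {
  # short format: values on bare lines after the two header lines
  body <- lines[nzchar(trimws(lines))]
  # body: File type, Object class, xmin, xmax, <exists>, ntiers, then tiers
  ntier <- suppressWarnings(as.integer(body[6]))
  if (is.na(ntier)) stop_gr("malformed short TextGrid header",
                            class = "gaitrhythm_format")
  pos <- 7L
  tiers <- vector("list", ntier)
  for (i in seq_len(ntier)) {
    cls <- tg_str(body[pos]); name <- tg_str(body[pos + 1L])
    n <- as.integer(body[pos + 4L])
    pos <- pos + 5L
    times <- numeric(0)
    if (cls == "TextTier") {
      for (j in seq_len(n)) {
        times[j] <- as.numeric(body[pos])
        pos <- pos + 2L  # time line + mark line
      }
    } else {
      pos <- pos + 3L * n  # interval tier: xmin, xmax, text per interval
    }
    tiers[[i]] <- list(name = name, class = cls, times = times)
  }
  tiers
}

#' Read footfall onsets from a Praat TextGrid point tier
#'
#' Parses a Praat TextGrid (long or short text dialect, UTF-8 or UTF-16) and
#' extracts the event times of the named point tier, sorted ascending.
#' Interval tiers are ignored. Duplicate points closer than 1e-9 s are
#' collapsed to one event with a warning (annotation double-clicks).
#'
#' @param path Path to the TextGrid file.
#' @param tier_name Name of the point tier holding footfall onsets.
#' @param individual_id,gait Labels for the returned recording. `individual_id`
#'   defaults to the file name without extension; `gait` defaults to
#'   `tier_name` when that is one of walk/trot/canter, otherwise it must be
#'   supplied.
#'
#' @return A [footfall_recording()].
#' @export
read_textgrid <- function(path, tier_name, individual_id = NULL, gait = NULL) {
  tiers <- parse_textgrid(read_textgrid_lines(path))
  names_all <- vapply(tiers, `[[`, "", "name")
  hit <- which(names_all == tier_name &
                 vapply(tiers, `[[`, "", "class") == "TextTier")
  if (!length(hit)) {
    stop_gr("point tier '", tier_name, "' not found (tiers present: ",
            paste(names_all, collapse = ", "), ")",
            class = "gaitrhythm_tier_not_found")
  }
  times <- sort(tiers[[hit[1]]]$times)
  dup <- which(diff(times) < 1e-9) + 1L
  if (length(dup)) {
    warning(sprintf("collapsed %d duplicate point(s) within 1e-9 s", length(dup)))
    times <- times[-dup]
  }
  individual_id <- individual_id %||% tools::file_path_sans_ext(basename(path))
  gait <- gait %||% (if (tier_name %in% GAITS) tier_name else
    stop_gr("gait not deducible from tier name '", tier_name,
            "'; pass gait explicitly", class = "gaitrhythm_invalid_parameter"))
  footfall_recording(individual_id, gait, times)
}

#' Write a recording as a Praat TextGrid point tier
#'
#' Emits a long-format UTF-8 TextGrid with a single point tier whose points
#' are the recording's onsets (marks left empty).
#'
#' @param rec A [footfall_recording()].
#' @param path Output path.
#' @param tier_name Name for the point tier (default: the gait label).
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(rec, path, tier_name = rec$gait) {
  stopifnot(inherits(rec, "footfall_recording"))
  xmax <- max(rec$onsets) + 1e-3
  n <- length(rec$onsets)
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0 ",
    sprintf("xmax = %.6f ", xmax),
    "tiers? <exists> ",
    "size = 1 ",
    "item []: ",
    "    item [1]:",
    '        class = "TextTier" ',
    sprintf('        name = "%s" ', tier_name),
    "        xmin = 0 ",
    sprintf("        xmax = %.6f ", xmax),
    sprintf("        points: size = %d ", n),
    unlist(lapply(seq_len(n), function(i) c(
      sprintf("        points [%d]:", i),
      sprintf("            number = %.6f ", rec$onsets[i]),
      '            mark = "" '
    )))
  )
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
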