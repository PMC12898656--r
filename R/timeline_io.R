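#' Read time-aligned token sequences from a CTM file
#'
#' CTM is the standard textual exchange format for time-aligned recognizer
#' output: one token per line,
#' `<utterance-id> <channel> <start> <duration> <label>`, times in
#' seconds. Lines starting with `#` and blank lines are ignored. One
#' `speech_timeline` is returned per utterance id, with token categories
#' assigned through `map`.
#'
#' @param path path to a CTM file.
#' @param map a [label_map()].
#' @return A list of unnormalized [speech_timeline()] objects, one per
#'   utterance id, in order of first appearance.
#' @examples
#' f <- tempfile(fileext = ".ctm")
#' writeLines(c("s1 1 0.00 0.30 a", "s1 1 0.30 0.20 sil",
#'              "s1 1 0.50 0.25 b"), f)
#' read_ctm(f, label_map())
#' @export
read_ctm <- function(path, map = label_map()) {
  if (!file.exists(path)) {
    stop_speechtsp(sprintf("CTM file not found: %s", path),
                   "speechtsp_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(list())
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 5L)) {
    bad <- idx[which(nf < 5L)[1L]]
    stop_speechtsp(sprintf(
      "%s:%d: expected at least 5 whitespace-separated fields, got %d",
      path, bad, nf[which(nf < 5L)[1L]]), "speechtsp_parse_error")
  }
  utt <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  dur <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
  lab <- vapply(parts, `[[`, "", 5L)
  if (anyNA(start) || anyNA(dur)) {
    bad <- idx[which(is.na(start) | is.na(dur))[1L]]
    stop_speechtsp(sprintf("%s:%d: unparsable numeric field", path, bad),
                   "speechtsp_parse_error")
  }
  if (any(dur <= 0)) {
    bad <- idx[which(dur <= 0)[1L]]
    stop_speechtsp(sprintf("%s:%d: non-positive token duration", path, bad),
                   "speechtsp_parse_error")
  }
  tok <- data.frame(utt = utt, label = lab,
                    category = assign_category(lab, map),
                    start = start, end = start + dur)
  lapply(unique(utt), function(u) {
    speech_timeline(u, tok[tok$utt == u,
                           c("label", "category", "start", "end")])
  })
}

#' Write timelines to a CTM file
#'
#' Times are rendered with 3 decimal places; reading the file back with
#' [read_ctm()] reproduces labels, categories and times to that
#' precision.
#'
#' @param timelines a list of [speech_timeline()] objects (or a single
#'   one).
#' @param path output path.
#' @param channel channel field to write (default `1`).
#' @return `path`, invisibly.
#' @export
write_ctm <- function(timelines, path, channel = 1L) {
  if (inherits(timelines, "speech_timeline")) timelines <- list(timelines)
  lines <- lapply(timelines, function(tl) {
    tok <- tl$tokens
    if (nrow(tok) == 0L) return(character())
    ## round start and end first so rounded tokens still tile without
    ## overlap; the written duration is the difference of the rounded
    ## endpoints
    s3 <- round(tok$start, 3); e3 <- round(tok$end, 3)
    sprintf("%s %d %.3f %.3f %s", tl$subject_id, as.integer(channel),
            s3, e3 - s3, tok$label)
  })
  lines <- as.character(unlist(lines))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_speechtsp(
                    sprintf("cannot open '%s' for writing: %s",
                            path, conditionMessage(e)),
                    "speechtsp_io_error"))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read one interval tier of a Praat TextGrid
#'
#' Supports both the long ("full") and short text formats. Non-empty
#' interval labels become tokens categorized through `map`; intervals
#' with an empty (or whitespace-only) label are the phonetician's
#' convention for silence and become silent pauses. Filled pauses must be
#' explicit labels listed in the map.
#'
#' @param path path to a `.TextGrid` file.
#' @param tier_name name of the interval tier to read.
#' @param map a [label_map()].
#' @param subject_id subject identifier for the resulting timeline;
#'   defaults to the file name without extension.
#' @return An unnormalized [speech_timeline()].
#' @export
read_textgrid <- function(path, tier_name, map = label_map(),
                          subject_id = NULL) {
  if (!file.exists(path)) {
    stop_speechtsp(sprintf("TextGrid file not found: %s", path),
                   "speechtsp_io_error")
  }
  tiers <- parse_textgrid(path)
  names_avail <- vapply(tiers, `[[`, "", "name")
  hit <- which(names_avail == tier_name)
  if (length(hit) == 0L) {
    stop_speechtsp(sprintf(
      "tier '%s' not found in %s; available tiers: %s",
      tier_name, path, paste(sprintf("'%s'", names_avail), collapse = ", ")),
      "speechtsp_io_error")
  }
  tier <- tiers[[hit[1L]]]
  if (tier$class != "IntervalTier") {
    stop_speechtsp(sprintf(
      "tier '%s' is a %s; only interval tiers are supported",
      tier_name, tier$class), "speechtsp_io_error")
  }
  iv <- tier$intervals
  lab <- trimws(iv$text)
  keep <- iv$xmax > iv$xmin
  iv <- iv[keep, , drop = FALSE]; lab <- lab[keep]
  category <- assign_category(lab, map)
  category[lab == ""] <- "silent_pause"
  lab[lab == ""] <- "sil"
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  speech_timeline(subject_id,
                  data.frame(label = lab, category = category,
                             start = iv$xmin, end = iv$xmax))
}

## Minimal TextGrid text parser (long and short formats). Returns a list
## of tiers: list(name, class, intervals = data.frame(xmin, xmax, text)).
## No installed R package reads TextGrids, hence the hand parser; it is
## deliberately tolerant of indentation and line-ending variation.
#' @keywords internal
#' @noRd
parse_textgrid <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  long_format <- any(grepl("^item\\s*\\[", lines)) ||
    any(grepl("^(xmin|xmax)\\s*=", lines))
  if (long_format) parse_textgrid_long(lines) else parse_textgrid_short(lines)
}

tg_unquote <- function(x) gsub("\"\"", "\"", sub("^\"", "", sub("\"$", "", x)))

parse_textgrid_long <- function(lines) {
  num_of <- function(l) as.numeric(sub(".*=\\s*", "", l))
  str_of <- function(l) tg_unquote(trimws(sub("^[^=]*=\\s*", "", l)))
  item_at <- grep("^item\\s*\\[\\s*[0-9]", lines)
  tiers <- list()
  bounds <- c(item_at, length(lines) + 1L)
  for (k in seq_along(item_at)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    cls <- str_of(block[grep("^class\\s*=", block)[1L]])
    name <- str_of(block[grep("^name\\s*=", block)[1L]])
    if (cls == "IntervalTier") {
      xmin <- num_of(block[grep("^xmin\\s*=", block)])
      xmax <- num_of(block[grep("^xmax\\s*=", block)])
      text <- vapply(block[grep("^text\\s*=", block)], str_of, "",
                     USE.NAMES = FALSE)
      ## first xmin/xmax pair is the tier's own range
      iv <- data.frame(xmin = xmin[-1L], xmax = xmax[-1L], text = text)
    } else {
      iv <- data.frame(xmin = numeric(), xmax = numeric(),
                       text = character())
    }
    tiers[[k]] <- list(name = name, class = cls, intervals = iv)
  }
  tiers
}

parse_textgrid_short <- function(lines) {
  ## strip the 5-line header: file type, object class, xmin, xmax,
  ## <exists>, ntiers
  i <- grep("\"ooTextFile\"", lines)[1L]
  if (is.na(i)) stop_speechtsp("not a TextGrid file", "speechtsp_parse_error")
  pos <- i + 2L             # skip object class line
  pos <- pos + 2L           # global xmin, xmax consumed
  if (grepl("exists", lines[pos])) pos <- pos + 1L
  ntier <- as.integer(lines[pos]); pos <- pos + 1L
  tiers <- vector("list", ntier)
  for (k in seq_len(ntier)) {
    cls <- tg_unquote(lines[pos]); pos <- pos + 1L
    name <- tg_unquote(lines[pos]); pos <- pos + 1L
    pos <- pos + 2L         # tier xmin, xmax
    n <- as.integer(lines[pos]); pos <- pos + 1L
    if (cls == "IntervalTier") {
      xmin <- xmax <- numeric(n); text <- character(n)
      for (j in seq_len(n)) {
        xmin[j] <- as.numeric(lines[pos]); pos <- pos + 1L
        xmax[j] <- as.numeric(lines[pos]); pos <- pos + 1L
        text[j] <- tg_unquote(lines[pos]); pos <- pos + 1L
      }
      iv <- data.frame(xmin = xmin, xmax = xmax, text = text)
    } else {
      ## point tier: time + mark per point
      pos <- pos + 2L * n
      iv <- data.frame(xmin = numeric(), xmax = numeric(),
                       text = character())
    }
    tiers[[k]] <- list(name = name, class = cls, intervals = iv)
  }
  tiers
}
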