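#' Canonical temporal-speech-parameter names
#'
#' The fifteen parameters in their canonical reporting order: utterance
#' length, the two tempi, then occurrence rate, duration rate, frequency
#' and average duration for the silent / filled / total pause scopes.
#'
#' @return Character vector of length 15.
#' @export
tsp_names <- function() {
  c("utterance_length", "articulation_tempo", "speech_tempo",
    "silent_pause_occurrence_rate", "filled_pause_occurrence_rate",
    "total_pause_occurrence_rate",
    "silent_pause_duration_rate", "filled_pause_duration_rate",
    "total_pause_duration_rate",
    "silent_pause_frequency", "filled_pause_frequency",
    "total_pause_frequency",
    "silent_pause_average_duration", "filled_pause_average_duration",
    "total_pause_average_duration")
}

#' Compute the 15 temporal speech parameters of a timeline
#'
#' All parameters are direct evaluations of their defining formulas on a
#' normalized timeline:
#' \itemize{
#'   \item utterance length: last token end minus first token start (s);
#'   \item articulation tempo: phones per second of utterance time
#'     excluding pauses; speech tempo: phones per second including
#'     pauses;
#'   \item occurrence rate (per scope): pauses × 100 / phones (%);
#'   \item duration rate: pause time × 100 / utterance length (%);
#'   \item frequency: pauses / utterance length (1/s);
#'   \item average duration: pause time / pause count (s), `NA` when the
#'     scope has no pauses (never 0 — zero would bias group means).
#' }
#' Pause tokens never count as phones, and spans excluded from the pause
#' inventory by [normalize_timeline()] count as articulation time.
#'
#' @param tl a normalized [speech_timeline()] with at least one phone.
#' @return An object of class `tsp_vector`: a list with `tsp` (named
#'   numeric of length 15), the backing counts (`n_phones`,
#'   `n_silent_pauses`, `n_filled_pauses`) and pause times per scope.
#' @examples
#' cfg <- default_configs()
#' tl <- construct_timeline(sample_subject(cfg$control, seed = 1), seed = 2)
#' compute_tsp(tl)
#' @export
compute_tsp <- function(tl) {
  stopifnot(inherits(tl, "speech_timeline"))
  if (!isTRUE(tl$normalized)) {
    stop_speechtsp(sprintf(
      "timeline '%s' is not normalized; call normalize_timeline() first",
      tl$subject_id), "speechtsp_contract_error")
  }
  tok <- tl$tokens
  dur <- tok$end - tok$start
  n_phones <- sum(tok$category == "phone")
  if (n_phones < 1L) {
    stop_speechtsp(sprintf("timeline '%s' has no phone tokens",
                           tl$subject_id), "speechtsp_degenerate_error")
  }
  U <- max(tok$end) - min(tok$start)
  sil <- tok$category == "silent_pause"
  fil <- tok$category == "filled_pause"
  n_s <- sum(sil); n_f <- sum(fil); n_t <- n_s + n_f
  p_s <- sum(dur[sil]); p_f <- sum(dur[fil]); p_t <- p_s + p_f

  avg <- function(p, n) if (n > 0L) p / n else NA_real_
  tsp <- c(
    utterance_length = U,
    articulation_tempo = n_phones / (U - p_t),
    speech_tempo = n_phones / U,
    silent_pause_occurrence_rate = n_s * 100 / n_phones,
    filled_pause_occurrence_rate = n_f * 100 / n_phones,
    total_pause_occurrence_rate = n_t * 100 / n_phones,
    silent_pause_duration_rate = p_s * 100 / U,
    filled_pause_duration_rate = p_f * 100 / U,
    total_pause_duration_rate = p_t * 100 / U,
    silent_pause_frequency = n_s / U,
    filled_pause_frequency = n_f / U,
    total_pause_frequency = n_t / U,
    silent_pause_average_duration = avg(p_s, n_s),
    filled_pause_average_duration = avg(p_f, n_f),
    total_pause_average_duration = avg(p_t, n_t)
  )
  structure(list(tsp = tsp[tsp_names()],
                 n_phones = n_phones,
                 n_silent_pauses = n_s, n_filled_pauses = n_f,
                 silent_pause_time = p_s, filled_pause_time = p_f,
                 total_pause_time = p_t),
            class = "tsp_vector")
}

#' @export
print.tsp_vector <- function(x, digits = 3, ...) {
  cat(sprintf("Temporal speech parameters (%d phones, %d silent + %d filled pauses)\n",
              x$n_phones, x$n_silent_pauses, x$n_filled_pauses))
  print(round(x$tsp, digits))
  invisible(x)
}

#' Build a per-subject feature table
#'
#' One row per subject, the 15 temporal parameters in canonical column
#' order plus `subject_id` and `group`. Undefined average durations
#' (pause-free scopes) are `NA`, serialized as empty cells by
#' [write_feature_table()].
#'
#' @param timelines list of normalized [speech_timeline()] objects with
#'   unique subject ids.
#' @return A `data.frame` of class `tsp_feature_table`.
#' @export
build_feature_table <- function(timelines) {
  if (inherits(timelines, "speech_timeline")) timelines <- list(timelines)
  ids <- vapply(timelines, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) {
    stop_speechtsp(sprintf("duplicate subject ids: %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                   "speechtsp_validation_error")
  }
  rows <- lapply(timelines, function(tl) {
    v <- compute_tsp(tl)
    cbind(data.frame(subject_id = tl$subject_id,
                     group = if (is.null(tl$group)) NA_character_ else tl$group),
          as.data.frame(as.list(v$tsp)))
  })
  ft <- do.call(rbind, rows)
  rownames(ft) <- NULL
  class(ft) <- c("tsp_feature_table", "data.frame")
  ft
}

#' Write / read a feature table as CSV
#'
#' Fixed header: `subject_id`, `group`, then [tsp_names()]. Missing cells
#' are empty.
#'
#' @param ft a feature table from [build_feature_table()].
#' @param path CSV path.
#' @return `path` (write) or the feature table (read).
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(ft, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("subject_id", "group", tsp_names()), names(ft))
  if (length(missing_cols) > 0L) {
    stop_speechtsp(sprintf("feature table %s lacks columns: %s", path,
                           paste(missing_cols, collapse = ", ")),
                   "speechtsp_validation_error")
  }
  class(ft) <- c("tsp_feature_table", "data.frame")
  ft
}
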