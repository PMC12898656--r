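#' Time-aligned speech timeline
#'
#' A `speech_timeline` is the ordered, time-stamped token sequence a
#' phone-level recognizer produces for one subject's recording: phones,
#' silent pauses and filled pauses, each with start and end times in
#' seconds. It is the unit of input for [compute_tsp()].
#'
#' Tokens must be strictly positive in duration, sorted by start time and
#' non-overlapping (token i ends at or before token i+1 starts). Gaps of
#' unlabeled time between consecutive tokens are permitted on input and
#' are converted to silent pauses by [normalize_timeline()].
#'
#' @param subject_id identifier for the speaker/utterance.
#' @param tokens data frame with columns `label` (character), `category`
#'   (one of `"phone"`, `"silent_pause"`, `"filled_pause"`), `start`,
#'   `end` (seconds).
#' @param group optional group label (e.g. `"control"`, `"aud"`).
#' @param normalized logical; `TRUE` only for timelines produced by
#'   [normalize_timeline()] (or constructed in already-normalized form).
#'
#' @return An object of class `speech_timeline`.
#' @seealso [normalize_timeline()], [read_ctm()], [read_textgrid()]
#' @export
speech_timeline <- function(subject_id, tokens, group = NULL,
                            normalized = FALSE) {
  tl <- structure(list(subject_id = as.character(subject_id),
                       group = if (is.null(group)) NULL else as.character(group),
                       tokens = as.data.frame(tokens),
                       normalized = isTRUE(normalized)),
                  class = "speech_timeline")
  validate_timeline(tl)
}

TOKEN_CATEGORIES <- c("phone", "silent_pause", "filled_pause", "excluded_pause")

#' @keywords internal
#' @noRd
validate_timeline <- function(tl) {
  tok <- tl$tokens
  need <- c("label", "category", "start", "end")
  if (!all(need %in% names(tok))) {
    stop_speechtsp(sprintf("timeline '%s': token columns must include %s",
                           tl$subject_id, paste(need, collapse = ", ")),
                   "speechtsp_validation_error")
  }
  if (nrow(tok) == 0L) return(tl)
  if (!all(tok$category %in% TOKEN_CATEGORIES)) {
    bad <- setdiff(unique(tok$category), TOKEN_CATEGORIES)
    stop_speechtsp(sprintf("timeline '%s': unknown token category: %s",
                           tl$subject_id, paste(bad, collapse = ", ")),
                   "speechtsp_validation_error")
  }
  if (any(!is.finite(tok$start)) || any(!is.finite(tok$end))) {
    stop_speechtsp(sprintf("timeline '%s': non-finite token times",
                           tl$subject_id), "speechtsp_validation_error")
  }
  if (any(tok$end <= tok$start)) {
    i <- which(tok$end <= tok$start)[1L]
    stop_speechtsp(sprintf(
      "timeline '%s': token %d ('%s') has non-positive duration (%.4f-%.4f)",
      tl$subject_id, i, tok$label[i], tok$start[i], tok$end[i]),
      "speechtsp_validation_error")
  }
  ord <- order(tok$start, tok$end)
  tok <- tok[ord, , drop = FALSE]
  rownames(tok) <- NULL
  if (nrow(tok) > 1L) {
    overlap <- tok$start[-1L] < tok$end[-nrow(tok)] - 1e-9
    if (any(overlap)) {
      i <- which(overlap)[1L]
      stop_speechtsp(sprintf(
        "timeline '%s': tokens %d and %d overlap (%.4f > %.4f)",
        tl$subject_id, i, i + 1L, tok$end[i], tok$start[i + 1L]),
        "speechtsp_validation_error")
    }
  }
  tl$tokens <- tok
  tl
}

#' Normalize the pause structure of a timeline
#'
#' Prepares a raw alignment for temporal-parameter computation:
#' \enumerate{
#'   \item unlabeled gaps between consecutive tokens become silent pauses;
#'   \item runs of adjacent silent pauses are merged into one;
#'   \item if `trim_edges`, leading and trailing silent pauses are deleted
#'     entirely (they shrink the utterance — lead-in/out silence is a
#'     recording artifact, not speech planning);
#'   \item internal silent pauses shorter than `min_pause_s` are removed
#'     from the pause inventory: their span stays inside the utterance
#'     (and counts as articulation time) but contributes to no pause
#'     statistic.
#' }
#' The operation is idempotent: normalizing a normalized timeline returns
#' it unchanged.
#'
#' @param tl a [speech_timeline()].
#' @param min_pause_s minimum silent-pause duration in seconds (default
#'   0.03 s, one step beyond a typical 10 ms recognizer hop).
#' @param trim_edges drop leading/trailing silence (default `TRUE`).
#' @return A normalized `speech_timeline`.
#' @examples
#' tok <- data.frame(label = c("sil", "a", "sil", "sil", "b", "sil"),
#'                   category = c("silent_pause", "phone", "silent_pause",
#'                                "silent_pause", "phone", "silent_pause"),
#'                   start = c(0, 0.2, 0.5, 0.8, 1.0, 1.6),
#'                   end   = c(0.2, 0.5, 0.8, 1.0, 1.6, 2.1))
#' normalize_timeline(speech_timeline("s1", tok))
#' @export
normalize_timeline <- function(tl, min_pause_s = 0.03, trim_edges = TRUE) {
  stopifnot(inherits(tl, "speech_timeline"))
  if (isTRUE(tl$normalized)) return(tl)
  tok <- tl$tokens

  ## 1. fill unlabeled gaps with silent pauses
  if (nrow(tok) > 1L) {
    gap <- which(tok$start[-1L] - tok$end[-nrow(tok)] > 1e-6)
    if (length(gap) > 0L) {
      fills <- data.frame(label = "sil", category = "silent_pause",
                          start = tok$end[gap], end = tok$start[gap + 1L])
      tok <- rbind(tok, fills)
      tok <- tok[order(tok$start), , drop = FALSE]
    }
  }

  ## 2. merge adjacent silent pauses
  if (nrow(tok) > 1L) {
    sil <- tok$category == "silent_pause"
    run_start <- sil & !c(FALSE, sil[-length(sil)])
    run_id <- cumsum(run_start)
    run_id[!sil] <- 0L
    keep <- rep(TRUE, nrow(tok))
    for (r in setdiff(unique(run_id), 0L)) {
      idx <- which(run_id == r)
      if (length(idx) > 1L) {
        tok$end[idx[1L]] <- tok$end[idx[length(idx)]]
        keep[idx[-1L]] <- FALSE
      }
    }
    tok <- tok[keep, , drop = FALSE]
  }

  ## 3. trim edge silences
  if (trim_edges && nrow(tok) > 0L) {
    while (nrow(tok) > 0L && tok$category[1L] == "silent_pause")
      tok <- tok[-1L, , drop = FALSE]
    while (nrow(tok) > 0L && tok$category[nrow(tok)] == "silent_pause")
      tok <- tok[-nrow(tok), , drop = FALSE]
  }

  ## 4. sub-threshold silences leave the pause inventory
  short <- tok$category == "silent_pause" & (tok$end - tok$start) < min_pause_s
  tok$category[short] <- "excluded_pause"

  if (sum(tok$category == "phone") == 0L) {
    stop_speechtsp(sprintf(
      "timeline '%s': no phone tokens remain after normalization",
      tl$subject_id), "speechtsp_degenerate_error")
  }
  rownames(tok) <- NULL
  tl$tokens <- tok
  tl$normalized <- TRUE
  validate_timeline(tl)
}

#' @export
print.speech_timeline <- function(x, ...) {
  tok <- x$tokens
  cat(sprintf("Speech timeline '%s'%s: %d tokens%s\n", x$subject_id,
              if (is.null(x$group)) "" else sprintf(" [%s]", x$group),
              nrow(tok),
              if (x$normalized) " (normalized)" else ""))
  if (nrow(tok) > 0L) {
    n <- table(factor(tok$category, levels = TOKEN_CATEGORIES))
    cat(sprintf("  span %.3f-%.3f s | phones %d, silent %d, filled %d\n",
                min(tok$start), max(tok$end),
                n[["phone"]], n[["silent_pause"]], n[["filled_pause"]]))
  }
  invisible(x)
}
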