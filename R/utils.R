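## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_speechtsp <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "speechtsp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

## FNV-1a 32-bit hash over a character string, kept below 2^31 so the
## result is always a valid R integer seed. Used for provenance hashes
## and per-subject RNG substreams.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    ## 32-bit modular multiply by the FNV prime 16777619, in doubles
    h <- (h * 16777619) %% 2^32
  }
  as.integer(h %% 2^31)
}

## Stable substream seed for subject `index` of group `group` under
## master seed `seed`; reordering subjects or groups never changes a
## subject's own stream.
subject_seed <- function(seed, group, index) {
  as.integer((fnv1a32(paste(seed, group, index, sep = "\r")) +
                as.double(index)) %% 2^31)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
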