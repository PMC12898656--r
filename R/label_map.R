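#' Map recognizer labels to pause categories
#'
#' A phone-level recognizer emits silence and hesitation vocalizations as
#' ordinary labeled tokens. A `label_map` binds the recognizer's symbol
#' inventory to the three categories the temporal analysis distinguishes:
#' `phone`, `silent_pause` and `filled_pause`. Category assignment always
#' goes through a label map; it is never guessed from the label string.
#'
#' @param silent_labels character vector of labels denoting silent pauses.
#' @param filled_labels character vector of labels denoting filled pauses
#'   (hesitations such as "umm"). Must be disjoint from `silent_labels`.
#' @param default_category category assigned to any other label; almost
#'   always `"phone"`.
#'
#' @return An object of class `tsp_label_map`.
#' @examples
#' lm <- label_map(silent_labels = "sil", filled_labels = c("fp", "hes"))
#' assign_category(c("a", "sil", "fp"), lm)
#' @export
label_map <- function(silent_labels = c("sil", "sp", "pau", "<sil>"),
                      filled_labels = c("fp", "hes", "um", "uh", "ööö"),
                      default_category = "phone") {
  silent_labels <- as.character(silent_labels)
  filled_labels <- as.character(filled_labels)
  if (length(intersect(silent_labels, filled_labels)) > 0L) {
    stop_speechtsp(
      sprintf("silent and filled label sets overlap: %s",
              paste(intersect(silent_labels, filled_labels), collapse = ", ")),
      "speechtsp_labelmap_error")
  }
  default_category <- match.arg(default_category,
                                c("phone", "silent_pause", "filled_pause"))
  structure(list(silent_labels = silent_labels,
                 filled_labels = filled_labels,
                 default_category = default_category),
            class = "tsp_label_map")
}

#' Read a label map from a YAML config file
#'
#' The file holds up to three keys: `silent_labels`, `filled_labels`
#' (sequences of strings) and `default_category` (a string). Missing keys
#' fall back to the [label_map()] defaults.
#'
#' @param path path to a YAML file.
#' @return A `tsp_label_map`.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) {
    stop_speechtsp(sprintf("label map file not found: %s", path),
                   "speechtsp_io_error")
  }
  cfg <- yaml::read_yaml(path)
  defaults <- label_map()
  label_map(
    silent_labels = cfg$silent_labels %||% defaults$silent_labels,
    filled_labels = cfg$filled_labels %||% defaults$filled_labels,
    default_category = cfg$default_category %||% defaults$default_category
  )
}

#' Assign token categories via a label map
#'
#' @param labels character vector of recognizer labels.
#' @param map a [label_map()].
#' @return character vector over `{"phone","silent_pause","filled_pause"}`.
#' @export
assign_category <- function(labels, map) {
  stopifnot(inherits(map, "tsp_label_map"))
  out <- rep(map$default_category, length(labels))
  out[labels %in% map$silent_labels] <- "silent_pause"
  out[labels %in% map$filled_labels] <- "filled_pause"
  out
}

#' @export
print.tsp_label_map <- function(x, ...) {
  cat("Label map\n")
  cat("  silent:", paste(x$silent_labels, collapse = " "), "\n")
  cat("  filled:", paste(x$filled_labels, collapse = " "), "\n")
  cat("  default category:", x$default_category, "\n")
  invisible(x)
}
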