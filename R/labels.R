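#' The six-behavior ethogram
#'
#' The behavior catalogue scored by the pipeline: standing, lying, eating,
#' drinking, chin-resting (a cow resting its chin on another's hindquarters,
#' a pre-mounting estrus sign) and riding (mounting, the primary estrus
#' sign). A sentinel label `"unknown"` is used internally for frames before
#' a cow's first successful identity-behavior match; it never appears in
#' simulator ground truth.
#'
#' @param include_unknown if `TRUE`, append the `"unknown"` sentinel.
#' @return character vector of behavior labels.
#' @export
#' @examples
#' behavior_labels()
behavior_labels <- function(include_unknown = FALSE) {
  labs <- c("stand", "lie", "eat", "drink", "chin_rest", "ride")
  if (include_unknown) c(labs, "unknown") else labs
}

#' Estrus-related behaviors
#'
#' Riding and chin-resting are the two behaviors indicative of estrus; the
#' remaining four (stand, lie, eat, drink) are non-estrus. This split
#' defines the positive class of the binary evaluation.
#'
#' @return character vector of the two estrus-related behavior labels.
#' @export
estrus_behaviors <- function() c("chin_rest", "ride")

# sentinel used for pre-first-match timeline entries
.unknown <- "unknown"

.sources_view <- c("matched", "fallback_low_iou", "fallback_missing",
                   "initial_unknown")
.rules_fused <- c("top_override", "front_default", "single_view",
                  "both_unknown")
.views <- c("top", "front")
.kinds <- c("identity", "behavior")

.assert_behaviors <- function(x, allow_unknown = FALSE, what = "behavior") {
  ok <- behavior_labels(include_unknown = allow_unknown)
  bad <- setdiff(unique(x), ok)
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s label(s): %s (expected %s)", what,
                 paste(bad, collapse = ", "), paste(ok, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

.assert_view <- function(view) {
  if (!(is.character(view) && length(view) == 1L && view %in% .views)) {
    stop("view must be one of: ", paste(.views, collapse = ", "),
         call. = FALSE)
  }
  view
}

.assert_prob <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1)) {
    stop(sprintf("%s must be a single number in [0, 1]", name), call. = FALSE)
  }
  x
}
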