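#' Per-view behavior timeline
#'
#' The result of identity-behavior association for one camera view: one
#' behavior per (cow, frame), with provenance. `source` records how each
#' entry was obtained: `"matched"` (a behavior box exceeded the IoU
#' threshold against the cow's identity box, `matched_iou` holds the
#' winning IoU), `"fallback_low_iou"` (identity seen but no behavior box
#' overlapped enough; previous frame's behavior carried forward),
#' `"fallback_missing"` (cow not detected at all; previous behavior
#' carried forward), or `"initial_unknown"` (no match has occurred yet
#' under the unknown-sentinel initial policy).
#'
#' @param entries data frame with columns `frame_index`, `cow`,
#'   `behavior`, `source`, `matched_iou` (`NA` unless `source ==
#'   "matched"`).
#' @param view `"top"` or `"front"`.
#' @param roster character vector of cow ids covered.
#' @param frames integer vector of frame indices covered.
#' @param iou_threshold optional; the association threshold the timeline
#'   was built with, kept for validation and reporting.
#' @return object of class `view_timeline` (a data frame).
#' @export
view_timeline <- function(entries, view, roster, frames,
                          iou_threshold = NA_real_) {
  .assert_view(view)
  entries <- .validate_timeline_entries(
    entries, roster, frames,
    status_col = "source", status_levels = .sources_view)
  if (!"matched_iou" %in% names(entries)) entries$matched_iou <- NA_real_
  is_m <- entries$source == "matched"
  if (any(is.na(entries$matched_iou[is_m]))) {
    stop("matched entries must carry matched_iou", call. = FALSE)
  }
  if (any(!is.na(entries$matched_iou[!is_m]))) {
    stop("matched_iou present on a non-matched entry", call. = FALSE)
  }
  if (is.finite(iou_threshold) && any(entries$matched_iou[is_m] <= iou_threshold)) {
    stop("matched entry with IoU not exceeding the threshold", call. = FALSE)
  }
  unk <- entries$behavior == .unknown
  if (!identical(unname(unk), unname(entries$source == "initial_unknown"))) {
    stop("behavior is 'unknown' if and only if source is 'initial_unknown'",
         call. = FALSE)
  }
  structure(entries, class = c("view_timeline", "data.frame"),
            view = view, roster = roster, frames = as.integer(frames),
            iou_threshold = iou_threshold)
}

#' Fused cross-view behavior timeline
#'
#' Output of the decision-level ensemble: one behavior per (cow, frame)
#' together with the fusion rule that produced it (`"top_override"`,
#' `"front_default"`, `"single_view"`, or `"both_unknown"`).
#'
#' @param entries data frame with columns `frame_index`, `cow`,
#'   `behavior`, `rule_applied`.
#' @param roster,frames coverage, as for [view_timeline()].
#' @return object of class `fused_timeline` (a data frame).
#' @export
fused_timeline <- function(entries, roster, frames) {
  entries <- .validate_timeline_entries(
    entries, roster, frames,
    status_col = "rule_applied", status_levels = .rules_fused)
  unk <- entries$behavior == .unknown
  if (any(unk & entries$rule_applied != "both_unknown")) {
    stop("an unknown fused behavior must come from rule 'both_unknown'",
         call. = FALSE)
  }
  structure(entries, class = c("fused_timeline", "data.frame"),
            roster = roster, frames = as.integer(frames))
}

.validate_timeline_entries <- function(entries, roster, frames,
                                       status_col, status_levels) {
  stopifnot(is.data.frame(entries))
  need <- c("frame_index", "cow", "behavior", status_col)
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols) > 0L) {
    stop("timeline entries missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  roster <- as.character(roster)
  frames <- as.integer(frames)
  if (length(roster) == 0L || any(!nzchar(roster)) || anyDuplicated(roster)) {
    stop("roster must be non-empty, unique cow ids", call. = FALSE)
  }
  entries$frame_index <- as.integer(entries$frame_index)
  .assert_behaviors(entries$behavior, allow_unknown = TRUE)
  bad <- setdiff(unique(entries[[status_col]]), status_levels)
  if (length(bad) > 0L) {
    stop("invalid ", status_col, " value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(entries$cow, entries$frame_index)
  want <- paste(rep(roster, each = length(frames)),
                rep(frames, times = length(roster)))
  if (anyDuplicated(key) || !setequal(key, want)) {
    stop("timeline must contain exactly one entry per (cow, frame) over ",
         "roster x frames", call. = FALSE)
  }
  entries <- entries[order(entries$frame_index, entries$cow), , drop = FALSE]
  rownames(entries) <- NULL
  entries
}

#' @export
print.view_timeline <- function(x, ...) {
  cat(sprintf("<view_timeline: %s view, %d cows x %d frames>\n",
              attr(x, "view"), length(attr(x, "roster")),
              length(attr(x, "frames"))))
  print(table(source = x$source))
  invisible(x)
}

#' @export
print.fused_timeline <- function(x, ...) {
  cat(sprintf("<fused_timeline: %d cows x %d frames>\n",
              length(attr(x, "roster")), length(attr(x, "frames"))))
  print(table(rule = x$rule_applied))
  invisible(x)
}

#' @export
summary.view_timeline <- function(object, ...) {
  print(object)
  cat("behavior occupancy:\n")
  print(round(prop.table(table(factor(object$behavior,
                                      levels = behavior_labels(TRUE)))), 4))
  invisible(object)
}

#' Write a timeline to CSV
#'
#' One row per (cow, frame) with columns `frame_index`, `cow`,
#' `behavior`, `source` (the fusion rule for fused timelines) and
#' `matched_iou` (empty except for matched view-timeline entries). The
#' `"unknown"` sentinel is serialized literally.
#'
#' @param timeline a [view_timeline()] or [fused_timeline()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_timeline()]
#' @export
write_timeline <- function(timeline, path) {
  if (inherits(timeline, "view_timeline")) {
    out <- data.frame(frame_index = timeline$frame_index,
                      cow = timeline$cow, behavior = timeline$behavior,
                      source = timeline$source,
                      matched_iou = timeline$matched_iou)
  } else if (inherits(timeline, "fused_timeline")) {
    out <- data.frame(frame_index = timeline$frame_index,
                      cow = timeline$cow, behavior = timeline$behavior,
                      source = timeline$rule_applied,
                      matched_iou = NA_real_)
  } else {
    stop("timeline must be a view_timeline or fused_timeline", call. = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a timeline CSV written by [write_timeline()]
#'
#' @param path CSV path.
#' @param view for view timelines, the view the timeline belongs to;
#'   ignored for fused timelines.
#' @param type `"auto"` detects a fused timeline by its rule values.
#' @param iou_threshold optional threshold recorded on the rebuilt
#'   view timeline.
#' @return a [view_timeline()] or [fused_timeline()].
#' @export
read_timeline <- function(path, view = NULL,
                          type = c("auto", "view", "fused"),
                          iou_threshold = NA_real_) {
  type <- match.arg(type)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "cow", "behavior", "source")
  if (!all(need %in% names(d))) {
    stop("timeline CSV missing required columns", call. = FALSE)
  }
  d$cow <- as.character(d$cow)
  if (!"matched_iou" %in% names(d)) d$matched_iou <- NA_real_
  d$matched_iou <- suppressWarnings(as.numeric(d$matched_iou))
  if (type == "auto") {
    type <- if (all(d$source %in% .rules_fused)) "fused" else "view"
  }
  roster <- sort(unique(d$cow))
  frames <- sort(unique(d$frame_index))
  if (type == "fused") {
    d$rule_applied <- d$source
    fused_timeline(d[c("frame_index", "cow", "behavior", "rule_applied")],
                   roster, frames)
  } else {
    if (is.null(view)) {
      stop("view is required to read a view timeline", call. = FALSE)
    }
    view_timeline(d[c("frame_index", "cow", "behavior", "source",
                      "matched_iou")],
                  view, roster, frames, iou_threshold = iou_threshold)
  }
}
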