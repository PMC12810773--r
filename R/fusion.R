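#' Fusion rule table
#'
#' The decision-level ensemble is rule-based: by default the front view's
#' label wins, except for (top, front) pairs listed here, for which the
#' top view's label is preferred. The default table encodes the two
#' documented front-view failure modes — a cow merely standing near the
#' water trough called `"drink"`, and a standing cow occluded by
#' rear-to-front alignment called `"chin_rest"` — both overridden when the
#' top view sees `"stand"`. Users may extend the table, e.g. with
#' `c("stand", "ride")`, without code changes.
#'
#' @param override_pairs list of length-2 character vectors
#'   `c(top_label, front_label)`; only non-sentinel behaviors allowed.
#' @return object of class `fusion_rules`.
#' @export
#' @examples
#' fusion_rules()
#' fusion_rules(list(c("stand", "drink")))
fusion_rules <- function(override_pairs = list(c("stand", "drink"),
                                               c("stand", "chin_rest"))) {
  if (length(override_pairs) == 0L) {
    tab <- data.frame(top = character(0), front = character(0))
  } else {
    stopifnot(all(vapply(override_pairs, length, 1L) == 2L))
    tab <- data.frame(top = vapply(override_pairs, `[[`, "", 1L),
                      front = vapply(override_pairs, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
    .assert_behaviors(tab$top, what = "override top")
    .assert_behaviors(tab$front, what = "override front")
    tab <- unique(tab)
  }
  structure(list(pairs = tab), class = "fusion_rules")
}

#' @export
print.fusion_rules <- function(x, ...) {
  cat("<fusion_rules>\n")
  if (nrow(x$pairs) == 0L) cat("  (no overrides: front view always wins)\n")
  else cat(sprintf("  top '%s' overrides front '%s'\n",
                   x$pairs$top, x$pairs$front), sep = "")
  invisible(x)
}

#' Fuse one pair of per-view labels
#'
#' Vectorized over equal-length label vectors. If the (top, front) pair is
#' in the override table the top label wins (`"top_override"`); if exactly
#' one view is `"unknown"` the informative view is used
#' (`"single_view"`); if both are unknown the result is unknown
#' (`"both_unknown"`); otherwise the front view's label is used
#' (`"front_default"`).
#'
#' @param top,front behavior labels (sentinel `"unknown"` allowed).
#' @param rules a [fusion_rules()] table.
#' @return data frame with columns `behavior` and `rule_applied`.
#' @export
#' @examples
#' fuse_labels("stand", "drink")   # -> stand, top_override
#' fuse_labels("lie", "eat")       # -> eat, front_default
fuse_labels <- function(top, front, rules = fusion_rules()) {
  stopifnot(length(top) == length(front), inherits(rules, "fusion_rules"))
  .assert_behaviors(top, allow_unknown = TRUE, what = "top")
  .assert_behaviors(front, allow_unknown = TRUE, what = "front")
  behavior <- front
  rule <- rep("front_default", length(front))
  ov <- paste(top, front) %in% paste(rules$pairs$top, rules$pairs$front)
  behavior[ov] <- top[ov]
  rule[ov] <- "top_override"
  top_unk <- top == .unknown
  front_unk <- front == .unknown
  one <- xor(top_unk, front_unk)
  behavior[one] <- ifelse(front_unk[one], top[one], front[one])
  rule[one] <- "single_view"
  both <- top_unk & front_unk
  behavior[both] <- .unknown
  rule[both] <- "both_unknown"
  data.frame(behavior = behavior, rule_applied = rule,
             stringsAsFactors = FALSE)
}

#' Fuse two per-view timelines into a final timeline
#'
#' Applies [fuse_labels()] to each (cow, frame) over the intersection of
#' the two timelines' frame ranges. Fallback-sourced labels are fused
#' exactly like matched ones: the ensemble operates on the association
#' output of each view, not on raw boxes.
#'
#' @param top,front [view_timeline()] objects for the top and front views,
#'   over the same roster and overlapping frame ranges.
#' @param rules a [fusion_rules()] table.
#' @return a [fused_timeline()] over the common frames.
#' @export
fuse_timelines <- function(top, front, rules = fusion_rules()) {
  stopifnot(inherits(top, "view_timeline"), inherits(front, "view_timeline"))
  if (!identical(attr(top, "view"), "top") ||
      !identical(attr(front, "view"), "front")) {
    stop("fuse_timelines expects a top-view and a front-view timeline, ",
         "in that order", call. = FALSE)
  }
  roster <- sort(attr(top, "roster"))
  if (!setequal(roster, attr(front, "roster"))) {
    stop("timelines cover different cow rosters", call. = FALSE)
  }
  frames <- intersect(attr(top, "frames"), attr(front, "frames"))
  if (length(frames) == 0L) {
    stop("timelines cover disjoint frame ranges; nothing to fuse",
         call. = FALSE)
  }
  frames <- sort(frames)
  key <- function(tl) paste(tl$cow, tl$frame_index)
  want <- paste(rep(roster, times = length(frames)),
                rep(frames, each = length(roster)))
  ti <- match(want, key(top))
  fi <- match(want, key(front))
  fused <- fuse_labels(top$behavior[ti], front$behavior[fi], rules)
  entries <- data.frame(
    frame_index = rep(frames, each = length(roster)),
    cow = rep(roster, times = length(frames)),
    behavior = fused$behavior, rule_applied = fused$rule_applied,
    stringsAsFactors = FALSE)
  fused_timeline(entries, sort(roster), frames)
}
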