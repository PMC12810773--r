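#' Association configuration
#'
#' Parameters of the per-frame identity-behavior matcher. A behavior box
#' is linked to a cow when its IoU against the cow's identity box is
#' strictly greater than `iou_threshold`; 0.5 is the usual
#' detection-overlap convention and the default. Before a cow's first
#' successful match the timeline carries either the `"unknown"` sentinel
#' (default, excluded from evaluation) or a fixed label of the user's
#' choosing. Optional confidence floors drop low-confidence detections of
#' either kind before matching; the default of 0 applies no filtering.
#'
#' @param iou_threshold IoU that a match must strictly exceed, in `[0, 1]`.
#' @param initial_behavior_policy `"unknown_sentinel"` or `"fixed_label"`.
#' @param fixed_initial_label behavior used before the first match under
#'   the `"fixed_label"` policy.
#' @param identity_confidence_floor,behavior_confidence_floor minimum
#'   confidence for a detection to take part in matching, in `[0, 1]`.
#' @return object of class `association_config`.
#' @export
association_config <- function(iou_threshold = 0.5,
                               initial_behavior_policy = c("unknown_sentinel",
                                                           "fixed_label"),
                               fixed_initial_label = "stand",
                               identity_confidence_floor = 0,
                               behavior_confidence_floor = 0) {
  initial_behavior_policy <- match.arg(initial_behavior_policy)
  .assert_prob(iou_threshold, "iou_threshold")
  .assert_prob(identity_confidence_floor, "identity_confidence_floor")
  .assert_prob(behavior_confidence_floor, "behavior_confidence_floor")
  .assert_behaviors(fixed_initial_label, what = "fixed_initial_label")
  structure(list(iou_threshold = iou_threshold,
                 initial_behavior_policy = initial_behavior_policy,
                 fixed_initial_label = fixed_initial_label,
                 identity_confidence_floor = identity_confidence_floor,
                 behavior_confidence_floor = behavior_confidence_floor),
            class = "association_config")
}

#' Match one frame's identity boxes to behavior boxes
#'
#' For each cow in the roster: if the cow has at least one identity box
#' (after the confidence floor), its best box is compared against every
#' behavior box (after the floor); among behavior boxes whose IoU strictly
#' exceeds the threshold, the max-IoU box's label is assigned
#' (`source = "matched"`). If no behavior box clears the threshold the
#' behavior is uncertain and the previous frame's behavior is carried
#' forward (`"fallback_low_iou"`); if the cow has no identity box at all,
#' likewise (`"fallback_missing"`). A single behavior box may be matched
#' to several cows (riding involves two animals), so no one-to-one
#' constraint is imposed.
#'
#' Tie-breaks are deterministic: among several identity boxes for one cow,
#' highest confidence, then larger area, then lowest `(x_min, y_min)`;
#' among equal-IoU behavior boxes, higher confidence, then lexicographic
#' behavior name.
#'
#' @param identity_dets,behavior_dets detection data frames for one frame
#'   of one view (see [detection_stream()]).
#' @param previous named character vector: each cow's behavior in the
#'   previous frame (`"unknown"` before any match).
#' @param config an [association_config()].
#' @param roster character vector of cow ids; an identity detection
#'   labeled outside the roster is an error.
#' @return data frame with one row per cow: `cow`, `behavior`, `source`,
#'   `matched_iou` (`NA` unless matched).
#' @export
match_frame <- function(identity_dets, behavior_dets, previous,
                        config = association_config(), roster) {
  identity_dets <- .validate_detections(identity_dets)
  behavior_dets <- .validate_detections(behavior_dets)
  roster <- as.character(roster)
  if (!all(identity_dets$label %in% roster)) {
    stop("identity detection labeled with a cow id outside the roster: ",
         paste(setdiff(identity_dets$label, roster), collapse = ", "),
         call. = FALSE)
  }
  if (!all(roster %in% names(previous))) {
    stop("previous-behavior map must cover the full roster", call. = FALSE)
  }
  res <- .match_frame_core(
    id_label = identity_dets$label, id_conf = identity_dets$confidence,
    id_x1 = identity_dets$x_min, id_y1 = identity_dets$y_min,
    id_x2 = identity_dets$x_max, id_y2 = identity_dets$y_max,
    bh_label = behavior_dets$label, bh_conf = behavior_dets$confidence,
    bh_x1 = behavior_dets$x_min, bh_y1 = behavior_dets$y_min,
    bh_x2 = behavior_dets$x_max, bh_y2 = behavior_dets$y_max,
    previous = previous, config = config, roster = roster)
  data.frame(cow = roster, behavior = res$behavior, source = res$source,
             matched_iou = res$matched_iou, stringsAsFactors = FALSE)
}

# plain-vector core shared by match_frame and the stream loop
.match_frame_core <- function(id_label, id_conf, id_x1, id_y1, id_x2, id_y2,
                              bh_label, bh_conf, bh_x1, bh_y1, bh_x2, bh_y2,
                              previous, config, roster) {
  keep_id <- id_conf >= config$identity_confidence_floor
  keep_bh <- bh_conf >= config$behavior_confidence_floor
  if (!all(keep_bh)) {
    bh_label <- bh_label[keep_bh]; bh_conf <- bh_conf[keep_bh]
    bh_x1 <- bh_x1[keep_bh]; bh_y1 <- bh_y1[keep_bh]
    bh_x2 <- bh_x2[keep_bh]; bh_y2 <- bh_y2[keep_bh]
  }
  n_bh <- length(bh_label)
  behavior <- character(length(roster))
  source <- character(length(roster))
  matched_iou <- rep(NA_real_, length(roster))
  for (k in seq_along(roster)) {
    cow <- roster[[k]]
    idx <- which(keep_id & id_label == cow)
    if (length(idx) == 0L) {
      prev <- previous[[cow]]
      if (identical(prev, .unknown)) {
        behavior[[k]] <- .unknown; source[[k]] <- "initial_unknown"
      } else {
        behavior[[k]] <- prev; source[[k]] <- "fallback_missing"
      }
      next
    }
    if (length(idx) > 1L) {
      # best identity box: confidence, then area, then lowest (x_min, y_min)
      area <- (id_x2[idx] - id_x1[idx]) * (id_y2[idx] - id_y1[idx])
      ord <- order(-id_conf[idx], -area, id_x1[idx], id_y1[idx])
      idx <- idx[ord[[1L]]]
    }
    matched <- FALSE
    if (n_bh > 0L) {
      iou <- .iou_vec(id_x1[idx], id_y1[idx], id_x2[idx], id_y2[idx],
                      bh_x1, bh_y1, bh_x2, bh_y2)
      over <- which(iou > config$iou_threshold)
      if (length(over) > 0L) {
        ord <- order(-iou[over], -bh_conf[over], bh_label[over],
                     method = "radix")
        best <- over[ord[[1L]]]
        behavior[[k]] <- bh_label[[best]]
        source[[k]] <- "matched"
        matched_iou[[k]] <- iou[[best]]
        matched <- TRUE
      }
    }
    if (!matched) {
      prev <- previous[[cow]]
      if (identical(prev, .unknown)) {
        behavior[[k]] <- .unknown; source[[k]] <- "initial_unknown"
      } else {
        behavior[[k]] <- prev; source[[k]] <- "fallback_low_iou"
      }
    }
  }
  list(behavior = behavior, source = source, matched_iou = matched_iou)
}

#' Associate a whole detection stream into a view timeline
#'
#' Iterates frames in index order, threading each cow's previous behavior
#' through the two fallback branches so the timeline is continuous even
#' through missed detections. Frames before a cow's first match carry the
#' initial policy's label (the `"unknown"` sentinel by default).
#'
#' @param stream a [detection_stream()].
#' @param config an [association_config()].
#' @param roster cow ids to track; defaults to the identity labels present
#'   in the stream.
#' @return a [view_timeline()].
#' @export
#' @examples
#' sc <- scenario_config(n_frames = 50, seed = 1)
#' ds <- corrupt_detections(project_views(simulate_truth(sc), sc),
#'                          zero_noise_error_model("top"))
#' associate_stream(ds, association_config(), roster = c("A", "B", "C"))
associate_stream <- function(stream, config = association_config(),
                             roster = NULL) {
  stopifnot(inherits(stream, "detection_stream"))
  if (length(stream$frames) == 0L) {
    stop("cannot associate an empty stream (no frames)", call. = FALSE)
  }
  d <- stream$detections
  if (is.null(roster)) {
    roster <- sort(unique(d$label[d$kind == "identity"]))
    if (length(roster) == 0L) {
      stop("stream has no identity detections; supply a roster", call. = FALSE)
    }
  }
  roster <- as.character(roster)
  if (!all(d$label[d$kind == "identity"] %in% roster)) {
    stop("identity detection labeled with a cow id outside the roster",
         call. = FALSE)
  }
  frames <- stream$frames
  n_f <- length(frames)
  n_c <- length(roster)
  # column extraction once; per-frame work on plain vectors
  is_id <- d$kind == "identity"
  f_fac <- factor(d$frame_index, levels = frames)
  rows_by_frame <- split(seq_len(nrow(d)), f_fac)
  lab <- d$label; conf <- d$confidence
  x1 <- d$x_min; y1 <- d$y_min; x2 <- d$x_max; y2 <- d$y_max

  previous <- stats::setNames(
    rep(if (config$initial_behavior_policy == "fixed_label")
      config$fixed_initial_label else .unknown, n_c), roster)
  behavior <- character(n_f * n_c)
  source <- character(n_f * n_c)
  miou <- rep(NA_real_, n_f * n_c)
  for (i in seq_len(n_f)) {
    rows <- rows_by_frame[[i]]
    idr <- rows[is_id[rows]]
    bhr <- rows[!is_id[rows]]
    res <- .match_frame_core(
      id_label = lab[idr], id_conf = conf[idr],
      id_x1 = x1[idr], id_y1 = y1[idr], id_x2 = x2[idr], id_y2 = y2[idr],
      bh_label = lab[bhr], bh_conf = conf[bhr],
      bh_x1 = x1[bhr], bh_y1 = y1[bhr], bh_x2 = x2[bhr], bh_y2 = y2[bhr],
      previous = previous, config = config, roster = roster)
    at <- ((i - 1L) * n_c + 1L):(i * n_c)
    behavior[at] <- res$behavior
    source[at] <- res$source
    miou[at] <- res$matched_iou
    previous[] <- res$behavior
  }
  entries <- data.frame(
    frame_index = rep(frames, each = n_c),
    cow = rep(roster, times = n_f),
    behavior = behavior, source = source, matched_iou = miou,
    stringsAsFactors = FALSE)
  view_timeline(entries, stream$view, roster, frames,
                iou_threshold = config$iou_threshold)
}
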