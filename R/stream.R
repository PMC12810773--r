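#' Per-view detection stream
#'
#' Container for the output of one camera view's two detectors (cow
#' identity and behavior) over a frame range. Detections are held as a
#' data frame with one row per labeled box; `frames` records every frame
#' index covered by the stream, including frames where the detectors saw
#' nothing.
#'
#' @param view `"top"` or `"front"`.
#' @param image_width,image_height frame size in pixels.
#' @param fps frame rate in frames per second.
#' @param detections data frame with columns `frame_index`, `kind`
#'   (`"identity"` or `"behavior"`), `label` (a cow id for identity rows,
#'   a non-sentinel behavior for behavior rows), `confidence` in `[0, 1]`,
#'   and box corners `x_min`, `y_min`, `x_max`, `y_max`.
#' @param frames integer vector of frame indices covered by the stream,
#'   strictly increasing; defaults to `0 .. max(frame_index)` when
#'   detections are present. A frame listed here with no detection rows is
#'   an empty frame, not a missing one.
#' @return object of class `detection_stream`.
#' @export
detection_stream <- function(view, image_width, image_height, fps,
                             detections, frames = NULL) {
  .assert_view(view)
  stopifnot(is.numeric(image_width), image_width > 0,
            is.numeric(image_height), image_height > 0,
            is.numeric(fps), fps > 0)
  detections <- .validate_detections(detections, view)
  if (is.null(frames)) {
    frames <- if (nrow(detections) == 0L) integer(0) else
      seq.int(0L, max(detections$frame_index))
  }
  frames <- as.integer(frames)
  if (anyDuplicated(frames)) {
    stop("duplicate frame index in stream", call. = FALSE)
  }
  if (is.unsorted(frames, strictly = TRUE)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  if (any(frames < 0L)) stop("frame indices must be non-negative", call. = FALSE)
  if (!all(detections$frame_index %in% frames)) {
    stop("detections refer to frame indices absent from the stream's frame list",
         call. = FALSE)
  }
  detections <- detections[order(detections$frame_index,
                                 match(detections$kind, .kinds),
                                 detections$label,
                                 detections$x_min, detections$y_min), ,
                           drop = FALSE]
  rownames(detections) <- NULL
  structure(
    list(view = view,
         image_width = as.numeric(image_width),
         image_height = as.numeric(image_height),
         fps = as.numeric(fps),
         frames = frames,
         detections = detections),
    class = "detection_stream")
}

.detection_cols <- c("frame_index", "kind", "label", "confidence",
                     "x_min", "y_min", "x_max", "y_max")

.empty_detections <- function() {
  data.frame(frame_index = integer(0), kind = character(0),
             label = character(0), confidence = numeric(0),
             x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0),
             stringsAsFactors = FALSE)
}

.validate_detections <- function(d, view = NULL) {
  if (is.null(d)) return(.empty_detections())
  if (!is.data.frame(d)) stop("detections must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.detection_cols, names(d))
  if (length(missing_cols) > 0L) {
    stop("detections missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- d[.detection_cols]
  if (nrow(d) == 0L) return(.empty_detections())
  d$frame_index <- as.integer(d$frame_index)
  if (any(is.na(d$frame_index)) || any(d$frame_index < 0L)) {
    stop("frame_index must be a non-negative integer", call. = FALSE)
  }
  bad_kind <- setdiff(unique(d$kind), .kinds)
  if (length(bad_kind) > 0L) {
    stop("detection kind must be 'identity' or 'behavior'", call. = FALSE)
  }
  if (any(!is.finite(d$confidence)) || any(d$confidence < 0) ||
      any(d$confidence > 1)) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  is_beh <- d$kind == "behavior"
  .assert_behaviors(d$label[is_beh], allow_unknown = FALSE,
                    what = "behavior-detection")
  if (any(!nzchar(d$label[!is_beh]))) {
    stop("identity labels must be non-empty cow ids", call. = FALSE)
  }
  .validate_box_cols(d$x_min, d$y_min, d$x_max, d$y_max, where = "detections")
  d
}

#' @export
print.detection_stream <- function(x, ...) {
  cat(sprintf("<detection_stream: %s view, %dx%d px @ %g fps>\n",
              x$view, x$image_width, x$image_height, x$fps))
  cat(sprintf("  frames: %d (%s)\n", length(x$frames),
              if (length(x$frames)) paste0(min(x$frames), "..", max(x$frames))
              else "none"))
  tab <- table(x$detections$kind)
  cat(sprintf("  detections: %d identity, %d behavior\n",
              if ("identity" %in% names(tab)) tab[["identity"]] else 0L,
              if ("behavior" %in% names(tab)) tab[["behavior"]] else 0L))
  invisible(x)
}

#' @export
summary.detection_stream <- function(object, ...) {
  print(object)
  beh <- object$detections[object$detections$kind == "behavior", "label"]
  if (length(beh)) {
    cat("  behavior-box labels:\n")
    print(table(factor(beh, levels = behavior_labels())))
  }
  invisible(object)
}

#' Parse one frame of YOLO-format detections
#'
#' Reads lines of the YOLO text format
#' `class_index x_center y_center width height [confidence]` (coordinates
#' normalized to `[0, 1]`, class indices 0-based) and returns absolute
#' half-open corner detections. Corners that land outside the image after
#' de-normalization are clipped to the frame. A missing confidence field
#' defaults to 1.
#'
#' @param text_lines character vector, one detection per line; blank lines
#'   are ignored.
#' @param image_width,image_height image size in pixels.
#' @param kind `"identity"` or `"behavior"`: which detector produced the
#'   lines (decides how labels are validated).
#' @param label_map character vector mapping class indices to labels. An
#'   unnamed vector is taken as 0-based (`label_map[1]` is class 0); a
#'   named vector's names are the class indices.
#' @param frame_index frame number the lines belong to.
#' @param view `"top"` or `"front"`.
#' @return detections data frame (see [detection_stream()]).
#' @export
#' @examples
#' parse_yolo_frame("0 0.5 0.5 1.0 1.0", 100, 100, "behavior",
#'                  c("stand"), frame_index = 0, view = "top")
parse_yolo_frame <- function(text_lines, image_width, image_height,
                             kind = c("identity", "behavior"), label_map,
                             frame_index = 0L, view = c("top", "front")) {
  kind <- match.arg(kind)
  view <- match.arg(view)
  if (is.null(names(label_map))) {
    names(label_map) <- as.character(seq_along(label_map) - 1L)
  }
  lines <- trimws(text_lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_detections())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "[[:space:]]+")[[1L]]
    if (!(length(fields) %in% c(5L, 6L))) {
      stop(sprintf("line %d: expected 5 or 6 fields, got %d", i,
                   length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop(sprintf("line %d: non-numeric field", i), call. = FALSE)
    }
    cls <- fields[[1L]]
    if (vals[[1L]] != floor(vals[[1L]])) {
      stop(sprintf("line %d: class index must be an integer", i),
           call. = FALSE)
    }
    cls <- as.character(as.integer(vals[[1L]]))
    if (!cls %in% names(label_map)) {
      stop(sprintf("line %d: class index %s not in label map", i, cls),
           call. = FALSE)
    }
    norm <- vals[2:5]
    if (any(norm < 0) || any(norm > 1)) {
      stop(sprintf("line %d: normalized coordinate outside [0, 1]", i),
           call. = FALSE)
    }
    conf <- if (length(vals) == 6L) vals[[6L]] else 1.0
    if (!is.finite(conf) || conf < 0 || conf > 1) {
      stop(sprintf("line %d: confidence outside [0, 1]", i), call. = FALSE)
    }
    box <- yolo_to_box(norm[1L], norm[2L], norm[3L], norm[4L],
                       image_width, image_height)
    out[[i]] <- data.frame(
      frame_index = as.integer(frame_index), kind = kind,
      label = unname(label_map[[cls]]), confidence = conf,
      x_min = max(box$x_min, 0), y_min = max(box$y_min, 0),
      x_max = min(box$x_max, image_width), y_max = min(box$y_max, image_height),
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  .validate_detections(d)
}

#' Read a detection stream from disk
#'
#' Two on-disk forms are supported. `"yolo_dir"` is a directory holding a
#' `manifest.yaml` (view, fps, image size, label maps, number of frames)
#' plus per-frame YOLO text files under `identity/` and `behavior/`
#' subdirectories named `frame_<index>.txt`; a frame covered by the
#' manifest but lacking a file is read as empty. `"jsonl"` is a single
#' JSON-lines file whose first record is a header (`type: "header"`) and
#' whose remaining records are one detection each; detections may appear
#' in any order and are sorted by frame index.
#'
#' @param path directory (`yolo_dir`) or file (`jsonl`).
#' @param format `"yolo_dir"` or `"jsonl"`; by default inferred from
#'   whether `path` is a directory.
#' @return a [detection_stream()].
#' @seealso [write_stream()]
#' @export
read_stream <- function(path, format = c("auto", "yolo_dir", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "yolo_dir" else "jsonl"
  }
  if (format == "yolo_dir") .read_stream_yolo(path) else .read_stream_jsonl(path)
}

.read_stream_yolo <- function(path) {
  manifest_path <- file.path(path, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    stop("missing manifest.yaml in ", path, call. = FALSE)
  }
  m <- yaml::read_yaml(manifest_path)
  req <- c("view", "fps", "image_width", "image_height", "n_frames",
           "identity_labels", "behavior_labels")
  missing_fields <- setdiff(req, names(m))
  if (length(missing_fields) > 0L) {
    stop("manifest missing field(s): ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  }
  frames <- seq.int(0L, m$n_frames - 1L)
  id_map <- as.character(unlist(m$identity_labels))
  beh_map <- as.character(unlist(m$behavior_labels))
  parts <- list()
  for (f in frames) {
    for (kind in .kinds) {
      fp <- file.path(path, kind, sprintf("frame_%06d.txt", f))
      if (!file.exists(fp)) next
      lab_map <- if (kind == "identity") id_map else beh_map
      parts[[length(parts) + 1L]] <-
        parse_yolo_frame(readLines(fp, warn = FALSE), m$image_width,
                         m$image_height, kind, lab_map, f, m$view)
    }
  }
  d <- if (length(parts)) do.call(rbind, parts) else .empty_detections()
  detection_stream(m$view, m$image_width, m$image_height, m$fps, d, frames)
}

.read_stream_jsonl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty jsonl stream: ", path, call. = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  types <- vapply(recs, function(r) r$type %||% "", "")
  if (types[[1L]] != "header") {
    stop("jsonl stream must start with a header record", call. = FALSE)
  }
  h <- recs[[1L]]
  dets <- recs[types == "detection"]
  d <- if (length(dets) == 0L) .empty_detections() else data.frame(
    frame_index = vapply(dets, function(r) as.integer(r$frame_index), 1L),
    kind = vapply(dets, function(r) r$kind, ""),
    label = vapply(dets, function(r) r$label, ""),
    confidence = vapply(dets, function(r) as.numeric(r$confidence), 1.0),
    x_min = vapply(dets, function(r) as.numeric(r$x_min), 1.0),
    y_min = vapply(dets, function(r) as.numeric(r$y_min), 1.0),
    x_max = vapply(dets, function(r) as.numeric(r$x_max), 1.0),
    y_max = vapply(dets, function(r) as.numeric(r$y_max), 1.0),
    stringsAsFactors = FALSE)
  frames <- if (!is.null(h$frames)) {
    fr <- as.integer(unlist(h$frames))
    if (anyDuplicated(fr)) stop("duplicate frame index in header", call. = FALSE)
    sort(fr)
  } else {
    seq.int(0L, h$n_frames - 1L)
  }
  detection_stream(h$view, h$image_width, h$image_height, h$fps, d, frames)
}

#' Write a detection stream to disk
#'
#' Inverse of [read_stream()]; both formats round-trip exactly (full
#' floating-point precision is retained).
#'
#' @param stream a [detection_stream()].
#' @param path output directory (`yolo_dir`) or file (`jsonl`).
#' @param format `"yolo_dir"` or `"jsonl"`.
#' @param roster optional cow roster recorded in the yolo manifest; used
#'   as the identity label map. Defaults to the identity labels present.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, format = c("jsonl", "yolo_dir"),
                         roster = NULL) {
  stopifnot(inherits(stream, "detection_stream"))
  format <- match.arg(format)
  if (format == "jsonl") .write_stream_jsonl(stream, path)
  else .write_stream_yolo(stream, path, roster)
  invisible(path)
}

.num17 <- function(x) sprintf("%.17g", x)

.write_stream_jsonl <- function(stream, path) {
  header <- jsonlite::toJSON(
    list(type = "header", view = stream$view,
         image_width = stream$image_width,
         image_height = stream$image_height,
         fps = stream$fps, n_frames = length(stream$frames),
         frames = as.integer(stream$frames)),
    auto_unbox = TRUE, digits = NA)
  d <- stream$detections
  body <- if (nrow(d) == 0L) character(0) else vapply(seq_len(nrow(d)),
    function(i) {
      as.character(jsonlite::toJSON(
        list(type = "detection", frame_index = d$frame_index[[i]],
             kind = d$kind[[i]], label = d$label[[i]],
             confidence = d$confidence[[i]],
             x_min = d$x_min[[i]], y_min = d$y_min[[i]],
             x_max = d$x_max[[i]], y_max = d$y_max[[i]]),
        auto_unbox = TRUE, digits = NA))
    }, "")
  writeLines(c(as.character(header), body), path)
}

.write_stream_yolo <- function(stream, path, roster = NULL) {
  d <- stream$detections
  id_labels <- roster %||% sort(unique(d$label[d$kind == "identity"]))
  beh_labels <- behavior_labels()
  dir.create(file.path(path, "identity"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "behavior"), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(
    list(view = stream$view, fps = stream$fps,
         image_width = stream$image_width,
         image_height = stream$image_height,
         n_frames = length(stream$frames),
         identity_labels = as.list(id_labels),
         behavior_labels = as.list(beh_labels)),
    file.path(path, "manifest.yaml"))
  by_frame <- split(seq_len(nrow(d)), factor(d$frame_index,
                                             levels = stream$frames))
  for (f in stream$frames) {
    idx <- by_frame[[as.character(f)]]
    if (length(idx) == 0L) next
    for (kind in .kinds) {
      rows <- idx[d$kind[idx] == kind]
      if (length(rows) == 0L) next
      labs <- if (kind == "identity") id_labels else beh_labels
      yolo <- box_to_yolo(d$x_min[rows], d$y_min[rows], d$x_max[rows],
                          d$y_max[rows], stream$image_width,
                          stream$image_height)
      cls <- match(d$label[rows], labs) - 1L
      if (anyNA(cls)) stop("identity label absent from roster", call. = FALSE)
      writeLines(
        paste(cls, .num17(yolo$x_center), .num17(yolo$y_center),
              .num17(yolo$width), .num17(yolo$height),
              .num17(d$confidence[rows])),
        file.path(path, kind, sprintf("frame_%06d.txt", f)))
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
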