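# one detection row
det_row <- function(frame, kind, label, conf, x1, y1, x2, y2) {
  data.frame(frame_index = frame, kind = kind, label = label,
             confidence = conf, x_min = x1, y_min = y1, x_max = x2,
             y_max = y2, stringsAsFactors = FALSE)
}

# a view timeline where every entry shares one source; matched entries
# get IoU 1
make_tl <- function(view, roster, frames, behavior,
                    source = "matched") {
  n <- length(roster) * length(frames)
  behavior <- rep_len(behavior, n)
  source <- rep_len(source, n)
  entries <- data.frame(
    frame_index = rep(frames, each = length(roster)),
    cow = rep(roster, times = length(frames)),
    behavior = behavior, source = source,
    matched_iou = ifelse(source == "matched", 1, NA_real_),
    stringsAsFactors = FALSE)
  view_timeline(entries, view, roster, frames)
}

# truth table aligned with a timeline
make_truth_tab <- function(roster, frames, behavior) {
  data.frame(
    frame_index = rep(frames, each = length(roster)),
    cow = rep(roster, times = length(frames)),
    behavior = rep_len(behavior, length(roster) * length(frames)),
    stringsAsFactors = FALSE)
}

# small noisy simulated stream for property tests
small_noisy_stream <- function(seed, n_frames = 60, view = "top") {
  sc <- scenario_config(n_frames = n_frames, seed = seed)
  proj <- project_views(simulate_truth(sc), sc)
  em <- view_error_model(view,
                         base_confusion = default_error_models()[[view]]$base_confusion,
                         identity_dropout_prob = 0.1,
                         behavior_dropout_prob = 0.1,
                         box_jitter_sd = 4,
                         confidence_range = c(0.5, 1))
  corrupt_detections(proj, em)
}

# drop rows of a stream by predicate, keeping the frame range
drop_detections <- function(stream, keep) {
  detection_stream(stream$view, stream$image_width, stream$image_height,
                   stream$fps, stream$detections[keep, , drop = FALSE],
                   frames = stream$frames)
}
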