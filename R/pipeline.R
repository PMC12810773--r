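#' Run the full two-view behavior-recognition pipeline
#'
#' Executes the post-detector stages end to end: associate the top
#' stream, associate the front stream, fuse the two view timelines with
#' the rule-based ensemble, and score all three against ground truth.
#' Inputs may be in-memory objects or paths (streams in either on-disk
#' format, truth as a CSV with columns `frame_index`, `cow`,
#' `behavior`). When `out_dir` is given, the three timelines, a metrics
#' JSON and a plain-text comparison table are written there, all
#' re-readable by the package's own readers.
#'
#' @param top,front [detection_stream()] objects or paths readable by
#'   [read_stream()].
#' @param truth ground-truth data frame or CSV path.
#' @param association an [association_config()].
#' @param rules a [fusion_rules()] table.
#' @param evaluation an [evaluation_config()].
#' @param roster cow ids; defaults to the identity labels in the top
#'   stream.
#' @param out_dir optional output directory for artifacts.
#' @return object of class `behavior_pipeline`: list with the two view
#'   timelines, the fused timeline, the [compare_views()] report, and a
#'   `diagnostics` list of association-source and fusion-rule counts.
#' @export
#' @examples
#' sc <- scenario_config(n_frames = 200, seed = 42)
#' ds <- generate_dataset(sc, zero_noise_error_model("top"),
#'                        zero_noise_error_model("front"))
#' fit <- run_pipeline(ds$top, ds$front, ds$truth)
#' fit
run_pipeline <- function(top, front, truth,
                         association = association_config(),
                         rules = fusion_rules(),
                         evaluation = evaluation_config(),
                         roster = NULL, out_dir = NULL) {
  top <- .as_stream(top, "top")
  front <- .as_stream(front, "front")
  truth <- .as_truth(truth)
  if (is.null(roster)) {
    roster <- sort(unique(top$detections$label[
      top$detections$kind == "identity"]))
  }
  top_tl <- associate_stream(top, association, roster)
  front_tl <- associate_stream(front, association, roster)
  fused <- fuse_timelines(top_tl, front_tl, rules)
  comparison <- compare_views(top_tl, front_tl, fused, truth, evaluation)
  diagnostics <- list(
    top_sources = table(factor(top_tl$source, levels = .sources_view)),
    front_sources = table(factor(front_tl$source, levels = .sources_view)),
    fusion_rules = table(factor(fused$rule_applied, levels = .rules_fused)))
  result <- structure(
    list(top_timeline = top_tl, front_timeline = front_tl, fused = fused,
         comparison = comparison, diagnostics = diagnostics,
         association = association, rules = rules, evaluation = evaluation),
    class = "behavior_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_timeline(top_tl, file.path(out_dir, "timeline_top.csv"))
    write_timeline(front_tl, file.path(out_dir, "timeline_front.csv"))
    write_timeline(fused, file.path(out_dir, "timeline_fused.csv"))
    jsonlite::write_json(pipeline_metrics(result),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(utils::capture.output(print(comparison)),
               file.path(out_dir, "comparison.txt"))
  }
  result
}

.as_stream <- function(x, expected_view) {
  if (inherits(x, "detection_stream")) {
    if (!identical(x$view, expected_view)) {
      stop("expected a ", expected_view, "-view stream, got ", x$view,
           call. = FALSE)
    }
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x) && !dir.exists(x)) {
      stop("missing ", expected_view, " stream input: ", x, call. = FALSE)
    }
    return(.as_stream(read_stream(x), expected_view))
  }
  stop("cannot interpret ", expected_view, " stream input", call. = FALSE)
}

.as_truth <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("missing truth input: ", x, call. = FALSE)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
    x$cow <- as.character(x$cow)
  }
  stopifnot(is.data.frame(x),
            all(c("frame_index", "cow", "behavior") %in% names(x)))
  x
}

#' Structured metrics from a pipeline result
#'
#' @param result a [run_pipeline()] result.
#' @return nested list suitable for JSON serialization: binary rows,
#'   per-behavior F1 matrix and diagnostic counts.
#' @export
pipeline_metrics <- function(result) {
  stopifnot(inherits(result, "behavior_pipeline"))
  b <- result$comparison$binary
  binary <- stats::setNames(lapply(seq_len(nrow(b)), function(i)
    as.list(b[i, setdiff(names(b), "configuration")])), b$configuration)
  list(
    binary = binary,
    per_behavior_f1 = apply(result$comparison$per_behavior, 2, as.list),
    diagnostics = lapply(result$diagnostics, function(t)
      as.list(stats::setNames(as.integer(t), names(t)))))
}

#' @export
print.behavior_pipeline <- function(x, ...) {
  cat("Two-view behavior recognition pipeline\n")
  cat(sprintf("  cows: %s; frames fused: %d\n",
              paste(attr(x$fused, "roster"), collapse = ", "),
              length(attr(x$fused, "frames"))))
  d <- x$diagnostics
  cat(sprintf("  top associations: %d matched, %d low-IoU fallback, %d missing-cow fallback\n",
              d$top_sources[["matched"]], d$top_sources[["fallback_low_iou"]],
              d$top_sources[["fallback_missing"]]))
  cat(sprintf("  front associations: %d matched, %d low-IoU fallback, %d missing-cow fallback\n",
              d$front_sources[["matched"]],
              d$front_sources[["fallback_low_iou"]],
              d$front_sources[["fallback_missing"]]))
  cat(sprintf("  fusion: %d top overrides, %d front defaults\n\n",
              d$fusion_rules[["top_override"]],
              d$fusion_rules[["front_default"]]))
  print(x$comparison)
  invisible(x)
}

#' @export
summary.behavior_pipeline <- function(object, ...) print(object)

#' @export
plot.behavior_pipeline <- function(x, ...) plot(x$comparison, ...)
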