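#' Evaluation configuration
#'
#' Frame-level scoring with an optional stride: only frames whose index is
#' a multiple of `sampling_interval` are scored, so coarser evaluation
#' units (e.g. one decision per second of 10 fps video) are expressible.
#' `exclude_unknown` drops (cow, frame) pairs whose prediction is still
#' the `"unknown"` sentinel (no match has ever occurred); with it
#' disabled, a sentinel prediction at an evaluated pair is an error, since
#' the binarization is undefined for it.
#'
#' @param sampling_interval evaluate every k-th frame; integer `>= 1`.
#' @param exclude_unknown drop sentinel-labeled predictions (default).
#' @return object of class `evaluation_config`.
#' @export
evaluation_config <- function(sampling_interval = 1L, exclude_unknown = TRUE) {
  sampling_interval <- as.integer(sampling_interval)
  if (is.na(sampling_interval) || sampling_interval < 1L) {
    stop("sampling_interval must be an integer >= 1", call. = FALSE)
  }
  stopifnot(is.logical(exclude_unknown), length(exclude_unknown) == 1L)
  structure(list(sampling_interval = sampling_interval,
                 exclude_unknown = exclude_unknown),
            class = "evaluation_config")
}

#' Binarize a behavior label into estrus vs non-estrus
#'
#' Riding and chin-resting are the estrus-related behaviors (the positive
#' class); standing, lying, eating and drinking are non-estrus.
#' Vectorized; the `"unknown"` sentinel is rejected — callers must filter
#' it first.
#'
#' @param label behavior label(s).
#' @return character vector of `"estrus"` / `"non_estrus"`.
#' @export
#' @examples
#' binarize_behavior(c("ride", "chin_rest", "drink"))
binarize_behavior <- function(label) {
  if (any(label == .unknown)) {
    stop("cannot binarize the 'unknown' sentinel; filter it first",
         call. = FALSE)
  }
  .assert_behaviors(label)
  ifelse(label %in% estrus_behaviors(), "estrus", "non_estrus")
}

#' Confusion counts for the estrus binarization
#'
#' @param tp,fp,tn,fn non-negative integer counts, estrus being the
#'   positive class.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, tn = 0L, fn = 0L) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != floor(v))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts: tp=%d fp=%d tn=%d fn=%d (n=%d)>\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

# resolve a timeline + truth + config into aligned label vectors
.evaluation_pairs <- function(pred, truth, config) {
  stopifnot(inherits(pred, "view_timeline") || inherits(pred, "fused_timeline"))
  stopifnot(is.data.frame(truth),
            all(c("frame_index", "cow", "behavior") %in% names(truth)))
  keep <- pred$frame_index %% config$sampling_interval == 0L
  p <- pred[keep, , drop = FALSE]
  key <- paste(p$cow, p$frame_index)
  ti <- match(key, paste(truth$cow, truth$frame_index))
  if (anyNA(ti)) {
    stop("ground truth missing ", sum(is.na(ti)),
         " evaluated (cow, frame) pair(s)", call. = FALSE)
  }
  tlab <- truth$behavior[ti]
  .assert_behaviors(tlab, what = "ground-truth")
  plab <- p$behavior
  n_excluded <- 0L
  if (config$exclude_unknown) {
    unk <- plab == .unknown
    n_excluded <- sum(unk)
    plab <- plab[!unk]
    tlab <- tlab[!unk]
  }
  list(pred = plab, truth = tlab, n_excluded = n_excluded)
}

#' Estrus/non-estrus confusion matrix of a timeline against ground truth
#'
#' Evaluates every (cow, frame) pair at the configured stride, binarizes
#' predicted and true behaviors, and counts TP/FP/TN/FN with estrus as
#' the positive class. `tp + fp + tn + fn` always equals the number of
#' evaluated pairs.
#'
#' @param pred a [view_timeline()] or [fused_timeline()].
#' @param truth data frame with columns `frame_index`, `cow`, `behavior`
#'   covering every evaluated pair.
#' @param config an [evaluation_config()].
#' @return a [confusion_counts()] object with attributes `n_evaluated`
#'   and `n_excluded`.
#' @export
confusion <- function(pred, truth, config = evaluation_config()) {
  pairs <- .evaluation_pairs(pred, truth, config)
  pb <- binarize_behavior(pairs$pred)
  tb <- binarize_behavior(pairs$truth)
  cc <- confusion_counts(
    tp = sum(pb == "estrus" & tb == "estrus"),
    fp = sum(pb == "estrus" & tb == "non_estrus"),
    tn = sum(pb == "non_estrus" & tb == "non_estrus"),
    fn = sum(pb == "non_estrus" & tb == "estrus"))
  attr(cc, "n_evaluated") <- length(pb)
  attr(cc, "n_excluded") <- pairs$n_excluded
  cc
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2 tp/(2 tp + fp + fn)`. A metric whose denominator is zero is
#' reported as 0 (the usual convention in the detection literature) and
#' named in the `"undefined"` attribute so the convention is never
#' silently misread.
#'
#' @param c a [confusion_counts()] object (or list with `tp`, `fp`, `fn`).
#' @return named numeric vector `c(precision, recall, f1)` with attribute
#'   `undefined` naming any zero-denominator metrics.
#' @export
#' @examples
#' precision_recall_f1(confusion_counts(tp = 1, fp = 1, fn = 1))
precision_recall_f1 <- function(c) {
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  undefined <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); 0
  }
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else {
    undefined <- c(undefined, "f1"); 0
  }
  structure(c(precision = precision, recall = recall, f1 = f1),
            undefined = undefined)
}

#' One-vs-rest F1 per behavior
#'
#' Treats each of the six behaviors in turn as the positive class and
#' computes its F1 over the evaluated pairs, under the same
#' zero-denominator convention as [precision_recall_f1()]. Behaviors
#' absent from both prediction and truth are flagged `"unsupported"`.
#'
#' @inheritParams confusion
#' @return named numeric vector of F1 per behavior, with attribute
#'   `unsupported` naming behaviors absent from both sides.
#' @export
per_behavior_f1 <- function(pred, truth, config = evaluation_config()) {
  pairs <- .evaluation_pairs(pred, truth, config)
  labs <- behavior_labels()
  f1 <- stats::setNames(numeric(length(labs)), labs)
  unsupported <- character(0)
  for (b in labs) {
    tp <- sum(pairs$pred == b & pairs$truth == b)
    fp <- sum(pairs$pred == b & pairs$truth != b)
    fn <- sum(pairs$pred != b & pairs$truth == b)
    if (tp + fp + fn == 0L) unsupported <- c(unsupported, b)
    f1[[b]] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  }
  structure(f1, unsupported = unsupported)
}

#' Compare single-view and ensemble performance
#'
#' Scores the top-view timeline, the front-view timeline and the fused
#' timeline against the same ground truth and assembles the three binary
#' (estrus vs non-estrus) rows plus per-behavior F1s — the standard
#' single-view vs two-view-ensemble comparison.
#'
#' @param top,front [view_timeline()] objects.
#' @param fused a [fused_timeline()].
#' @param truth ground-truth data frame (`frame_index`, `cow`,
#'   `behavior`).
#' @param config an [evaluation_config()].
#' @return object of class `view_comparison`: list with `binary` (one row
#'   per configuration: counts, precision, recall, F1) and `per_behavior`
#'   (behavior x configuration F1 matrix).
#' @export
compare_views <- function(top, front, fused, truth,
                          config = evaluation_config()) {
  tls <- list("top only" = top, "front only" = front,
              "two-view ensemble" = fused)
  rows <- lapply(names(tls), function(nm) {
    cc <- confusion(tls[[nm]], truth, config)
    m <- precision_recall_f1(cc)
    data.frame(configuration = nm, tp = cc$tp, fp = cc$fp, tn = cc$tn,
               fn = cc$fn, n_evaluated = attr(cc, "n_evaluated"),
               precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], stringsAsFactors = FALSE)
  })
  pb <- vapply(tls, per_behavior_f1, numeric(6L), truth = truth,
               config = config)
  structure(list(binary = do.call(rbind, rows), per_behavior = pb),
            class = "view_comparison")
}

#' @export
print.view_comparison <- function(x, digits = 3, ...) {
  cat("Estrus-vs-non-estrus performance by camera configuration\n\n")
  b <- x$binary
  b$precision <- round(b$precision, digits)
  b$recall <- round(b$recall, digits)
  b$f1 <- round(b$f1, digits)
  print(b, row.names = FALSE)
  cat("\nPer-behavior one-vs-rest F1\n\n")
  print(round(x$per_behavior, digits))
  invisible(x)
}

#' @export
plot.view_comparison <- function(x, ...) {
  graphics::barplot(stats::setNames(x$binary$f1, x$binary$configuration),
                    ylab = "estrus F1", ylim = c(0, 1), ...)
  invisible(x)
}
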