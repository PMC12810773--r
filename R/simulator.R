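#' Scenario configuration for the two-view barn simulator
#'
#' Describes the simulated measurement setup: a small group of cows in a
#' rectangular pen filmed by two synchronized views (a top-down camera
#' mapping the whole pen, and a front camera looking along the pen depth
#' axis) at a fixed frame rate. Defaults emulate the reference setup the
#' package targets: three cows in a 4 x 8 m pen, 960 x 570 px frames at
#' 10 fps, a water trough along part of the front wall, and a strongly
#' imbalanced ethogram in which the estrus behaviors (chin-rest, ride)
#' are rare, short events.
#'
#' Behavior is simulated per cow as a semi-Markov process: bout lengths
#' are geometric with the per-behavior mean `mean_dwell` (in frames), and
#' the next behavior is drawn from `behavior_stationary_probs` excluding
#' the current one. Positions follow a bounded random walk, forced into
#' the trough zone during drink bouts and into adjacent rear-to-front
#' pairing during ride/chin-rest bouts (which therefore require at least
#' two cows).
#'
#' @param n_frames number of frames to simulate.
#' @param n_cows number of cows; roster is `LETTERS[1:n_cows]`.
#' @param pen_width,pen_depth pen size in meters (`x` runs along the
#'   width, `y` along the depth away from the front camera).
#' @param trough_zone named vector `c(x_min, y_min, x_max, y_max)` in pen
#'   meters: where the water trough is.
#' @param fps frame rate, frames per second.
#' @param image_width,image_height camera resolution in pixels (both
#'   views).
#' @param behavior_stationary_probs named probability vector over the six
#'   behaviors; must sum to 1.
#' @param mean_dwell named vector of mean bout lengths in frames, `>= 1`.
#' @param walk_step_sd random-walk step standard deviation, meters/frame.
#' @param align_max_dx,align_max_dy alignment cone (meters): a cow is
#'   `aligned_behind` another when it is up to `align_max_dy` deeper and
#'   within `align_max_dx` laterally.
#' @param seed integer seed; every simulator draw derives from it.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_frames = 5000L,
                            n_cows = 3L,
                            pen_width = 8,
                            pen_depth = 4,
                            trough_zone = c(x_min = 3, y_min = 0,
                                            x_max = 5, y_max = 0.7),
                            fps = 10,
                            image_width = 960L,
                            image_height = 570L,
                            behavior_stationary_probs = c(
                              stand = 0.45, lie = 0.25, eat = 0.15,
                              drink = 0.08, chin_rest = 0.04, ride = 0.03),
                            mean_dwell = c(
                              stand = 300, lie = 600, eat = 200,
                              drink = 100, chin_rest = 50, ride = 30),
                            walk_step_sd = 0.08,
                            align_max_dx = 0.5,
                            align_max_dy = 2,
                            seed = 1L) {
  labs <- behavior_labels()
  n_frames <- as.integer(n_frames)
  n_cows <- as.integer(n_cows)
  stopifnot(n_frames >= 1L, n_cows >= 1L, pen_width > 0, pen_depth > 0,
            fps > 0, image_width > 0, image_height > 0, walk_step_sd >= 0,
            align_max_dx >= 0, align_max_dy >= 0)
  if (!setequal(names(behavior_stationary_probs), labs)) {
    stop("behavior_stationary_probs must be named over the six behaviors",
         call. = FALSE)
  }
  behavior_stationary_probs <- behavior_stationary_probs[labs]
  if (any(behavior_stationary_probs < 0) ||
      abs(sum(behavior_stationary_probs) - 1) > 1e-9) {
    stop("behavior_stationary_probs must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!setequal(names(mean_dwell), labs)) {
    stop("mean_dwell must be named over the six behaviors", call. = FALSE)
  }
  mean_dwell <- mean_dwell[labs]
  if (any(mean_dwell < 1)) stop("mean dwells must be >= 1 frame", call. = FALSE)
  tz <- trough_zone[c("x_min", "y_min", "x_max", "y_max")]
  if (anyNA(tz) || tz[["x_min"]] >= tz[["x_max"]] ||
      tz[["y_min"]] >= tz[["y_max"]] ||
      tz[["x_max"]] > pen_width || tz[["y_max"]] > pen_depth ||
      any(tz < 0)) {
    stop("trough_zone must be a valid rectangle inside the pen", call. = FALSE)
  }
  structure(list(n_frames = n_frames, n_cows = n_cows,
                 roster = LETTERS[seq_len(n_cows)],
                 pen_width = pen_width, pen_depth = pen_depth,
                 trough_zone = tz, fps = fps,
                 image_width = as.numeric(image_width),
                 image_height = as.numeric(image_height),
                 behavior_stationary_probs = behavior_stationary_probs,
                 mean_dwell = mean_dwell,
                 walk_step_sd = walk_step_sd,
                 align_max_dx = align_max_dx, align_max_dy = align_max_dy,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Simulate ground-truth behavior and positions
#'
#' Generates the latent state a camera system would observe: for each cow
#' a semi-Markov behavior sequence (geometric bout lengths, next behavior
#' drawn from the stationary probabilities excluding the current one) and
#' a bounded random-walk trajectory in the pen. Drink bouts pull the cow
#' into the trough zone; ride and chin-rest bouts place the actor
#' directly behind its nearest neighbour (rear-to-front pairing), which
#' is what later produces alignment occlusion in the front view. Fully
#' reproducible from the scenario seed.
#'
#' @param config a [scenario_config()].
#' @return object of class `ground_truth`: a data frame with columns
#'   `frame_index`, `cow`, `behavior`, `x`, `y` (pen meters), one row per
#'   (cow, frame), with the config stored as an attribute.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  probs <- config$behavior_stationary_probs
  pair_behaviors <- c("chin_rest", "ride")
  if (config$n_cows < 2L && any(probs[pair_behaviors] > 0)) {
    stop("ride/chin_rest require at least two cows; set their ",
         "stationary probabilities to 0 or add cows", call. = FALSE)
  }
  labs <- behavior_labels()
  n_f <- config$n_frames
  n_c <- config$n_cows
  dwell <- config$mean_dwell
  .with_seed(config$seed, {
    # behavior sequences, one cow at a time
    beh <- matrix("", nrow = n_f, ncol = n_c)
    bout_start <- matrix(FALSE, nrow = n_f, ncol = n_c)
    for (k in seq_len(n_c)) {
      filled <- 0L
      cur <- sample(labs, 1L, prob = probs)
      while (filled < n_f) {
        len <- stats::rgeom(1L, 1 / dwell[[cur]]) + 1L
        len <- min(len, n_f - filled)
        beh[(filled + 1L):(filled + len), k] <- cur
        bout_start[filled + 1L, k] <- TRUE
        filled <- filled + len
        if (filled < n_f) {
          p <- probs
          p[[cur]] <- 0
          cur <- if (sum(p) <= 0) cur else sample(labs, 1L, prob = p)
        }
      }
    }
    # positions: bounded walk with behavior-driven constraints
    X <- matrix(0, n_f, n_c); Y <- matrix(0, n_f, n_c)
    px <- stats::runif(n_c, 0, config$pen_width)
    py <- stats::runif(n_c, 0, config$pen_depth)
    partner <- rep(NA_integer_, n_c)
    tz <- config$trough_zone
    for (f in seq_len(n_f)) {
      sx <- stats::rnorm(n_c, sd = config$walk_step_sd)
      sy <- stats::rnorm(n_c, sd = config$walk_step_sd)
      nx <- px + sx
      ny <- py + sy
      for (k in seq_len(n_c)) {
        b <- beh[f, k]
        if (b %in% pair_behaviors) {
          if (is.na(partner[[k]]) || bout_start[f, k]) {
            others <- setdiff(seq_len(n_c), k)
            d2 <- (px[others] - px[[k]])^2 + (py[others] - py[[k]])^2
            partner[[k]] <- others[[which.min(d2)]]
          }
          p <- partner[[k]]
          nx[[k]] <- px[[p]] + sx[[k]] * 0.3
          ny[[k]] <- py[[p]] + 0.75 + sy[[k]] * 0.3
        } else {
          partner[[k]] <- NA_integer_
          if (b == "drink") {
            nx[[k]] <- min(max(nx[[k]], tz[["x_min"]]), tz[["x_max"]])
            ny[[k]] <- min(max(ny[[k]], tz[["y_min"]]), tz[["y_max"]])
          }
        }
      }
      px <- pmin(pmax(nx, 0), config$pen_width)
      py <- pmin(pmax(ny, 0), config$pen_depth)
      X[f, ] <- px
      Y[f, ] <- py
    }
    out <- data.frame(
      frame_index = rep(seq_len(n_f) - 1L, times = n_c),
      cow = rep(config$roster, each = n_f),
      behavior = as.vector(beh),
      x = as.vector(X), y = as.vector(Y),
      stringsAsFactors = FALSE)
    out <- out[order(out$frame_index, out$cow), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("ground_truth", "data.frame"), config = config)
  })
}

# per-behavior body footprint (meters) used for true boxes
.body_size_m <- function() {
  rbind(stand = c(1.6, 0.7), lie = c(1.7, 1.1), eat = c(1.6, 0.7),
        drink = c(1.6, 0.7), chin_rest = c(2.0, 0.8), ride = c(1.9, 0.9))
}

# front-view apparent-height factor per behavior
.front_h_factor <- c(stand = 1, lie = 0.6, eat = 0.9, drink = 0.9,
                     chin_rest = 1.1, ride = 1.5)

#' Project ground truth into per-view true boxes and contexts
#'
#' Maps each cow's pen position to an idealized bounding box in each
#' view and flags the geometric contexts that drive view-specific
#' misclassification. The top view maps pen `(x, y)` linearly to image
#' coordinates with a fixed per-behavior footprint. The front view maps
#' `x` to the image column and depth `y` to the row and apparent scale
#' (nearer cows appear lower and larger). Context flags:
#' `near_trough_standing` when a cow stands inside the trough zone (both
#' views), and, in the front view only, `aligned_behind` when a cow lies
#' within the alignment cone directly behind another cow (rear-to-front
#' occlusion). When both apply, the trough context wins.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the matching [scenario_config()]; defaults to the one
#'   stored on `truth`.
#' @return object of class `projected_truth`: list with data frames
#'   `top` and `front` (columns `frame_index`, `cow`, `behavior`,
#'   box corners, `context`) plus the config.
#' @export
project_views <- function(truth, config = attr(truth, "config")) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "scenario_config"))
  labs <- behavior_labels()
  size <- .body_size_m()
  W <- config$image_width; H <- config$image_height
  b <- truth$behavior
  wm <- size[b, 1L]; hm <- size[b, 2L]

  # ---- top view: linear pen-to-image map
  sx <- W / config$pen_width
  sy <- H / config$pen_depth
  cx <- truth$x * sx; cy <- truth$y * sy
  half_w <- wm * sx / 2; half_h <- hm * sy / 2
  top <- .clip_boxes(cx - half_w, cy - half_h, cx + half_w, cy + half_h, W, H)

  # ---- front view: column from x, row and scale from depth
  t <- truth$y / config$pen_depth
  scale <- 1.2 / (1 + t)
  fx <- truth$x / config$pen_width * W
  fw <- 260 * scale * (wm / 1.6)
  fh <- 220 * scale * .front_h_factor[b]
  ground <- H * (0.92 - 0.35 * t)
  front <- .clip_boxes(fx - fw / 2, ground - fh, fx + fw / 2, ground, W, H)

  # ---- contexts
  tz <- config$trough_zone
  near_trough <- b == "stand" &
    truth$x >= tz[["x_min"]] & truth$x <= tz[["x_max"]] &
    truth$y >= tz[["y_min"]] & truth$y <= tz[["y_max"]]
  aligned <- .aligned_behind_flags(truth, config)

  ctx_top <- ifelse(near_trough, "near_trough_standing", "default")
  ctx_front <- ifelse(near_trough, "near_trough_standing",
                      ifelse(aligned, "aligned_behind", "default"))
  base <- truth[c("frame_index", "cow", "behavior")]
  structure(list(
    top = cbind(base, top, context = ctx_top, stringsAsFactors = FALSE),
    front = cbind(base, front, context = ctx_front, stringsAsFactors = FALSE),
    config = config), class = "projected_truth")
}

.clip_boxes <- function(x1, y1, x2, y2, W, H) {
  x1 <- pmin(pmax(x1, 0), W - 1)
  y1 <- pmin(pmax(y1, 0), H - 1)
  x2 <- pmin(pmax(x2, x1 + 1), W)
  y2 <- pmin(pmax(y2, y1 + 1), H)
  data.frame(x_min = x1, y_min = y1, x_max = x2, y_max = y2)
}

# flag cows sitting in the alignment cone directly behind another cow
.aligned_behind_flags <- function(truth, config) {
  n_f <- config$n_frames
  n_c <- config$n_cows
  ord <- order(match(truth$cow, config$roster), truth$frame_index)
  X <- matrix(truth$x[ord], n_f, n_c)
  Y <- matrix(truth$y[ord], n_f, n_c)
  flag <- matrix(FALSE, n_f, n_c)
  for (i in seq_len(n_c)) {
    for (j in seq_len(n_c)) {
      if (i == j) next
      dy <- Y[, i] - Y[, j]
      flag[, i] <- flag[, i] |
        (dy > 0 & dy <= config$align_max_dy &
           abs(X[, i] - X[, j]) <= config$align_max_dx)
    }
  }
  out <- logical(nrow(truth))
  out[ord] <- as.vector(flag)
  out
}

#' View-specific detection error model
#'
#' Describes how a view's detectors corrupt the latent truth: a 6 x 6
#' row-stochastic confusion matrix (true behavior to emitted behavior-box
#' label), optional context-gated override rows that replace the base row
#' in a geometric context (`near_trough_standing`, `aligned_behind`),
#' independent dropout of identity and behavior boxes, Gaussian jitter of
#' box corners, and a uniform confidence range.
#'
#' @param view `"top"` or `"front"`.
#' @param base_confusion 6 x 6 matrix with behavior dimnames, rows
#'   summing to 1; defaults to the identity (no misclassification).
#' @param context_rules named list: context name to a named list of
#'   replacement confusion rows keyed by true behavior, e.g.
#'   `list(near_trough_standing = list(stand = c(stand = .4, drink = .6,
#'   ...)))`.
#' @param identity_dropout_prob,behavior_dropout_prob per-(cow, frame)
#'   probability that the identity / behavior box is missed entirely.
#' @param box_jitter_sd standard deviation (pixels) of independent
#'   Gaussian noise added to each box corner; boxes are re-validated and
#'   clipped to the image.
#' @param confidence_range detections get confidences uniform in this
#'   range.
#' @return object of class `view_error_model`.
#' @seealso [default_error_models()], [zero_noise_error_model()]
#' @export
view_error_model <- function(view,
                             base_confusion = NULL,
                             context_rules = list(),
                             identity_dropout_prob = 0,
                             behavior_dropout_prob = 0,
                             box_jitter_sd = 0,
                             confidence_range = c(1, 1)) {
  .assert_view(view)
  labs <- behavior_labels()
  if (is.null(base_confusion)) {
    base_confusion <- diag(6L)
    dimnames(base_confusion) <- list(labs, labs)
  }
  .assert_confusion_matrix(base_confusion)
  valid_ctx <- c("near_trough_standing", "aligned_behind")
  if (length(context_rules) > 0L) {
    bad <- setdiff(names(context_rules), valid_ctx)
    if (length(bad) > 0L) {
      stop("unknown context(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (ctx in names(context_rules)) {
      rows <- context_rules[[ctx]]
      .assert_behaviors(names(rows), what = "context-rule behavior")
      for (bname in names(rows)) {
        rows[[bname]] <- .assert_confusion_row(rows[[bname]])
      }
      context_rules[[ctx]] <- rows
    }
  }
  .assert_prob(identity_dropout_prob, "identity_dropout_prob")
  .assert_prob(behavior_dropout_prob, "behavior_dropout_prob")
  stopifnot(box_jitter_sd >= 0, length(confidence_range) == 2L,
            confidence_range[[1L]] <= confidence_range[[2L]])
  .assert_prob(confidence_range[[1L]], "confidence_range[1]")
  .assert_prob(confidence_range[[2L]], "confidence_range[2]")
  structure(list(view = view, base_confusion = base_confusion,
                 context_rules = context_rules,
                 identity_dropout_prob = identity_dropout_prob,
                 behavior_dropout_prob = behavior_dropout_prob,
                 box_jitter_sd = box_jitter_sd,
                 confidence_range = as.numeric(confidence_range)),
            class = "view_error_model")
}

.assert_confusion_row <- function(row) {
  labs <- behavior_labels()
  if (!setequal(names(row), labs)) {
    stop("a confusion row must be named over the six behaviors",
         call. = FALSE)
  }
  row <- row[labs]
  if (any(row < 0) || abs(sum(row) - 1) > 1e-9) {
    stop("confusion rows must be non-negative and sum to 1", call. = FALSE)
  }
  row
}

.assert_confusion_matrix <- function(m) {
  labs <- behavior_labels()
  if (!is.matrix(m) || !identical(dim(m), c(6L, 6L)) ||
      !setequal(rownames(m), labs) || !setequal(colnames(m), labs)) {
    stop("base_confusion must be a 6 x 6 matrix with behavior dimnames",
         call. = FALSE)
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("confusion rows must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(m)
}

#' Noise-free error model
#'
#' Identity confusion, no dropout, no jitter, confidence 1: the perfect
#' detector. Under this model the full pipeline must reproduce ground
#' truth exactly.
#'
#' @param view `"top"` or `"front"`.
#' @return a [view_error_model()].
#' @export
zero_noise_error_model <- function(view) view_error_model(view)

#' Shipped barn-default error models for the two views
#'
#' The calibration constants of the simulated study. The top view loses
#' postural cues, so its `stand` row leaks heavily into the two estrus
#' labels (`ride`, `chin_rest`) regardless of context; this floods the
#' top view with estrus false positives. The front view is milder and
#' context-gated: a standing cow inside the trough zone is often called
#' `drink`, and a standing cow aligned directly behind another is often
#' called `chin_rest` (occasionally `ride`). Both views have small
#' dropout and jitter. These magnitudes are properties of the simulated
#' detectors, chosen so the two views exhibit the documented qualitative
#' error modes; they are not measurements of any real detector.
#'
#' @return named list with elements `top` and `front`, each a
#'   [view_error_model()].
#' @export
default_error_models <- function() {
  labs <- behavior_labels()
  near_diag <- function(diag_p) {
    off <- (1 - diag_p) / 5
    m <- matrix(off, 6L, 6L, dimnames = list(labs, labs))
    diag(m) <- diag_p
    m
  }
  top_conf <- near_diag(0.95)
  top_conf["stand", ] <- c(stand = 0.60, lie = 0.02, eat = 0.02,
                           drink = 0.02, chin_rest = 0.17, ride = 0.17)
  front_conf <- near_diag(0.93)
  front_conf["stand", ] <- c(stand = 0.90, lie = 0.02, eat = 0.02,
                             drink = 0.02, chin_rest = 0.03, ride = 0.01)
  front_rules <- list(
    near_trough_standing = list(
      stand = c(stand = 0.37, lie = 0, eat = 0, drink = 0.60,
                chin_rest = 0.02, ride = 0.01)),
    aligned_behind = list(
      stand = c(stand = 0.40, lie = 0.01, eat = 0.02, drink = 0.02,
                chin_rest = 0.45, ride = 0.10)))
  list(
    top = view_error_model("top", base_confusion = top_conf,
                           identity_dropout_prob = 0.05,
                           behavior_dropout_prob = 0.05,
                           box_jitter_sd = 3,
                           confidence_range = c(0.55, 0.95)),
    front = view_error_model("front", base_confusion = front_conf,
                             context_rules = front_rules,
                             identity_dropout_prob = 0.05,
                             behavior_dropout_prob = 0.05,
                             box_jitter_sd = 3,
                             confidence_range = c(0.55, 0.95)))
}

#' Corrupt projected truth into a detection stream
#'
#' Applies a view's error model to the idealized boxes: per (cow, frame)
#' the identity box is emitted unless identity dropout fires; the
#' behavior box is emitted unless behavior dropout fires, with its label
#' sampled from the context-selected confusion row; both boxes receive
#' independent Gaussian corner jitter (clipped to the image) and a
#' confidence uniform in the configured range. Reproducible from the
#' seed.
#'
#' @param projected a [project_views()] result.
#' @param error_model a [view_error_model()]; its `view` field selects
#'   which projection to corrupt.
#' @param seed integer seed; defaults to a view-specific offset of the
#'   scenario seed so the two views get independent but reproducible
#'   noise.
#' @return a [detection_stream()].
#' @export
corrupt_detections <- function(projected, error_model, seed = NULL) {
  stopifnot(inherits(projected, "projected_truth"),
            inherits(error_model, "view_error_model"))
  config <- projected$config
  view <- error_model$view
  d <- projected[[view]]
  if (is.null(seed)) {
    seed <- (config$seed + if (view == "top") 100003L else 200003L) %%
      2147483647L
  }
  labs <- behavior_labels()
  n <- nrow(d)
  .with_seed(seed, {
    keep_id <- stats::runif(n) >= error_model$identity_dropout_prob
    keep_bh <- stats::runif(n) >= error_model$behavior_dropout_prob
    # emitted behavior labels, sampled group-wise by (context row, truth)
    emitted <- character(n)
    has_rule <- function(ctx, b) {
      !is.null(error_model$context_rules[[ctx]]) &&
        !is.null(error_model$context_rules[[ctx]][[b]])
    }
    eff_ctx <- ifelse(mapply(has_rule, d$context, d$behavior),
                      d$context, "default")
    grp <- paste(eff_ctx, d$behavior)
    for (g in sort(unique(grp))) {
      rows <- which(grp == g)
      ctx <- eff_ctx[[rows[[1L]]]]
      b <- d$behavior[[rows[[1L]]]]
      p <- if (ctx == "default") error_model$base_confusion[b, ]
           else error_model$context_rules[[ctx]][[b]]
      emitted[rows] <- sample(labs, length(rows), replace = TRUE, prob = p)
    }
    jit <- function() matrix(stats::rnorm(n * 4L, sd = error_model$box_jitter_sd),
                             n, 4L)
    id_box <- .jitter_clip(d, jit(), config)
    bh_box <- .jitter_clip(d, jit(), config)
    conf <- matrix(stats::runif(2L * n, error_model$confidence_range[[1L]],
                                error_model$confidence_range[[2L]]), n, 2L)
    id_rows <- data.frame(
      frame_index = d$frame_index[keep_id],
      kind = rep("identity", sum(keep_id)),
      label = d$cow[keep_id], confidence = conf[keep_id, 1L],
      id_box[keep_id, , drop = FALSE], stringsAsFactors = FALSE)
    bh_rows <- data.frame(
      frame_index = d$frame_index[keep_bh],
      kind = rep("behavior", sum(keep_bh)),
      label = emitted[keep_bh], confidence = conf[keep_bh, 2L],
      bh_box[keep_bh, , drop = FALSE], stringsAsFactors = FALSE)
    detection_stream(view, config$image_width, config$image_height,
                     config$fps, rbind(id_rows, bh_rows),
                     frames = seq.int(0L, config$n_frames - 1L))
  })
}

.jitter_clip <- function(d, jitter, config) {
  x1 <- d$x_min + jitter[, 1L]; y1 <- d$y_min + jitter[, 2L]
  x2 <- d$x_max + jitter[, 3L]; y2 <- d$y_max + jitter[, 4L]
  lo_x <- pmin(x1, x2); hi_x <- pmax(x1, x2)
  lo_y <- pmin(y1, y2); hi_y <- pmax(y1, y2)
  .clip_boxes(lo_x, lo_y, hi_x, hi_y, config$image_width,
              config$image_height)
}

#' Generate a complete two-view synthetic dataset
#'
#' Runs [simulate_truth()], [project_views()] and [corrupt_detections()]
#' for both views, returning (and optionally writing) the two detection
#' streams, the ground-truth behavior table, and a dataset manifest.
#' With the shipped [default_error_models()] this is the package's
#' simulated study: rare estrus behaviors, a top view that floods
#' estrus labels from `stand`, and a milder, context-gated front view.
#'
#' @param scenario a [scenario_config()].
#' @param top_model,front_model [view_error_model()]s; default to
#'   [default_error_models()].
#' @param out_dir if non-`NULL`, write `top.jsonl`, `front.jsonl`,
#'   `truth.csv` and `dataset.yaml` there (and, with
#'   `format = "yolo_dir"`, YOLO directories `top/` and `front/`).
#' @param format on-disk stream format, `"jsonl"` or `"yolo_dir"`.
#' @return list with `top` and `front` [detection_stream()]s, `truth`
#'   (data frame `frame_index`, `cow`, `behavior`), and `paths` when
#'   written.
#' @export
generate_dataset <- function(scenario = scenario_config(),
                             top_model = default_error_models()$top,
                             front_model = default_error_models()$front,
                             out_dir = NULL,
                             format = c("jsonl", "yolo_dir")) {
  format <- match.arg(format)
  stopifnot(identical(top_model$view, "top"),
            identical(front_model$view, "front"))
  truth <- simulate_truth(scenario)
  proj <- project_views(truth, scenario)
  top <- corrupt_detections(proj, top_model)
  front <- corrupt_detections(proj, front_model)
  truth_tab <- as.data.frame(truth)[c("frame_index", "cow", "behavior")]
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (format == "jsonl") {
      top_path <- file.path(out_dir, "top.jsonl")
      front_path <- file.path(out_dir, "front.jsonl")
      write_stream(top, top_path, "jsonl")
      write_stream(front, front_path, "jsonl")
    } else {
      top_path <- file.path(out_dir, "top")
      front_path <- file.path(out_dir, "front")
      write_stream(top, top_path, "yolo_dir", roster = scenario$roster)
      write_stream(front, front_path, "yolo_dir", roster = scenario$roster)
    }
    truth_path <- file.path(out_dir, "truth.csv")
    utils::write.csv(truth_tab, truth_path, row.names = FALSE, quote = FALSE)
    manifest_path <- file.path(out_dir, "dataset.yaml")
    yaml::write_yaml(list(
      n_frames = scenario$n_frames, n_cows = scenario$n_cows,
      roster = as.list(scenario$roster),
      pen_width = scenario$pen_width, pen_depth = scenario$pen_depth,
      fps = scenario$fps, image_width = scenario$image_width,
      image_height = scenario$image_height, seed = scenario$seed,
      format = format), manifest_path)
    paths <- list(top = top_path, front = front_path, truth = truth_path,
                  manifest = manifest_path)
  }
  list(top = top, front = front, truth = truth_tab, paths = paths)
}
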