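test_that("compute_iou matches the hand cases and is well-behaved", {
  expect_equal(compute_iou(c(3, 4, 10, 12), c(3, 4, 10, 12)), 1.0)
  expect_equal(compute_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0.0)
  # brute-force pixel count: intersection 50, union 150
  expect_equal(compute_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3,
               tolerance = 1e-12)
})

test_that("compute_iou agrees with the pixel-counting oracle", {
  set.seed(101)
  for (i in 1:1000) {
    a <- random_int_box()
    b <- random_int_box()
    iou <- compute_iou(a, b)
    expect_equal(iou, pixel_iou_oracle(a, b), tolerance = 1e-9)
    expect_equal(iou, compute_iou(b, a))  # symmetry
    expect_gte(iou, 0); expect_lte(iou, 1)
  }
})

test_that("match_frame implements matching and both fallback branches", {
  cfg <- association_config(iou_threshold = 0.5)
  roster <- c("A", "B", "C")
  prev <- c(A = "stand", B = "lie", C = "drink")
  ids <- rbind(det_row(0, "identity", "A", 0.9, 0, 0, 10, 10),
               det_row(0, "identity", "B", 0.9, 50, 50, 60, 60))
  behs <- rbind(det_row(0, "behavior", "eat", 0.9, 0, 0, 10, 10),     # IoU 1 vs A
                det_row(0, "behavior", "ride", 0.9, 80, 80, 90, 90))  # disjoint
  res <- match_frame(ids, behs, prev, cfg, roster)
  a <- res[res$cow == "A", ]
  expect_equal(a$behavior, "eat")
  expect_equal(a$source, "matched")
  expect_equal(a$matched_iou, 1.0)
  # B's identity box overlaps nothing above threshold -> previous behavior
  b <- res[res$cow == "B", ]
  expect_equal(b$behavior, "lie")
  expect_equal(b$source, "fallback_low_iou")
  expect_true(is.na(b$matched_iou))
  # C has no identity box at all -> previous behavior
  cc <- res[res$cow == "C", ]
  expect_equal(cc$behavior, "drink")
  expect_equal(cc$source, "fallback_missing")
})

test_that("the max-IoU behavior box wins when several clear the threshold", {
  cfg <- association_config(iou_threshold = 0.5)
  ids <- det_row(0, "identity", "A", 0.9, 0, 0, 10, 10)
  behs <- rbind(det_row(0, "behavior", "stand", 0.99, 0, 0, 10, 6),  # IoU 0.6
                det_row(0, "behavior", "ride", 0.50, 0, 0, 10, 8))   # IoU 0.8
  res <- match_frame(ids, behs, c(A = "unknown"), cfg, "A")
  expect_equal(res$behavior, "ride")
  expect_equal(res$matched_iou, 0.8)
})

test_that("tie-breaks are deterministic", {
  cfg <- association_config(iou_threshold = 0.5)
  # two identity boxes for one cow: higher confidence wins
  ids <- rbind(det_row(0, "identity", "A", 0.6, 0, 0, 10, 10),
               det_row(0, "identity", "A", 0.9, 100, 100, 110, 110))
  behs <- det_row(0, "behavior", "eat", 0.9, 100, 100, 110, 110)
  res <- match_frame(ids, behs, c(A = "unknown"), cfg, "A")
  expect_equal(res$behavior, "eat")
  # equal confidence: larger area wins
  ids2 <- rbind(det_row(0, "identity", "A", 0.9, 0, 0, 10, 10),
                det_row(0, "identity", "A", 0.9, 100, 100, 120, 120))
  res2 <- match_frame(ids2, det_row(0, "behavior", "drink", 0.9, 100, 100,
                                120, 120),
                      c(A = "unknown"), cfg, "A")
  expect_equal(res2$behavior, "drink")
  # equal-IoU behavior boxes: higher confidence, then lexicographic name
  behs3 <- rbind(det_row(0, "behavior", "ride", 0.7, 0, 0, 10, 10),
                 det_row(0, "behavior", "eat", 0.9, 0, 0, 10, 10))
  res3 <- match_frame(det_row(0, "identity", "A", 1, 0, 0, 10, 10), behs3,
                      c(A = "unknown"), cfg, "A")
  expect_equal(res3$behavior, "eat")
  behs4 <- rbind(det_row(0, "behavior", "ride", 0.9, 0, 0, 10, 10),
                 det_row(0, "behavior", "eat", 0.9, 0, 0, 10, 10))
  res4 <- match_frame(det_row(0, "identity", "A", 1, 0, 0, 10, 10), behs4,
                      c(A = "unknown"), cfg, "A")
  expect_equal(res4$behavior, "eat")
})

test_that("one behavior box may serve several cows", {
  cfg <- association_config(iou_threshold = 0.5)
  ids <- rbind(det_row(0, "identity", "A", 0.9, 0, 0, 10, 10),
               det_row(0, "identity", "B", 0.9, 1, 0, 11, 10))
  behs <- det_row(0, "behavior", "ride", 0.9, 0, 0, 11, 10)
  res <- match_frame(ids, behs, c(A = "unknown", B = "unknown"), cfg,
                     c("A", "B"))
  expect_equal(res$behavior, c("ride", "ride"))
  expect_equal(res$source, c("matched", "matched"))
})

test_that("identity labels outside the roster are an error", {
  expect_error(
    match_frame(det_row(0, "identity", "D", 0.9, 0, 0, 10, 10), NULL,
                c(A = "unknown"), association_config(), "A"),
    "roster")
})

test_that("fallback carries behavior through absence; no detections means unknown", {
  cfg <- association_config()
  # matched 'eat' at frame 0, then the cow disappears for frames 1-4
  d <- rbind(det_row(0, "identity", "A", 0.9, 0, 0, 10, 10),
             det_row(0, "behavior", "eat", 0.9, 0, 0, 10, 10))
  s <- detection_stream("top", 100, 100, 10, d, frames = 0:4)
  tl <- associate_stream(s, cfg, roster = "A")
  expect_equal(tl$behavior, rep("eat", 5))
  expect_equal(tl$source, c("matched", rep("fallback_missing", 4)))

  # never detected: the whole timeline is the unknown sentinel
  s2 <- detection_stream("top", 100, 100, 10, NULL, frames = 0:9)
  tl2 <- associate_stream(s2, cfg, roster = "A")
  expect_equal(tl2$behavior, rep("unknown", 10))
  expect_equal(tl2$source, rep("initial_unknown", 10))

  # the fixed-label initial policy seeds the fallback state instead
  tl3 <- associate_stream(s2, association_config(
    initial_behavior_policy = "fixed_label", fixed_initial_label = "stand"),
    roster = "A")
  expect_equal(tl3$behavior, rep("stand", 10))

  expect_error(associate_stream(
    detection_stream("top", 100, 100, 10, NULL, frames = integer(0)),
    cfg, roster = "A"), "empty")
})

test_that("a noiseless simulated stream reproduces ground truth", {
  sc <- scenario_config(n_frames = 400, seed = 3)
  truth <- simulate_truth(sc)
  stream <- corrupt_detections(project_views(truth, sc),
                               zero_noise_error_model("top"))
  tl <- associate_stream(stream, association_config(), sc$roster)
  expect_true(all(tl$source == "matched"))
  key <- paste(tl$cow, tl$frame_index)
  tkey <- paste(truth$cow, truth$frame_index)
  expect_equal(tl$behavior, truth$behavior[match(key, tkey)])
})

test_that("iou_threshold = 1 never matches (strict inequality)", {
  s <- small_noisy_stream(seed = 21)
  tl <- associate_stream(s, association_config(iou_threshold = 1),
                         c("A", "B", "C"))
  expect_equal(sum(tl$source == "matched"), 0L)
})

test_that("raising the threshold never increases matched entries", {
  s <- small_noisy_stream(seed = 22, n_frames = 150)
  matched <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    tl <- associate_stream(s, association_config(iou_threshold = th),
                           c("A", "B", "C"))
    sum(tl$source == "matched")
  }, 1L)
  expect_true(all(diff(matched) <= 0))
  expect_gt(matched[[1L]], 0L)
})

test_that("association is causal: edits cannot reach earlier frames", {
  for (seed in 31:33) {
    s <- small_noisy_stream(seed = seed)
    cfg <- association_config()
    tl <- associate_stream(s, cfg, c("A", "B", "C"))
    cut <- 30L
    keep <- s$detections$frame_index < cut |
      s$detections$frame_index > cut
    tl2 <- associate_stream(drop_detections(s, keep), cfg, c("A", "B", "C"))
    before <- tl$frame_index < cut
    expect_equal(as.data.frame(tl2)[before, ], as.data.frame(tl)[before, ])
  }
})
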