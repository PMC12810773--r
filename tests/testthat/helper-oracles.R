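# Brute-force pixel-counting IoU for integer-coordinate boxes under the
# half-open convention: a box covers pixels x_min .. x_max-1. Independent
# of the analytic implementation.
pixel_iou_oracle <- function(a, b) {
  px <- function(bx) {
    xs <- seq.int(bx[[1L]], bx[[3L]] - 1L)
    ys <- seq.int(bx[[2L]], bx[[4L]] - 1L)
    as.vector(outer(xs, ys, function(x, y) paste(x, y)))
  }
  pa <- px(a); pb <- px(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

random_int_box <- function(max_coord = 30L, max_size = 15L) {
  x1 <- sample.int(max_coord, 1L) - 1L
  y1 <- sample.int(max_coord, 1L) - 1L
  c(x1, y1, x1 + sample.int(max_size, 1L), y1 + sample.int(max_size, 1L))
}

# Long-run behavior occupancy of the simulator's semi-Markov process:
# stationary distribution of the embedded jump chain (next behavior drawn
# from the stationary probs excluding the current one), weighted by mean
# dwell. Computed numerically by eigen-decomposition, independently of
# the simulation path.
occupancy_oracle <- function(probs, dwell) {
  labs <- names(probs)
  active <- labs[probs > 0]
  p <- probs[active]
  k <- length(active)
  P <- matrix(0, k, k, dimnames = list(active, active))
  for (i in seq_len(k)) {
    row <- p
    row[[i]] <- 0
    P[i, ] <- row / sum(row)
  }
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_embed <- v / sum(v)
  occ <- pi_embed * dwell[active]
  out <- stats::setNames(numeric(length(labs)), labs)
  out[active] <- occ / sum(occ)
  out
}

# build a ground_truth object by hand for projection tests
make_truth <- function(df, config) {
  df <- df[order(df$frame_index, df$cow), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ground_truth", "data.frame"), config = config)
}
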