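# Independent brute-force references used across the suite.

# random valid box table inside a frame
random_boxes <- function(n, frame = c(100, 100), scored = FALSE) {
  x0 <- runif(n, 0, frame[2] - 2)
  y0 <- runif(n, 0, frame[1] - 2)
  b <- boxes(x0, y0,
             x0 + runif(n, 1, frame[2] - x0),
             y0 + runif(n, 1, frame[1] - y0))
  if (scored) b$score <- runif(n)
  b
}

# NMS by literal definition: walk in score order (same tie-break), keep a
# box iff it clears every kept box
nms_reference <- function(b, thr) {
  ord <- order(-b$score, b$y0, b$x0, b$x1, b$y1)
  b <- b[ord, ]
  kept <- b[0, ]
  for (i in seq_len(nrow(b))) {
    ok <- TRUE
    for (j in seq_len(nrow(kept))) {
      if (box_iou(b[i, ], kept[j, ])[1, 1] >= thr) { ok <- FALSE; break }
    }
    if (ok) kept <- rbind(kept, b[i, ])
  }
  kept
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# exhaustive minimum assignment cost over the smaller dimension
assignment_reference <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) return(assignment_reference(t(cost)))
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in all_permutations(cols)) {
      best <- min(best, sum(cost[cbind(seq_len(n), p)]))
    }
  }
  best
}

# region filter pipeline by literal re-statement of its steps
filter_reference <- function(regions, min_pi = 0.88, min_st = 0.95,
                             nms = 0.5, min_area = 2000, top_k = 10) {
  keep <- regions[regions$pred_iou >= min_pi & regions$stability >= min_st, ]
  if (nrow(keep)) {
    keep$score <- keep$rank_score
    keep <- nms_reference(keep, nms)
    keep$score <- NULL
  }
  keep <- keep[keep$area_px >= min_area, ]
  keep <- keep[order(-keep$rank_score), ]
  utils::head(keep, top_k)
}

# a square region table built directly from box corners
square_regions <- function(x0, y0, side, pred_iou, stability,
                           frame = c(256, 448), label = NULL) {
  masks <- lapply(seq_along(x0), function(i) {
    m <- matrix(FALSE, frame[1], frame[2])
    m[(y0[i] + 1):(y0[i] + side[i]), (x0[i] + 1):(x0[i] + side[i])] <- TRUE
    m
  })
  candidate_regions(masks, pred_iou, stability, label = label)
}

# single-channel CAM with given matrix
one_channel_cam <- function(m, class = "grasper", frame = c(256, 448)) {
  cam_grid(array(m, c(dim(m), 1)), class, frame)
}

# minimal annotation set from a gt tibble
make_annotations <- function(gt, width = 448, height = 256) {
  ann <- list(video_id = "fixture",
              frames = tibble::tibble(frame_id = unique(gt$frame_id),
                                      width = width, height = height),
              gt = gt, classes = sort(unique(gt$label)))
  ann
}
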