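#' Read / write bounding-box annotations
#'
#' Ground truth is exchanged as JSON:
#' `{video_id, frames: [{frame_id, width, height, boxes: [{x0, y0, x1, y1,
#' label}]}]}`. In memory an annotation set is a list with a `frames`
#' tibble (`frame_id`, `width`, `height`) and a `gt` tibble of boxes
#' (`frame_id`, `x0..y1`, `label`), plus the class list.
#'
#' @param annotations An annotation set (as returned by `read_annotations`
#'   or [generate_scenes()]).
#' @param path JSON file path.
#' @param video_id Identifier stored in the file.
#' @return `write_annotations()` the path, invisibly; `read_annotations()`
#'   an annotation set.
#' @export
write_annotations <- function(annotations, path, video_id = NULL) {
  fr <- annotations$frames; gt <- annotations$gt
  frames <- lapply(seq_len(nrow(fr)), function(i) {
    b <- gt[gt$frame_id == fr$frame_id[i], ]
    list(frame_id = fr$frame_id[i], width = fr$width[i],
         height = fr$height[i],
         boxes = lapply(seq_len(nrow(b)), function(j) {
           list(x0 = b$x0[j], y0 = b$y0[j], x1 = b$x1[j], y1 = b$y1[j],
                label = b$label[j])
         }))
  })
  jsonlite::write_json(
    list(video_id = video_id %||% annotations$video_id %||% "synthetic",
         frames = frames),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fr <- purrr::map_dfr(obj$frames, function(f) {
    tibble::tibble(frame_id = f$frame_id, width = f$width,
                   height = f$height)
  })
  gt <- purrr::map_dfr(obj$frames, function(f) {
    purrr::map_dfr(f$boxes, function(b) {
      tibble::tibble(frame_id = f$frame_id, x0 = b$x0, y0 = b$y0,
                     x1 = b$x1, y1 = b$y1, label = b$label)
    })
  })
  ann <- list(video_id = obj$video_id, frames = fr, gt = gt,
              classes = sort(unique(gt$label)))
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  stopifnot(is.list(ann), is.data.frame(ann$frames), is.data.frame(ann$gt))
  gt <- validate_boxes(ann$gt)
  fr <- ann$frames
  merged <- dplyr::left_join(gt, fr, by = "frame_id")
  if (any(is.na(merged$width)) ||
      any(merged$x1 > merged$width) || any(merged$y1 > merged$height)) {
    stop("ground-truth box outside its frame, or unknown frame_id")
  }
  if (is.null(ann$classes)) ann$classes <- sort(unique(gt$label))
  if (!all(gt$label %in% ann$classes)) {
    stop("ground-truth label outside the class list")
  }
  ann
}

#' Assign TP/FP flags for one class at one IoU threshold
#'
#' Detections (already restricted to a single class) are processed in
#' descending score order, ties broken by best available IoU. Each
#' detection becomes a true positive if some not-yet-consumed ground-truth
#' box of the same frame reaches IoU >= `iou_threshold` (the detection
#' consumes the GT with the highest IoU); otherwise it is a false
#' positive. Ground truths never consumed are false negatives.
#'
#' @param detections Tibble with `frame_id`, box columns and `score`.
#' @param gts Tibble of ground-truth boxes with `frame_id`.
#' @param iou_threshold Threshold in `[0, 1]`.
#' @return List: `detections` (input rows sorted by descending score, with
#'   a logical `tp` column), `fn` (count of unmatched ground truths).
#' @export
assign_detections <- function(detections, gts, iou_threshold = 0.5) {
  if (nrow(detections) == 0) {
    return(list(detections = dplyr::mutate(detections, tp = logical(0)),
                fn = nrow(gts)))
  }
  ord <- order(-detections$score)
  det <- detections[ord, ]
  iou <- iou_core(det, gts)
  # detections may only consume ground truths of their own frame
  iou[outer(det$frame_id, gts$frame_id, "!=")] <- -1
  tp <- greedy_tp(iou, iou_threshold)
  det$tp <- tp
  list(detections = det, fn = nrow(gts) - sum(tp))
}

# greedy TP flags given a (score-ordered detections) x (gts) IoU matrix
greedy_tp <- function(iou, threshold) {
  n <- nrow(iou)
  tp <- logical(n)
  if (ncol(iou) == 0) return(tp)
  free <- rep(TRUE, ncol(iou))
  for (i in seq_len(n)) {
    cand <- which(free)
    if (!length(cand)) break
    best <- cand[which.max(iou[i, cand])]
    if (iou[i, best] >= threshold) {
      tp[i] <- TRUE
      free[best] <- FALSE
    }
  }
  tp
}

#' Average precision for one class
#'
#' Sweeps the score-ranked detections, accumulating precision
#' `TP / (TP + FP)` against recall `TP / (TP + FN)`, and integrates
#' precision over recall using the all-points interpolation: the precision
#' curve is first made monotone non-increasing from the right (each point
#' takes the maximum precision at any equal-or-higher recall), then the
#' area is summed over recall increments. A detector that ranks a true
#' positive for every ground truth ahead of any false positive scores 1.
#'
#' @inheritParams assign_detections
#' @return Scalar AP in `[0, 1]`, or `NA` when the class has no ground
#'   truth (undefined; excluded from macro means).
#' @export
average_precision <- function(detections, gts, iou_threshold = 0.5) {
  n_gt <- nrow(gts)
  if (n_gt == 0) return(NA_real_)
  if (nrow(detections) == 0) return(0)
  a <- assign_detections(detections, gts, iou_threshold)
  ap_from_flags(a$detections$tp, n_gt)
}

ap_from_flags <- function(tp, n_gt) {
  tp_cum <- cumsum(tp)
  fp_cum <- cumsum(!tp)
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Average recall for one class
#'
#' Recall is computed at each IoU threshold of the grid (the TP/FN
#' assignment is redone independently per threshold), the recall-vs-IoU
#' curve is integrated over `[0.5, 1]` by the trapezoid rule, and the area
#' is doubled so that a detector with recall 1 across the whole interval
#' scores exactly 1. The curve is evaluated at the grid points plus the
#' right endpoint 1.0 so the integral covers the full interval.
#'
#' @inheritParams assign_detections
#' @param iou_grid Increasing thresholds spanning `[0.5, 0.95]` by
#'   default.
#' @return Scalar AR in `[0, 1]`, or `NA` when the class has no ground
#'   truth.
#' @export
average_recall <- function(detections, gts,
                           iou_grid = seq(0.5, 0.95, by = 0.05)) {
  n_gt <- nrow(gts)
  if (n_gt == 0) return(NA_real_)
  grid <- sort(unique(c(iou_grid, 1)))
  if (nrow(detections) == 0) {
    rec <- rep(0, length(grid))
  } else {
    ord <- order(-detections$score)
    det <- detections[ord, ]
    iou <- iou_core(det, gts)
    iou[outer(det$frame_id, gts$frame_id, "!=")] <- -1
    rec <- vapply(grid, function(th) sum(greedy_tp(iou, th)) / n_gt,
                  numeric(1))
  }
  widths <- diff(grid)
  2 * sum(widths * (rec[-1] + rec[-length(rec)]) / 2)
}

#' Evaluate detections against an annotation set
#'
#' Per-class average precision at `iou_threshold` (mAP\@0.5 by default) and
#' average recall over the IoU grid, macro-averaged over the classes with
#' at least one ground-truth instance; classes without ground truth are
#' reported `NA` and excluded from the means.
#'
#' @param detections Detection tibble (`frame_id`, box columns, `label`,
#'   `score`).
#' @param annotations Annotation set (see [read_annotations()]).
#' @param iou_threshold IoU threshold for AP.
#' @param iou_grid Threshold grid for AR.
#' @param taxonomy Optional [class_taxonomy()]; when given, the report
#'   also carries instrument-only and target-only macro means.
#' @return A `metric_report`: list with `per_class` tibble (`label`,
#'   `n_gt`, `n_det`, `ap`, `ar`), `mAP`, `mAR`, optional `instrument` and
#'   `target` summaries, and the thresholds used. [tidy()] returns the
#'   per-class table, [glance()] the one-row summary.
#' @export
evaluate_detections <- function(detections, annotations,
                                iou_threshold = 0.5,
                                iou_grid = seq(0.5, 0.95, by = 0.05),
                                taxonomy = NULL) {
  annotations <- validate_annotations(annotations)
  gt <- annotations$gt
  if (nrow(gt) == 0) stop("no class has ground-truth instances")
  classes <- annotations$classes
  if (nrow(detections) && !all(detections$label %in% classes)) {
    stop("detection label(s) outside the annotation class list")
  }
  per <- purrr::map_dfr(classes, function(cl) {
    d <- detections[detections$label == cl, , drop = FALSE]
    g <- gt[gt$label == cl, , drop = FALSE]
    tibble::tibble(
      label = cl, n_gt = nrow(g), n_det = nrow(d),
      ap = average_precision(d, g, iou_threshold),
      ar = average_recall(d, g, iou_grid))
  })
  scored <- per[per$n_gt > 0, ]
  rep <- list(per_class = per,
              mAP = mean(scored$ap), mAR = mean(scored$ar),
              iou_threshold = iou_threshold, iou_grid = iou_grid)
  if (!is.null(taxonomy)) {
    kind <- class_kind(scored$label, taxonomy)
    rep$instrument <- list(mAP = mean(scored$ap[kind == "Instrument"]),
                           mAR = mean(scored$ar[kind == "Instrument"]))
    rep$target <- list(mAP = mean(scored$ap[kind == "Tissue"]),
                       mAR = mean(scored$ar[kind == "Tissue"]))
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Detection metrics (AP@IoU ", format(x$iou_threshold), ", AR over [",
      min(x$iou_grid), ", 1])\n", sep = "")
  p <- x$per_class
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-22s AP %6s  AR %6s  (gt %d, det %d)\n", p$label[i],
                fmt_pct(p$ap[i]), fmt_pct(p$ar[i]), p$n_gt[i], p$n_det[i]))
  }
  cat(sprintf("  %-22s mAP %5s  mAR %5s\n", "macro",
              fmt_pct(x$mAP), fmt_pct(x$mAR)))
  if (!is.null(x$instrument)) {
    cat(sprintf("  %-22s mAP %5s  mAR %5s\n", "instruments",
                fmt_pct(x$instrument$mAP), fmt_pct(x$instrument$mAR)))
    cat(sprintf("  %-22s mAP %5s  mAR %5s\n", "targets",
                fmt_pct(x$target$mAP), fmt_pct(x$target$mAR)))
  }
  invisible(x)
}

fmt_pct <- function(x) {
  if (is.na(x)) "   NA" else sprintf("%.2f%%", 100 * x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_detections
#' @param x A `metric_report`.
#' @param ... Unused.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_class

#' @rdname evaluate_detections
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  out <- tibble::tibble(mAP = x$mAP, mAR = x$mAR,
                        iou_threshold = x$iou_threshold,
                        n_classes = sum(x$per_class$n_gt > 0))
  if (!is.null(x$instrument)) {
    out$instrument_mAP <- x$instrument$mAP
    out$instrument_mAR <- x$instrument$mAR
    out$target_mAP <- x$target$mAP
    out$target_mAR <- x$target$mAR
  }
  out
}
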