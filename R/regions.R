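#' Build a candidate-region table from binary masks
#'
#' Candidate regions are scored binary masks proposed by a promptable
#' segmentation backend (or by the synthetic generator). Each region
#' carries the backend's predicted-IoU (confidence) and stability scores;
#' the tight bounding box, pixel area and rank score
#' `(pred_iou + stability) / 2` are derived here from the mask itself.
#'
#' @param masks A list of logical (or 0/1) matrices, all of the same frame
#'   size, each with at least one true pixel.
#' @param pred_iou,stability Numeric score vectors in `[0, 1]`, one per
#'   mask.
#' @param label Optional per-region label (e.g. oracle
#'   `"Instrument"`/`"Tissue"` tags from a fixture).
#' @param frame_id Optional frame identifier column.
#' @return A tibble with list-column `mask` and columns `pred_iou`,
#'   `stability`, `rank_score`, `area_px`, `x0, y0, x1, y1` (tight bbox,
#'   half-open pixels) plus `label`/`frame_id` when given.
#' @export
candidate_regions <- function(masks, pred_iou, stability, label = NULL,
                              frame_id = NULL) {
  stopifnot(is.list(masks), length(masks) == length(pred_iou),
            length(masks) == length(stability))
  if (!length(masks)) return(empty_regions())
  if (any(pred_iou < 0 | pred_iou > 1) || any(stability < 0 | stability > 1)) {
    stop("pred_iou and stability scores must lie in [0, 1]")
  }
  masks <- lapply(masks, function(m) {
    m <- m > 0
    if (!any(m)) stop("candidate region mask has no positive pixel")
    m
  })
  fs <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), fs), logical(1)))) {
    stop("all masks in a frame must share one frame size")
  }
  bb <- t(vapply(masks, mask_bbox, numeric(4)))
  out <- tibble::tibble(
    mask = masks,
    pred_iou = as.numeric(pred_iou),
    stability = as.numeric(stability),
    rank_score = (as.numeric(pred_iou) + as.numeric(stability)) / 2,
    area_px = vapply(masks, sum, numeric(1)),
    x0 = bb[, 1], y0 = bb[, 2], x1 = bb[, 3], y1 = bb[, 4]
  )
  if (!is.null(label)) out$label <- rep_len(label, nrow(out))
  if (!is.null(frame_id)) out$frame_id <- rep_len(frame_id, nrow(out))
  attr(out, "frame_size") <- as.integer(fs)
  out
}

empty_regions <- function() {
  tibble::tibble(mask = list(), pred_iou = numeric(), stability = numeric(),
                 rank_score = numeric(), area_px = numeric(),
                 x0 = numeric(), y0 = numeric(), x1 = numeric(),
                 y1 = numeric())
}

# Tight half-open bbox (x0, y0, x1, y1) of a logical matrix.
mask_bbox <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
}

#' Filter, rank and truncate candidate regions
#'
#' The region-proposal pipeline applied to each frame's raw candidate set,
#' in order: (1) keep regions with `pred_iou >= min_pred_iou` and
#' `stability >= min_stability`; (2) greedy NMS on region bounding boxes
#' scored by `rank_score`; (3) drop regions strictly smaller than
#' `min_area_px` pixels (small spurious components from reflections or
#' water stains); (4) sort by `rank_score` descending; (5) truncate to the
#' `top_k` proposals. The operation is idempotent.
#'
#' @param regions A region table from [candidate_regions()] or
#'   [read_regions()].
#' @param min_pred_iou,min_stability Score floors in `[0, 1]`. Defaults are
#'   the reference automatic-mask-generation settings.
#' @param nms_threshold IoU threshold for bbox NMS.
#' @param min_area_px Minimum pixel area kept (strict `>=`; a 1999 px
#'   region is dropped at the default 2000).
#' @param top_k Maximum number of proposals returned.
#' @return The surviving rows, `rank_score` non-increasing.
#' @export
filter_regions <- function(regions, min_pred_iou = 0.88,
                           min_stability = 0.95, nms_threshold = 0.5,
                           min_area_px = 2000, top_k = 10) {
  stopifnot(is.data.frame(regions), min_area_px >= 0, top_k >= 1,
            min_pred_iou >= 0, min_pred_iou <= 1,
            min_stability >= 0, min_stability <= 1)
  fs <- attr(regions, "frame_size")
  out <- dplyr::filter(regions, .data$pred_iou >= min_pred_iou,
                       .data$stability >= min_stability)
  if (nrow(out) > 0) {
    out$score <- out$rank_score
    out <- box_nms(out, nms_threshold)
    out$score <- NULL
  }
  out <- dplyr::filter(out, .data$area_px >= min_area_px)
  out <- dplyr::arrange(out, dplyr::desc(.data$rank_score))
  out <- utils::head(out, top_k)
  attr(out, "frame_size") <- fs
  out
}

#' Read / write per-frame candidate regions
#'
#' Masks are stored one PNG per region (grayscale, 0/255) next to a JSON
#' manifest holding the frame id, frame size and per-region scores, area
#' and bounding box. The round trip is bit-exact for masks and scores; on
#' load, area and bbox are recomputed from the mask and must agree with the
#' manifest.
#'
#' @param regions A region table (see [candidate_regions()]).
#' @param manifest_path Path of the JSON manifest; mask PNGs are written to
#'   the same directory.
#' @param frame_id Frame identifier recorded in the manifest (defaults to
#'   the table's `frame_id` or `"frame"`).
#' @return `write_regions()` the manifest path, invisibly; `read_regions()`
#'   a region table with a `frame_size` attribute and `frame_id` column.
#' @export
write_regions <- function(regions, manifest_path, frame_id = NULL) {
  stopifnot(is.data.frame(regions))
  if (is.null(frame_id)) {
    frame_id <- if (!is.null(regions$frame_id) && nrow(regions) > 0)
      regions$frame_id[1] else "frame"
  }
  dir <- dirname(manifest_path)
  fs <- attr(regions, "frame_size")
  if (is.null(fs) && nrow(regions) > 0) fs <- dim(regions$mask[[1]])
  recs <- lapply(seq_len(nrow(regions)), function(i) {
    mf <- sprintf("%s_region_%03d.png", frame_id, i)
    png::writePNG(regions$mask[[i]] * 1, file.path(dir, mf))
    list(mask_file = mf, pred_iou = regions$pred_iou[i],
         stability = regions$stability[i], area_px = regions$area_px[i],
         bbox = c(regions$x0[i], regions$y0[i], regions$x1[i],
                  regions$y1[i]),
         label = if (!is.null(regions$label)) regions$label[i] else NULL)
  })
  jsonlite::write_json(
    list(frame_id = frame_id, frame_size = fs, regions = recs),
    manifest_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest_path)
}

#' @rdname write_regions
#' @export
read_regions <- function(manifest_path) {
  obj <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  fs <- as.integer(unlist(obj$frame_size))
  dir <- dirname(manifest_path)
  if (!length(obj$regions)) {
    out <- empty_regions()
    attr(out, "frame_size") <- fs
    return(out)
  }
  masks <- list(); pred <- stab <- numeric(0); labs <- character(0)
  has_lab <- FALSE
  for (i in seq_along(obj$regions)) {
    r <- obj$regions[[i]]
    who <- sprintf("region %d (%s)", i, r$mask_file %||% "?")
    mp <- file.path(dir, r$mask_file)
    if (!file.exists(mp)) stop("missing mask file for ", who)
    m <- png::readPNG(mp)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m <- m > 0.5
    if (!identical(dim(m), as.integer(fs))) {
      stop("mask size mismatch with frame size for ", who)
    }
    if (r$pred_iou < 0 || r$pred_iou > 1 || r$stability < 0 ||
        r$stability > 1) {
      stop("scores outside [0, 1] for ", who)
    }
    if (sum(m) != r$area_px) {
      stop("manifest area (", r$area_px, ") disagrees with mask (",
           sum(m), " px) for ", who)
    }
    bb <- mask_bbox(m)
    if (!isTRUE(all.equal(bb, as.numeric(unlist(r$bbox))))) {
      stop("manifest bbox disagrees with mask bounds for ", who)
    }
    masks[[i]] <- m; pred[i] <- r$pred_iou; stab[i] <- r$stability
    if (!is.null(r$label)) { has_lab <- TRUE; labs[i] <- r$label }
  }
  candidate_regions(masks, pred, stab,
                    label = if (has_lab) labs else NULL,
                    frame_id = obj$frame_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
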