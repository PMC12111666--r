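#' Class activation map grid
#'
#' A CAM grid holds an `H x W x C` array of pre-pooling activations (H rows
#' of activation points vertically, W columns horizontally, one channel per
#' class) together with the pixel size of the source frame, so grid cells
#' can be lifted to pixel boxes. Cells with value > 0 are "positive" and
#' carry class evidence; the default resolution used throughout is 8 x 14
#' over 256 x 448 frames, i.e. square 32 px cells.
#'
#' @param values Numeric `H x W x C` array (a matrix is promoted to one
#'   channel). All values must be finite.
#' @param class_names Character vector of length C naming the channels.
#' @param frame_size `c(height_px, width_px)` of the source frame; each
#'   frame dimension must be at least the matching grid dimension.
#' @return An object of class `cam_grid`.
#' @export
cam_grid <- function(values, class_names, frame_size) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3)
  d <- dim(values)
  if (any(d < 1)) stop("CAM grid needs H >= 1, W >= 1, C >= 1")
  if (!all(is.finite(values))) stop("CAM values must be finite")
  class_names <- as.character(class_names)
  if (length(class_names) != d[3]) {
    stop("class_names length (", length(class_names),
         ") must equal channel count (", d[3], ")")
  }
  frame_size <- as.numeric(frame_size)
  stopifnot(length(frame_size) == 2, all(frame_size >= d[1:2]))
  structure(
    list(values = values, class_names = class_names,
         frame_size = frame_size),
    class = "cam_grid"
  )
}

#' @export
print.cam_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<cam_grid> ", d[1], "x", d[2], " cells, ", d[3], " channel(s), frame ",
      x$frame_size[1], "x", x$frame_size[2], " px\n", sep = "")
  cat("channels:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cam_grid <- function(x) dim(x$values)

cam_cell_size <- function(cam) {
  d <- dim(cam$values)
  c(h = cam$frame_size[1] / d[1], w = cam$frame_size[2] / d[2])
}

#' Infer the signed attention-guide shift from a single channel
#'
#' Instruments enter the laparoscopic scene from the periphery and move
#' toward its center, so the forward direction of an instrument — and hence
#' the direction in which the operated tissue lies — is taken as pointing
#' from the instrument's activation toward the grid center. Among the
#' 4-connected positive components of the channel the one with maximal mean
#' activation is selected (multiple activation areas arise when several
#' instruments share a class channel); its activation-weighted centroid
#' `(rbar, cbar)` determines the sign component-wise:
#' `kh = sign((W-1)/2 - cbar) * kh_mag`,
#' `kv = sign((H-1)/2 - rbar) * kv_mag`, with positive `kv` meaning a
#' downward shift in screen coordinates. `sign(0)` is 0.
#'
#' @param channel Numeric `H x W` matrix (one CAM channel).
#' @param kh_mag,kv_mag Non-negative integer shift magnitudes in cells.
#' @return A list with integer `kh`, `kv` and logical `no_activation`
#'   (`TRUE` when the channel has no positive cell; the shift is then 0).
#' @export
infer_forward_shift <- function(channel, kh_mag = 2L, kv_mag = 2L) {
  stopifnot(is.matrix(channel), kh_mag >= 0, kv_mag >= 0)
  H <- nrow(channel); W <- ncol(channel)
  stopifnot(kh_mag <= W, kv_mag <= H)
  lab <- label_components(channel > 0)
  if (max(lab) == 0) {
    return(list(kh = 0L, kv = 0L, no_activation = TRUE))
  }
  means <- vapply(seq_len(max(lab)), function(k) mean(channel[lab == k]),
                  numeric(1))
  k <- which.max(means)
  idx <- which(lab == k, arr.ind = TRUE)
  w <- channel[lab == k]
  rbar <- sum((idx[, 1] - 1) * w) / sum(w)
  cbar <- sum((idx[, 2] - 1) * w) / sum(w)
  list(kh = as.integer(sign((W - 1) / 2 - cbar) * kh_mag),
       kv = as.integer(sign((H - 1) / 2 - rbar) * kv_mag),
       no_activation = FALSE)
}

#' Cyclically shift attention-guide channels
#'
#' Channel-wise toroidal translation of a CAM: the value at activation
#' point `(x, y)` moves to `((x + kh) mod W, (y + kv) mod H)`. The shift is
#' exactly mass-preserving — the per-channel sum of activations is
#' unchanged — and shifting by `(kh, kv)` then `(-kh, -kv)` is the
#' identity. Activation mass that wraps across a grid edge is physically
#' dubious (an instrument leaving bottom-right does not reappear top-left),
#' so `clip_wrap = TRUE` instead drops wrapped mass, zero-filling the
#' vacated cells; the default keeps the literal modular rule.
#'
#' @param cam A [cam_grid()].
#' @param shifts Either a single `c(kh, kv)` applied to all channels, or a
#'   data frame with columns `channel` (index or class name), `kh`, `kv`.
#'   Channels not listed are left unshifted.
#' @param clip_wrap If `TRUE`, mass shifted past an edge is discarded
#'   rather than wrapped.
#' @return A `cam_grid` of the same shape.
#' @export
agc_shift <- function(cam, shifts, clip_wrap = FALSE) {
  stopifnot(inherits(cam, "cam_grid"))
  d <- dim(cam$values); H <- d[1]; W <- d[2]; C <- d[3]
  if (is.numeric(shifts) && length(shifts) == 2) {
    shifts <- tibble::tibble(channel = seq_len(C),
                             kh = shifts[1], kv = shifts[2])
  }
  stopifnot(is.data.frame(shifts),
            all(c("channel", "kh", "kv") %in% names(shifts)))
  ch <- shifts$channel
  if (is.character(ch)) ch <- match(ch, cam$class_names)
  if (anyNA(ch) || any(ch < 1) || any(ch > C)) stop("unknown CAM channel")
  stopifnot(all(abs(shifts$kh) <= W), all(abs(shifts$kv) <= H))
  out <- cam$values
  for (i in seq_along(ch)) {
    kh <- as.integer(shifts$kh[i]); kv <- as.integer(shifts$kv[i])
    plane <- cam$values[, , ch[i]]
    rows <- ((seq_len(H) - 1 + kv) %% H) + 1   # destination of row r
    cols <- ((seq_len(W) - 1 + kh) %% W) + 1
    new <- matrix(0, H, W)
    new[rows, cols] <- plane
    if (clip_wrap) {
      wrapped_r <- (seq_len(H) - 1 + kv) != (rows - 1)
      wrapped_c <- (seq_len(W) - 1 + kh) != (cols - 1)
      new[rows[wrapped_r], ] <- 0
      new[, cols[wrapped_c]] <- 0
    }
    out[, , ch[i]] <- new
  }
  cam_grid(out, cam$class_names, cam$frame_size)
}

# 4-connected component labelling of a logical matrix; returns an integer
# matrix of labels (0 = background). Grids here are tiny (8x14 default), so
# a plain BFS is proportionate.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r <- p[1] + d[1]; s <- p[2] + d[2]
        if (r >= 1 && r <= H && s >= 1 && s <= W &&
            mask[r, s] && lab[r, s] == 0L) {
          lab[r, s] <- cur
          queue <- rbind(queue, c(r, s))
        }
      }
    }
  }
  lab
}

# Local maxima of a channel: cells > 0 that are >= all 8-neighbours
# (out-of-grid neighbours count as -Inf). All cells of a plateau qualify;
# extract_prelim_boxes() deduplicates by component and records the
# top-left-most peak.
local_maxima <- function(channel) {
  H <- nrow(channel); W <- ncol(channel)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- channel
  best <- matrix(-Inf, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    best <- pmax(best, pad[2:(H + 1) + dr, 2:(W + 1) + dc])
  }
  channel > 0 & channel >= best
}

#' Extract preliminary boxes from a CAM
#'
#' For each channel flagged present in the frame: (1) find positive local
#' maxima (8-neighbourhood); (2) grow the 4-connected positive component
#' around each peak; (3) lift the component's cell bounding box to frame
#' pixels (cell `(r, c)` covers the half-open pixel rectangle
#' `[c*cell_w, (c+1)*cell_w) x [r*cell_h, (r+1)*cell_h)`); (4) per-channel
#' NMS scored by the component's mean activation. The union over channels
#' is the preliminary box set.
#'
#' @param cam A [cam_grid()].
#' @param presence Logical vector (length C) or character vector of class
#'   names marking channels predicted present; defaults to all channels.
#' @param positive_threshold Activation strictly above this value counts as
#'   positive (default 0, matching pre-pooling logit maps).
#' @param nms_threshold IoU threshold for the per-channel NMS.
#' @return A tibble of preliminary boxes: `x0, y0, x1, y1` (frame pixels),
#'   `channel` (index), `label` (class name), `mean_activation` (> 0),
#'   `peak_row`, `peak_col` (0-based cell of the seeding maximum).
#' @export
extract_prelim_boxes <- function(cam, presence = NULL,
                                 positive_threshold = 0,
                                 nms_threshold = 0.5) {
  stopifnot(inherits(cam, "cam_grid"))
  d <- dim(cam$values); C <- d[3]
  if (is.null(presence)) presence <- rep(TRUE, C)
  if (is.character(presence)) presence <- cam$class_names %in% presence
  stopifnot(is.logical(presence), length(presence) == C)
  cs <- cam_cell_size(cam)
  out <- list()
  for (ci in which(presence)) {
    plane <- cam$values[, , ci] - positive_threshold
    peaks <- which(local_maxima(plane), arr.ind = TRUE)
    if (nrow(peaks) == 0) next
    lab <- label_components(plane > 0)
    comp_of_peak <- lab[peaks]
    comps <- sort(unique(comp_of_peak))
    rows <- lapply(comps, function(k) {
      cells <- which(lab == k, arr.ind = TRUE)
      vals <- cam$values[, , ci][lab == k]
      in_comp <- peaks[comp_of_peak == k, , drop = FALSE]
      pk_val <- cam$values[cbind(in_comp[, 1], in_comp[, 2], ci)]
      cand <- in_comp[pk_val == max(pk_val), , drop = FALSE]
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      tibble::tibble(
        x0 = (min(cells[, 2]) - 1) * cs[["w"]],
        y0 = (min(cells[, 1]) - 1) * cs[["h"]],
        x1 = max(cells[, 2]) * cs[["w"]],
        y1 = max(cells[, 1]) * cs[["h"]],
        channel = ci,
        label = cam$class_names[ci],
        mean_activation = mean(vals),
        peak_row = cand[1, 1] - 1L,
        peak_col = cand[1, 2] - 1L
      )
    })
    ch_boxes <- dplyr::bind_rows(rows)
    ch_boxes$score <- ch_boxes$mean_activation
    ch_boxes <- box_nms(ch_boxes, nms_threshold)
    ch_boxes$score <- NULL
    out[[length(out) + 1]] <- ch_boxes
  }
  if (!length(out)) {
    return(tibble::tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                          y1 = numeric(), channel = integer(),
                          label = character(), mean_activation = numeric(),
                          peak_row = integer(), peak_col = integer()))
  }
  dplyr::bind_rows(out)
}

#' Read / write a CAM grid
#'
#' One JSON file per frame: grid dimensions, channel names, frame size and
#' the activation values (nested channel -> row -> column arrays). Numeric
#' values are written at full precision.
#'
#' @param cam A [cam_grid()].
#' @param path File path of the JSON container.
#' @param frame_id Optional frame identifier stored alongside.
#' @return `write_cam()` returns `path` invisibly; `read_cam()` returns a
#'   `cam_grid` with a `frame_id` attribute when one was stored.
#' @export
write_cam <- function(cam, path, frame_id = NULL) {
  stopifnot(inherits(cam, "cam_grid"))
  d <- dim(cam$values)
  vals <- lapply(seq_len(d[3]), function(c)
    lapply(seq_len(d[1]), function(r) cam$values[r, , c]))
  obj <- list(frame_id = frame_id, grid_size = d[1:2],
              frame_size = cam$frame_size, class_names = cam$class_names,
              values = vals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_cam
#' @export
read_cam <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gs <- as.integer(obj$grid_size)
  vals <- array(0, c(gs[1], gs[2], length(obj$class_names)))
  if (is.array(obj$values) && length(dim(obj$values)) == 3) {
    # jsonlite simplifies the channel -> row -> column nesting to a
    # (channel, row, col) array
    vals[] <- aperm(obj$values, c(2, 3, 1))
  } else {
    for (c in seq_along(obj$class_names)) {
      ch <- obj$values[[c]]
      if (is.list(ch)) ch <- do.call(rbind, lapply(ch, unlist))
      vals[, , c] <- ch
    }
  }
  cam <- cam_grid(vals, obj$class_names, as.numeric(obj$frame_size))
  if (!is.null(obj$frame_id)) attr(cam, "frame_id") <- obj$frame_id
  cam
}
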