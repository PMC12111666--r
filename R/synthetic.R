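#' Synthetic scene specification
#'
#' Describes the study conditions the generator emulates: frames of
#' 256 x 448 px with 8 x 14 activation grids (square 32 px cells), one or
#' two instrument/target pairs per frame, and a planted center-to-center
#' displacement between each instrument and the tissue it operates on —
#' horizontal distance drawn from `Uniform(0.1, 0.2)` of the frame width
#' and vertical from `Uniform(0.1, 0.3)` of the frame height, the
#' high-density region observed for laparoscopic cholecystectomy. The
#' displacement points from the instrument toward the frame center
#' (instruments enter from the periphery), component-wise. Target-channel
#' CAM blobs are planted at the *instrument* center — the attention-guide
#' flaw this toolkit corrects — while instrument-channel blobs sit at the
#' instrument itself.
#'
#' @param frame_size `c(height_px, width_px)`.
#' @param grid_size `c(H, W)` activation points.
#' @param n_pairs Integer vector of admissible pairs per frame (sampled
#'   uniformly).
#' @param dh_range,dv_range Uniform supports of the planted displacement,
#'   as fractions of frame width / height.
#' @param displacement_cells Optional `c(dh, dv)` in CAM cells; when set
#'   it replaces the uniform draws with this fixed displacement (used by
#'   the shift-magnitude sweep).
#' @param direction `"toward_center"` (default) or `"random"` sign choice
#'   per axis (the latter stress-tests the direction rule).
#' @param blob_sigma_cells Gaussian spread of CAM blobs, in cells.
#' @param blob_floor Constant subtracted from each blob so the positive
#'   area is compact (positive radius about
#'   `sigma * sqrt(2 * log(1 / blob_floor))` cells).
#' @param jitter_px Half-width of the uniform jitter applied to each
#'   candidate-mask edge, emulating unstable segmentation boundaries.
#' @param n_distractors Spurious tissue-like candidate regions per frame,
#'   with lower scores than true regions.
#' @param score_noise Half-width of the uniform noise on region scores.
#' @param taxonomy A [class_taxonomy()] supplying the channel vocabulary.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(frame_size = c(256, 448), grid_size = c(8, 14),
                       n_pairs = 1:2, dh_range = c(0.1, 0.2),
                       dv_range = c(0.1, 0.3),
                       displacement_cells = NULL,
                       direction = c("toward_center", "random"),
                       blob_sigma_cells = 1.2, blob_floor = 0.15,
                       jitter_px = 4, n_distractors = 3,
                       score_noise = 0.02,
                       taxonomy = cholec_taxonomy()) {
  direction <- match.arg(direction)
  spec <- list(frame_size = as.numeric(frame_size),
               grid_size = as.integer(grid_size),
               n_pairs = as.integer(n_pairs),
               dh_range = dh_range, dv_range = dv_range,
               displacement_cells = displacement_cells,
               direction = direction,
               blob_sigma_cells = blob_sigma_cells,
               blob_floor = blob_floor, jitter_px = jitter_px,
               n_distractors = as.integer(n_distractors),
               score_noise = score_noise, taxonomy = taxonomy)
  stopifnot(all(spec$frame_size > 0), all(spec$grid_size >= 1),
            all(spec$n_pairs >= 1), all(spec$n_pairs <= 2),
            spec$blob_sigma_cells > 0, spec$blob_floor > 0,
            spec$blob_floor < 1, spec$jitter_px >= 0,
            spec$n_distractors >= 0, spec$score_noise >= 0)
  # a pair must fit in a half-frame with the margins used by the sampler
  if (spec$frame_size[2] < 360 || spec$frame_size[1] < 200) {
    stop("frame too small to place instrument/target pairs")
  }
  structure(spec, class = "scene_spec")
}

# instrument boxes are long and thin, targets blobby; sizes in px
sample_pair_geometry <- function(spec, half) {
  fh <- spec$frame_size[1]; fw <- spec$frame_size[2]
  iw <- stats::runif(1, 130, 180); ih <- stats::runif(1, 40, 52)
  tw <- stats::runif(1, 90, 140); th <- stats::runif(1, 70, 110)
  # instrument center: inside its half, clear of the frame-center axes
  # (instruments sit peripherally) and with the box inside the frame
  xm <- 0.08 * fw; ym <- 0.08 * fh
  xr <- if (half == "left") c(iw / 2, fw / 2 - xm) else
    c(fw / 2 + xm, fw - iw / 2)
  icx <- stats::runif(1, xr[1], xr[2])
  top <- c(ih / 2 + 2, fh / 2 - ym); bot <- c(fh / 2 + ym, fh - ih / 2 - 2)
  icy <- if (stats::runif(1) < 0.5) stats::runif(1, top[1], top[2]) else
    stats::runif(1, bot[1], bot[2])
  cell <- c(h = fh / spec$grid_size[1], w = fw / spec$grid_size[2])
  if (!is.null(spec$displacement_cells)) {
    dh_px <- spec$displacement_cells[1] * cell["w"]
    dv_px <- spec$displacement_cells[2] * cell["h"]
  } else {
    dh_px <- stats::runif(1, spec$dh_range[1], spec$dh_range[2]) * fw
    dv_px <- stats::runif(1, spec$dv_range[1], spec$dv_range[2]) * fh
  }
  sx <- sign(fw / 2 - icx); sy <- sign(fh / 2 - icy)
  if (spec$direction == "random") {
    sx <- sample(c(-1, 1), 1); sy <- sample(c(-1, 1), 1)
  }
  tcx <- icx + sx * dh_px; tcy <- icy + sy * dv_px
  # clamp target box into frame (can only bind under direction = "random")
  tcx <- min(max(tcx, tw / 2), fw - tw / 2)
  tcy <- min(max(tcy, th / 2), fh - th / 2)
  list(icx = icx, icy = icy, iw = iw, ih = ih,
       tcx = tcx, tcy = tcy, tw = tw, th = th,
       dh = abs(tcx - icx) / fw, dv = abs(tcy - icy) / fh)
}

pair_gt_boxes <- function(geoms) {
  dplyr::bind_rows(lapply(geoms, function(g) {
    tibble::tibble(x0 = c(g$icx - g$iw / 2, g$tcx - g$tw / 2),
                   y0 = c(g$icy - g$ih / 2, g$tcy - g$th / 2),
                   x1 = c(g$icx + g$iw / 2, g$tcx + g$tw / 2),
                   y1 = c(g$icy + g$ih / 2, g$tcy + g$th / 2))
  }))
}

blob_channel <- function(spec, cx_px, cy_px, amp) {
  H <- spec$grid_size[1]; W <- spec$grid_size[2]
  cell_w <- spec$frame_size[2] / W; cell_h <- spec$frame_size[1] / H
  gc <- cx_px / cell_w - 0.5; gr <- cy_px / cell_h - 0.5
  d2 <- outer((seq_len(H) - 1 - gr)^2, (seq_len(W) - 1 - gc)^2, "+")
  amp * (exp(-d2 / (2 * spec$blob_sigma_cells^2)) - spec$blob_floor)
}

rect_mask <- function(b, frame_size) {
  m <- matrix(FALSE, frame_size[1], frame_size[2])
  m[(floor(b[2]) + 1):ceiling(b[4]), (floor(b[1]) + 1):ceiling(b[3])] <- TRUE
  m
}

jitter_box <- function(b, jitter, frame_size) {
  if (jitter > 0) b <- b + stats::runif(4, -jitter, jitter)
  b <- c(max(0, b[1]), max(0, b[2]),
         min(frame_size[2], b[3]), min(frame_size[1], b[4]))
  if (b[3] - b[1] < 2) b[3] <- min(frame_size[2], b[1] + 2)
  if (b[4] - b[2] < 2) b[4] <- min(frame_size[1], b[2] + 2)
  round(b)
}

#' Generate synthetic scenes
#'
#' Draws `n_frames` scenes from a [scene_spec()]: ground-truth instrument
#' and target boxes (pairs in separate frame halves when two are present,
#' with distinct class channels), a CAM whose instrument channels carry
#' Gaussian blobs at the instrument centers while target channels carry
#' the mislocated blob at the paired instrument's center, and candidate
#' regions rendered from the ground-truth boxes with edge jitter plus
#' low-score tissue distractors. Fully reproducible under `seed`.
#'
#' @param spec A [scene_spec()].
#' @param n_frames Number of frames.
#' @param seed Integer seed (set once for the whole draw).
#' @param render Materialize CAM arrays and region masks (default). With
#'   `render = FALSE` only the geometry (ground truth, pairs, annotations)
#'   is produced — the random stream is identical, so the same seed gives
#'   the same boxes either way; useful for displacement statistics at
#'   large n.
#' @return List with `scenes` (list of `camcrm_scene`), `annotations` (an
#'   annotation set, see [read_annotations()]) and `pairs` (one row per
#'   instrument/target pair: classes, centers, planted `dh`, `dv`, the
#'   frame dimensions).
#' @export
generate_scenes <- function(spec, n_frames, seed = NULL, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"), n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  tax <- spec$taxonomy
  channels <- c(tax$instrument_classes, tax$target_classes)
  scenes <- vector("list", n_frames)
  pair_rows <- list()
  for (f in seq_len(n_frames)) {
    fid <- sprintf("frame_%04d", f)
    np <- if (length(spec$n_pairs) == 1) spec$n_pairs else
      sample(spec$n_pairs, 1)
    halves <- if (np == 2) c("left", "right") else
      sample(c("left", "right"), 1)
    icls <- sample(tax$instrument_classes, np)
    tcls <- sample(tax$target_classes, np)
    vals <- if (render)
      array(-spec$blob_floor, c(spec$grid_size, length(channels)))
    gt <- list(); masks <- list(); labs <- character(0)
    pi_ <- st_ <- numeric(0)
    geoms <- list(sample_pair_geometry(spec, halves[1]))
    if (np == 2) {
      # two instruments operate at distinct sites: resample the second
      # pair until no two ground-truth boxes overlap appreciably (both
      # targets are displaced toward the frame center and could collide)
      for (try in 1:100) {
        g2 <- sample_pair_geometry(spec, halves[2])
        all_boxes <- pair_gt_boxes(c(geoms, list(g2)))
        if (max(box_iou(all_boxes, all_boxes) -
                  diag(nrow(all_boxes))) < 0.3) break
      }
      geoms[[2]] <- g2
    }
    for (p in seq_len(np)) {
      g <- geoms[[p]]
      amp <- stats::runif(1, 0.9, 1.1)
      ibox <- c(g$icx - g$iw / 2, g$icy - g$ih / 2,
                g$icx + g$iw / 2, g$icy + g$ih / 2)
      tbox <- c(g$tcx - g$tw / 2, g$tcy - g$th / 2,
                g$tcx + g$tw / 2, g$tcy + g$th / 2)
      ic <- match(icls[p], channels); tc <- match(tcls[p], channels)
      if (render) {
        vals[, , ic] <- vals[, , ic] + spec$blob_floor +
          blob_channel(spec, g$icx, g$icy, amp)
        # the planted flaw: the target channel's blob sits at the instrument
        vals[, , tc] <- vals[, , tc] + spec$blob_floor +
          blob_channel(spec, g$icx, g$icy, amp)
      }
      gt[[length(gt) + 1]] <- tibble::tibble(
        frame_id = fid,
        x0 = c(ibox[1], tbox[1]), y0 = c(ibox[2], tbox[2]),
        x1 = c(ibox[3], tbox[3]), y1 = c(ibox[4], tbox[4]),
        label = c(icls[p], tcls[p]),
        role = c("instrument", "target"), pair_id = p)
      jb <- jitter_box(ibox, spec$jitter_px, spec$frame_size)
      if (render) masks[[length(masks) + 1]] <- rect_mask(jb, spec$frame_size)
      labs <- c(labs, "Instrument")
      jb <- jitter_box(tbox, spec$jitter_px, spec$frame_size)
      if (render) masks[[length(masks) + 1]] <- rect_mask(jb, spec$frame_size)
      labs <- c(labs, "Tissue")
      ns <- spec$score_noise
      pi_ <- c(pi_, stats::runif(2, 0.97 - ns, min(1, 0.97 + ns)))
      st_ <- c(st_, stats::runif(2, 0.98 - ns / 2, min(1, 0.98 + ns / 2)))
      pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
        frame_id = fid, pair_id = p,
        instrument = icls[p], target = tcls[p],
        icx = g$icx, icy = g$icy, tcx = g$tcx, tcy = g$tcy,
        ix0 = ibox[1], iy0 = ibox[2], ix1 = ibox[3], iy1 = ibox[4],
        tx0 = tbox[1], ty0 = tbox[2], tx1 = tbox[3], ty1 = tbox[4],
        dh = g$dh, dv = g$dv,
        width = spec$frame_size[2], height = spec$frame_size[1])
    }
    gt_boxes <- pair_gt_boxes(geoms[seq_len(np)])
    for (d in seq_len(spec$n_distractors)) {
      # distractors model spurious components (reflections, water
      # stains): areas of no interest, kept clear of the annotated boxes
      for (try in 1:50) {
        dw <- stats::runif(1, 50, 90); dh <- stats::runif(1, 50, 90)
        dcx <- stats::runif(1, dw / 2, spec$frame_size[2] - dw / 2)
        dcy <- stats::runif(1, dh / 2, spec$frame_size[1] - dh / 2)
        dbox <- tibble::tibble(x0 = dcx - dw / 2, y0 = dcy - dh / 2,
                               x1 = dcx + dw / 2, y1 = dcy + dh / 2)
        if (max(iou_core(dbox, gt_boxes)) < 0.2) break
      }
      db <- jitter_box(c(dcx - dw / 2, dcy - dh / 2,
                         dcx + dw / 2, dcy + dh / 2),
                       spec$jitter_px, spec$frame_size)
      if (render) masks[[length(masks) + 1]] <- rect_mask(db, spec$frame_size)
      labs <- c(labs, "Tissue")
      ns <- spec$score_noise
      pi_ <- c(pi_, stats::runif(1, 0.90 - ns, 0.90 + ns))
      st_ <- c(st_, stats::runif(1, 0.96 - ns / 2, 0.96 + ns / 2))
    }
    regions <- if (render) {
      candidate_regions(masks, pmin(pmax(pi_, 0), 1),
                        pmin(pmax(st_, 0), 1),
                        label = labs, frame_id = fid)
    }
    scenes[[f]] <- structure(
      list(frame_id = fid, frame_size = spec$frame_size,
           cam = if (render) cam_grid(vals, channels, spec$frame_size),
           presence = c(icls, tcls),
           regions = regions,
           gt = dplyr::bind_rows(gt)),
      class = "camcrm_scene")
  }
  gt_all <- dplyr::bind_rows(lapply(scenes, `[[`, "gt"))
  ann <- list(
    video_id = "synthetic",
    frames = tibble::tibble(
      frame_id = vapply(scenes, `[[`, character(1), "frame_id"),
      width = spec$frame_size[2], height = spec$frame_size[1]),
    gt = gt_all, classes = sort(unique(gt_all$label)))
  list(scenes = scenes, annotations = validate_annotations(ann),
       pairs = dplyr::bind_rows(pair_rows))
}

#' @export
print.camcrm_scene <- function(x, ...) {
  cat("<camcrm_scene> ", x$frame_id, ": ", nrow(x$gt), " GT boxes, ",
      nrow(x$regions), " candidate regions, classes ",
      paste(x$presence, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Instrument-target displacement statistics
#'
#' For each instrument/target pair, the normalized center displacements
#' `D_h = |x-center difference| / frame width` and
#' `D_v = |y-center difference| / frame height` are computed; with at
#' least two pairs a 2-D Gaussian kernel density estimate (Scott's-rule
#' bandwidth) is evaluated on a fixed lattice and its highest-density cell
#' located. This is the analysis that motivates the shift-magnitude
#' defaults: the density mode, divided by the CAM cell size as a fraction
#' of the frame, is the natural shift magnitude.
#'
#' @param pairs A pair table as returned by [generate_scenes()] (columns
#'   `icx, icy, tcx, tcy, width, height`; or precomputed `dh`, `dv`).
#' @param lattice_n Lattice points per axis.
#' @param lattice_max Upper limit of the evaluation lattice (fractions).
#' @return A `displacement_stats` object: `pairs` tibble with `dh`, `dv`;
#'   `kde` (`x`, `y`, `z` as from [MASS::kde2d()]) or `NULL` when fewer
#'   than two pairs; `mode` (`c(dh, dv)` of the densest cell);
#'   `bandwidth`. [tidy()] returns the pair table, [glance()] the mode.
#' @export
displacement_stats <- function(pairs, lattice_n = 101, lattice_max = 0.5) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("dh", "dv") %in% names(pairs))) {
    stopifnot(all(c("icx", "icy", "tcx", "tcy", "width", "height") %in%
                    names(pairs)))
    pairs$dh <- abs(pairs$icx - pairs$tcx) / pairs$width
    pairs$dv <- abs(pairs$icy - pairs$tcy) / pairs$height
  }
  out <- list(pairs = tibble::as_tibble(pairs), kde = NULL, mode = NULL,
              bandwidth = NULL)
  if (nrow(pairs) >= 2) {
    # Scott's rule per axis; kde2d() divides its h by 4 internally
    n <- nrow(pairs)
    h <- 4 * c(stats::sd(pairs$dh), stats::sd(pairs$dv)) * n^(-1 / 6)
    h[h <= 0] <- 1e-6
    kde <- MASS::kde2d(pairs$dh, pairs$dv, h = h, n = lattice_n,
                       lims = c(0, lattice_max, 0, lattice_max))
    peak <- which(kde$z == max(kde$z), arr.ind = TRUE)[1, ]
    out$kde <- kde
    out$mode <- c(dh = kde$x[peak[1]], dv = kde$y[peak[2]])
    out$bandwidth <- h / 4
  }
  structure(out, class = "displacement_stats")
}

#' @export
print.displacement_stats <- function(x, ...) {
  cat("<displacement_stats> ", nrow(x$pairs), " pairs\n", sep = "")
  if (!is.null(x$mode)) {
    cat(sprintf("  KDE mode: Dh = %.3f, Dv = %.3f (Scott bandwidth %.4f, %.4f)\n",
                x$mode[1], x$mode[2], x$bandwidth[1], x$bandwidth[2]))
  } else cat("  fewer than 2 pairs: KDE not computed\n")
  invisible(x)
}

#' @rdname displacement_stats
#' @param x A `displacement_stats` object.
#' @param ... Unused.
#' @method tidy displacement_stats
#' @export
tidy.displacement_stats <- function(x, ...) {
  dplyr::select(x$pairs, dplyr::any_of(c("frame_id", "pair_id",
                                         "instrument", "target")),
                "dh", "dv")
}

#' @rdname displacement_stats
#' @method glance displacement_stats
#' @export
glance.displacement_stats <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs),
                 mode_dh = if (is.null(x$mode)) NA_real_ else x$mode[1],
                 mode_dv = if (is.null(x$mode)) NA_real_ else x$mode[2],
                 mean_dh = mean(x$pairs$dh), mean_dv = mean(x$pairs$dv))
}

#' Sweep the AGC shift magnitudes
#'
#' Generates one batch of scenes and runs the full detection and
#' evaluation pipeline for every combination of shift magnitudes
#' `|K_h| x |K_v|`, recording the target-class and instrument-class macro
#' mAP. Because the attention-guide correction only moves target guides,
#' the instrument column is expected to stay flat while the target column
#' peaks where the shift magnitude matches the planted displacement in
#' cells.
#'
#' @param spec A [scene_spec()]; for magnitude recovery use a fixed
#'   `displacement_cells`.
#' @param n_frames Frames per batch.
#' @param kh_range,kv_range Integer magnitude ranges of interest.
#' @param seed Seed for scene generation.
#' @param config Base [detect_config()]; its `kh_mag`/`kv_mag` are
#'   overridden per grid point.
#' @return Tibble `kh_mag, kv_mag, target_mAP, instrument_mAP,
#'   target_mean_cost` with attribute `argmax`: the grid point(s)
#'   maximising target mAP, ordered by ascending mean target matching
#'   cost (the continuous tie-break; the first row is the selected
#'   optimum).
#' @export
sweep_agc <- function(spec, n_frames = 50, kh_range = 0:4, kv_range = 1:3,
                      seed = NULL, config = detect_config()) {
  batch <- generate_scenes(spec, n_frames, seed = seed)
  grid <- tidyr::expand_grid(kh_mag = as.integer(kh_range),
                             kv_mag = as.integer(kv_range))
  res <- purrr::pmap_dfr(grid, function(kh_mag, kv_mag) {
    cfg <- config
    cfg$kh_mag <- kh_mag; cfg$kv_mag <- kv_mag; cfg$agc <- TRUE
    det <- run_detect(batch$scenes, cfg)
    rep <- run_evaluate(det, batch$annotations, cfg,
                        taxonomy = spec$taxonomy)
    tcost <- det$cost[det$label %in% spec$taxonomy$target_classes]
    tibble::tibble(kh_mag = kh_mag, kv_mag = kv_mag,
                   target_mAP = rep$target$mAP,
                   instrument_mAP = rep$instrument$mAP,
                   target_mean_cost = mean(tcost))
  })
  # mAP can plateau at its maximum over neighbouring magnitudes at finite
  # n; ties are ordered by mean target matching cost, a continuous
  # alignment measure (cost falls as CIoU between the corrected guide's
  # boxes and the matched regions rises)
  best <- res[res$target_mAP == max(res$target_mAP),
              c("kh_mag", "kv_mag", "target_mAP", "target_mean_cost")]
  best <- best[order(best$target_mean_cost), ]
  attr(res, "argmax") <- best
  res
}
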