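#' Detection pipeline configuration
#'
#' Collects every tunable of the pipeline with its default, validated on
#' construction: the attention-guide correction switch and shift
#' magnitudes, CAM positivity threshold and preliminary-box NMS, the
#' region filter settings, the matching constant `K` and forbidden-pair
#' mode, the classifier choice, and the evaluation thresholds.
#'
#' @param agc Apply attention-guide correction to target channels.
#' @param kh_mag,kv_mag Non-negative shift magnitudes in CAM cells.
#' @param clip_wrap Drop activation mass that wraps across a grid edge
#'   instead of applying the literal modular translation.
#' @param positive_threshold CAM positivity cut (activation strictly above
#'   counts).
#' @param prelim_nms IoU threshold for preliminary-box NMS.
#' @param min_pred_iou,min_stability,region_nms,min_area_px,top_k Region
#'   filter settings (see [filter_regions()]).
#' @param K Matching constant; must exceed 1 so `CIoU + K > 0`.
#' @param match_mode `"post_filter"` or `"hard_forbid"` (see
#'   [crm_match()]).
#' @param classifier `"oracle"`, `"heuristic"`, or a classifier function.
#' @param iou_threshold AP threshold; `iou_grid` the AR grid.
#' @param iou_grid Increasing IoU thresholds for average recall.
#' @return A validated `detect_config` list.
#' @export
detect_config <- function(agc = TRUE, kh_mag = 2L, kv_mag = 2L,
                          clip_wrap = FALSE, positive_threshold = 0,
                          prelim_nms = 0.5, min_pred_iou = 0.88,
                          min_stability = 0.95, region_nms = 0.5,
                          min_area_px = 2000, top_k = 10, K = 2,
                          match_mode = c("post_filter", "hard_forbid"),
                          classifier = "oracle", iou_threshold = 0.5,
                          iou_grid = seq(0.5, 0.95, by = 0.05)) {
  match_mode <- match.arg(match_mode)
  cfg <- list(agc = isTRUE(agc), kh_mag = as.integer(kh_mag),
              kv_mag = as.integer(kv_mag), clip_wrap = isTRUE(clip_wrap),
              positive_threshold = positive_threshold,
              prelim_nms = prelim_nms, min_pred_iou = min_pred_iou,
              min_stability = min_stability, region_nms = region_nms,
              min_area_px = min_area_px, top_k = as.integer(top_k),
              K = K, match_mode = match_mode, classifier = classifier,
              iou_threshold = iou_threshold, iou_grid = iou_grid)
  if (cfg$K <= 1) stop("config: K must exceed 1", call. = FALSE)
  if (cfg$kh_mag < 0 || cfg$kv_mag < 0) {
    stop("config: shift magnitudes must be non-negative", call. = FALSE)
  }
  for (nm in c("prelim_nms", "min_pred_iou", "min_stability", "region_nms",
               "iou_threshold")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("config: ", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$min_area_px < 0 || cfg$top_k < 1) {
    stop("config: min_area_px >= 0 and top_k >= 1 required", call. = FALSE)
  }
  structure(cfg, class = "detect_config")
}

resolve_classifier <- function(classifier) {
  if (is.function(classifier)) return(classifier)
  switch(classifier,
         oracle = oracle_classifier(),
         heuristic = heuristic_classifier(),
         stop("unknown classifier: ", classifier))
}

#' Run the detection pipeline over scenes
#'
#' Per frame: infer the forward-direction shift of every present target
#' channel from its own activation and cyclically translate those
#' channels (when `agc` is enabled); extract preliminary boxes for all
#' present channels; filter and rank the frame's candidate regions;
#' classify the survivors and solve the candidate-region matching. The
#' result is one detection table for the whole batch with a per-frame
#' stage-count table attached as attribute `counts`.
#'
#' @param scenes A `camcrm_scene` list (or single scene) as produced by
#'   [generate_scenes()] or [read_scene()].
#' @param config A [detect_config()].
#' @param taxonomy A [class_taxonomy()]; class channels outside it are
#'   rejected.
#' @return Detection tibble (`frame_id`, `x0..y1`, `label`, `score`,
#'   `cost`, `prelim_index`, `region_index`) with attribute `counts`.
#' @export
run_detect <- function(scenes, config = detect_config(),
                       taxonomy = cholec_taxonomy()) {
  stopifnot(inherits(config, "detect_config"))
  if (inherits(scenes, "camcrm_scene")) scenes <- list(scenes)
  classifier <- resolve_classifier(config$classifier)
  out <- vector("list", length(scenes))
  counts <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    cam <- sc$cam
    presence <- sc$presence %||%
      cam$class_names[apply(cam$values > config$positive_threshold,
                            3, any)]
    kinds <- class_kind(presence, taxonomy)
    if (config$agc && (config$kh_mag > 0 || config$kv_mag > 0)) {
      tch <- presence[kinds == "Tissue"]
      if (length(tch)) {
        shifts <- purrr::map_dfr(tch, function(ch) {
          plane <- cam$values[, , match(ch, cam$class_names)]
          s <- infer_forward_shift(plane, config$kh_mag, config$kv_mag)
          tibble::tibble(channel = ch, kh = s$kh, kv = s$kv)
        })
        cam <- agc_shift(cam, shifts, clip_wrap = config$clip_wrap)
      }
    }
    prelims <- extract_prelim_boxes(
      cam, presence, positive_threshold = config$positive_threshold,
      nms_threshold = config$prelim_nms)
    regions <- filter_regions(
      sc$regions, min_pred_iou = config$min_pred_iou,
      min_stability = config$min_stability,
      nms_threshold = config$region_nms,
      min_area_px = config$min_area_px, top_k = config$top_k)
    det <- crm_detect(prelims, regions, classifier = classifier,
                      taxonomy = taxonomy, K = config$K,
                      match_mode = config$match_mode)
    det$frame_id <- rep(sc$frame_id, nrow(det))
    out[[i]] <- det
    counts[[i]] <- tibble::tibble(frame_id = sc$frame_id,
                                  n_prelims = nrow(prelims),
                                  n_regions = nrow(regions),
                                  n_detections = nrow(det))
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                          y1 = numeric(), label = character(),
                          score = numeric(), cost = numeric(),
                          prelim_index = integer(),
                          region_index = integer(), frame_id = character())
  }
  attr(res, "counts") <- dplyr::bind_rows(counts)
  res
}

#' Evaluate a detection run
#'
#' Thin wrapper over [evaluate_detections()] taking its thresholds from
#' the pipeline configuration.
#'
#' @param detections Detection tibble from [run_detect()].
#' @param annotations Annotation set.
#' @param config A [detect_config()].
#' @param taxonomy Optional [class_taxonomy()] for instrument/target
#'   sub-means.
#' @return A `metric_report`.
#' @export
run_evaluate <- function(detections, annotations,
                         config = detect_config(), taxonomy = NULL) {
  stopifnot(inherits(config, "detect_config"))
  evaluate_detections(detections, annotations,
                      iou_threshold = config$iou_threshold,
                      iou_grid = config$iou_grid, taxonomy = taxonomy)
}

#' Write / read a scene as portable files
#'
#' A scene is materialized as `cam_<frame>.json` (the CAM container) and
#' `regions_<frame>.json` plus one PNG per region mask, in `dir`. Class
#' presence is recoverable from the CAM (channels with positive cells);
#' oracle region labels travel in the region manifest.
#'
#' @param scene A `camcrm_scene`.
#' @param dir Directory (created if needed).
#' @param frame_id Frame identifier (for `read_scene`).
#' @return `write_scene()` the directory, invisibly; `read_scene()` a
#'   `camcrm_scene` (without ground truth, which lives in the annotation
#'   JSON).
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cam(scene$cam, file.path(dir, paste0("cam_", scene$frame_id, ".json")),
            frame_id = scene$frame_id)
  write_regions(scene$regions,
                file.path(dir, paste0("regions_", scene$frame_id, ".json")),
                frame_id = scene$frame_id)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir, frame_id) {
  cam <- read_cam(file.path(dir, paste0("cam_", frame_id, ".json")))
  stored <- attr(cam, "frame_id")
  if (!is.null(stored) && !identical(stored, frame_id)) {
    stop("frame-id mismatch: CAM file stores '", stored, "'")
  }
  regions <- read_regions(file.path(dir,
                                    paste0("regions_", frame_id, ".json")))
  if (nrow(regions) && !is.null(regions$frame_id) &&
      !all(regions$frame_id == frame_id)) {
    stop("frame-id mismatch between CAM and region manifest")
  }
  structure(list(frame_id = frame_id, frame_size = cam$frame_size,
                 cam = cam,
                 presence = cam$class_names[apply(cam$values > 0, 3, any)],
                 regions = regions, gt = NULL),
            class = "camcrm_scene")
}

#' List the frame ids materialized in a scene directory
#'
#' @param dir Directory written by [write_scene()].
#' @return Character vector of frame ids.
#' @export
list_scene_frames <- function(dir) {
  f <- list.files(dir, pattern = "^cam_.*\\.json$")
  sort(sub("^cam_(.*)\\.json$", "\\1", f))
}
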