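#' Instrument / target class taxonomy
#'
#' The matching cost gates box-region pairs on coarse kind: a preliminary
#' box whose CAM channel is an instrument class may only match a region
#' classified `"Instrument"`, and a target-class box only a `"Tissue"`
#' region. The taxonomy records which class names are instruments and
#' which are tissue targets; the two sets must be disjoint.
#'
#' @param instrument_classes,target_classes Character vectors of class
#'   names.
#' @return An object of class `class_taxonomy`.
#' @export
class_taxonomy <- function(instrument_classes, target_classes) {
  instrument_classes <- as.character(instrument_classes)
  target_classes <- as.character(target_classes)
  if (length(intersect(instrument_classes, target_classes))) {
    stop("instrument and target class sets must be disjoint")
  }
  structure(list(instrument_classes = instrument_classes,
                 target_classes = target_classes),
            class = "class_taxonomy")
}

#' The laparoscopic cholecystectomy taxonomy
#'
#' Six instrument classes and fifteen tissue-target classes of the
#' surgical action-triplet vocabulary.
#'
#' @return A [class_taxonomy()].
#' @export
cholec_taxonomy <- function() {
  class_taxonomy(
    instrument_classes = c("grasper", "bipolar", "hook", "scissors",
                           "clipper", "irrigator"),
    target_classes = c("gallbladder", "cystic-plate", "cystic-duct",
                       "cystic-artery", "cystic-pedicle", "blood-vessel",
                       "fluid", "abdominal-wall-cavity", "liver",
                       "adhesion", "omentum", "peritoneum", "gut",
                       "specimen-bag", "null-target"))
}

class_kind <- function(label, taxonomy) {
  stopifnot(inherits(taxonomy, "class_taxonomy"))
  out <- rep(NA_character_, length(label))
  out[label %in% taxonomy$instrument_classes] <- "Instrument"
  out[label %in% taxonomy$target_classes] <- "Tissue"
  if (anyNA(out)) {
    stop("class label(s) outside the taxonomy: ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  }
  out
}

#' Region classifiers
#'
#' The matching stage needs every candidate region labelled
#' `"Instrument"` or `"Tissue"`. A region classifier is any function
#' `f(regions)` returning one of those two labels per row — the contract a
#' trained CNN classifier would fulfil in production. Two implementations
#' ship: `oracle_classifier()` reads the `label` column planted by a
#' fixture or annotation source, and `heuristic_classifier()` labels a
#' region `"Instrument"` when its mask is elongated and thin (bbox aspect
#' ratio above `aspect_cut` or mask fill fraction of its bbox below
#' `fill_cut`) — metal tools are long and narrow, tissue regions blobby.
#' The heuristic is a demo-grade stand-in, not a trained model.
#'
#' @param aspect_cut Aspect-ratio threshold (long side / short side).
#' @param fill_cut Mask-area / bbox-area threshold.
#' @return A classifier function usable by [crm_detect()].
#' @export
oracle_classifier <- function() {
  function(regions) {
    if (!"label" %in% names(regions)) {
      stop("oracle_classifier() needs a `label` column on the regions")
    }
    bad <- !regions$label %in% c("Instrument", "Tissue")
    if (any(bad)) stop("oracle labels must be 'Instrument' or 'Tissue'")
    regions$label
  }
}

#' @rdname oracle_classifier
#' @export
heuristic_classifier <- function(aspect_cut = 2.5, fill_cut = 0.55) {
  force(aspect_cut); force(fill_cut)
  function(regions) {
    if (nrow(regions) == 0) return(character(0))
    w <- regions$x1 - regions$x0
    h <- regions$y1 - regions$y0
    aspect <- pmax(w, h) / pmin(w, h)
    fill <- regions$area_px / (w * h)
    ifelse(aspect >= aspect_cut | fill <= fill_cut, "Instrument", "Tissue")
  }
}

#' Class-gated overlap between preliminary boxes and regions
#'
#' `Overlap(box, reg) = [I + T] * (CIoU(box, reg.bbox) + K)` where the gate
#' `I + T` is 1 iff the box's CAM class and the region's coarse label are
#' of the same kind (instrument box with Instrument region, or target box
#' with Tissue region) and 0 otherwise, and `K > 1` keeps `CIoU + K`
#' strictly positive (CIoU > -1). A gated-off pair therefore contributes
#' zero overlap regardless of geometry.
#'
#' @param prelims Preliminary box table (see [extract_prelim_boxes()]).
#' @param regions Candidate-region table.
#' @param region_labels Character vector, `"Instrument"`/`"Tissue"` per
#'   region.
#' @param taxonomy A [class_taxonomy()].
#' @param K Positive constant, must exceed 1.
#' @return List with `overlap` (matrix, prelims x regions) and `gate`
#'   (logical matrix; `FALSE` marks incompatible pairs).
#' @export
crm_overlap <- function(prelims, regions, region_labels, taxonomy, K = 2) {
  if (K <= 1) stop("K must exceed 1 so that CIoU + K stays positive")
  stopifnot(length(region_labels) == nrow(regions))
  if (!all(region_labels %in% c("Instrument", "Tissue"))) {
    stop("region labels must be 'Instrument' or 'Tissue'")
  }
  if (nrow(prelims) == 0 || nrow(regions) == 0) {
    z <- matrix(numeric(0), nrow(prelims), nrow(regions))
    return(list(overlap = z, gate = z > 0))
  }
  kind <- class_kind(prelims$label, taxonomy)
  gate <- outer(kind == "Instrument", region_labels == "Instrument", "&") |
    outer(kind == "Tissue", region_labels == "Tissue", "&")
  ciou <- box_ciou(prelims, regions)
  list(overlap = ifelse(gate, ciou + K, 0), gate = gate)
}

#' Matching cost matrix
#'
#' The reciprocal of each cost entry is the gated overlap plus the
#' preliminary box's mean activation:
#' `C[i, j] = 1 / (Overlap(box_i, reg_j) + mean_activation_i)`. Because
#' mean activation is strictly positive, every entry is finite and
#' positive even for gated-off pairs; those pairs are additionally flagged
#' `forbidden`.
#'
#' @inheritParams crm_overlap
#' @return List with `cost` (positive matrix) and `forbidden` (logical
#'   matrix).
#' @export
crm_cost <- function(prelims, regions, region_labels, taxonomy, K = 2) {
  ov <- crm_overlap(prelims, regions, region_labels, taxonomy, K)
  if (nrow(prelims) > 0 && any(prelims$mean_activation <= 0)) {
    stop("preliminary boxes must carry positive mean activation")
  }
  cost <- 1 / (ov$overlap + prelims$mean_activation)
  list(cost = cost, forbidden = !ov$gate)
}

#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Jonker–Volgenant-style shortest-augmenting-path solver, O(n^3).
#' Rectangular matrices are solved over the smaller dimension (every row
#' is assigned when `nrow <= ncol`, and vice versa). Deterministic: among
#' equal-cost optima the scan order (increasing row, then column) decides.
#'
#' @param cost Numeric matrix of finite costs.
#' @return Integer vector `a` of length `nrow(cost)`; `a[i]` is the column
#'   assigned to row `i`, or `NA` for rows left unassigned (only when
#'   `nrow > ncol`).
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), all(is.finite(cost)))
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  transposed <- n > m
  if (transposed) { cost <- t(cost); n <- nrow(cost); m <- ncol(cost) }
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)          # p[j]: row matched to column j (0 = free)
  way <- integer(m)
  for (i in seq_len(n)) {
    p[m + 1] <- i              # virtual column m+1 starts the path
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      ui0 <- if (i0 <= n) u[i0] else 0
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - ui0 - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(m)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      u[p[m + 1]] <- u[p[m + 1]] + delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == m + 1L) i else p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0) assign_row[p[j]] <- j
  if (!transposed) return(assign_row)
  out <- rep(NA_integer_, ncol(cost))  # original rows = columns here
  out[assign_row[!is.na(assign_row)]] <-
    which(!is.na(assign_row))
  out
}

#' Match preliminary boxes to candidate regions
#'
#' Solves the minimum-total-cost one-to-one assignment over the smaller of
#' the two sets. In the default `"post_filter"` mode the solver runs on
#' the literal cost matrix — gated-off pairs keep their finite activation
#' cost — and incompatible pairs are removed from the returned matching
#' afterwards, so a preliminary box may end up unmatched. In
#' `"hard_forbid"` mode incompatible pairs get a large sentinel cost
#' before solving instead.
#'
#' @param cost Positive cost matrix (prelims x regions).
#' @param forbidden Logical matrix marking incompatible pairs.
#' @param mode `"post_filter"` (default) or `"hard_forbid"`.
#' @return Tibble with columns `prelim`, `region` (1-based indices) and
#'   `cost`.
#' @export
crm_match <- function(cost, forbidden = NULL,
                      mode = c("post_filter", "hard_forbid")) {
  mode <- match.arg(mode)
  if (is.null(forbidden)) forbidden <- matrix(FALSE, nrow(cost), ncol(cost))
  stopifnot(identical(dim(cost), dim(forbidden)))
  if (nrow(cost) == 0 || ncol(cost) == 0) {
    return(tibble::tibble(prelim = integer(), region = integer(),
                          cost = numeric()))
  }
  solved <- cost
  if (mode == "hard_forbid" && any(forbidden)) {
    sentinel <- (max(cost) + 1) * (min(dim(cost)) + 1)
    solved[forbidden] <- sentinel
  }
  a <- solve_assignment(solved)
  keep <- which(!is.na(a))
  out <- tibble::tibble(prelim = keep, region = a[keep],
                        cost = cost[cbind(keep, a[keep])])
  out[!forbidden[cbind(out$prelim, out$region)], ]
}

#' Detect components by candidate-region matching
#'
#' Runs the classifier over the regions, builds the gated cost matrix,
#' solves the assignment and emits one detection per surviving pair: the
#' matched region's bounding box becomes the localization, the class is
#' inherited from the preliminary box's CAM channel, and the detection
#' score is the preliminary box's mean activation.
#'
#' @param prelims Preliminary box table for one frame.
#' @param regions Filtered candidate-region table for the same frame.
#' @param classifier A region classifier (see [oracle_classifier()]).
#' @param taxonomy A [class_taxonomy()].
#' @param K Overlap constant (> 1).
#' @param match_mode Passed to [crm_match()].
#' @return Detection tibble: `x0, y0, x1, y1, label, score, cost` (the
#'   matched pair's assignment cost), `prelim_index, region_index`.
#' @export
crm_detect <- function(prelims, regions, classifier = oracle_classifier(),
                       taxonomy = cholec_taxonomy(), K = 2,
                       match_mode = "post_filter") {
  labels <- classifier(regions)
  if (length(labels) != nrow(regions) ||
      !all(labels %in% c("Instrument", "Tissue"))) {
    stop("classifier must return 'Instrument' or 'Tissue' per region")
  }
  cm <- crm_cost(prelims, regions, labels, taxonomy, K)
  m <- crm_match(cm$cost, cm$forbidden, mode = match_mode)
  tibble::tibble(
    x0 = regions$x0[m$region], y0 = regions$y0[m$region],
    x1 = regions$x1[m$region], y1 = regions$y1[m$region],
    label = prelims$label[m$prelim],
    score = prelims$mean_activation[m$prelim],
    cost = m$cost,
    prelim_index = m$prelim, region_index = m$region
  )
}

#' Read / write detections
#'
#' Per-run JSON: a list of frames, each with its detections (bbox, label,
#' score and the provenance indices of the matched preliminary box and
#' region).
#'
#' @param detections Detection tibble with a `frame_id` column.
#' @param path JSON file path.
#' @return `write_detections()` the path, invisibly; `read_detections()` a
#'   detection tibble.
#' @export
write_detections <- function(detections, path) {
  stopifnot(is.data.frame(detections))
  fid <- detections$frame_id %||% rep("frame", nrow(detections))
  frames <- lapply(unique(fid), function(f) {
    d <- detections[fid == f, ]
    list(frame_id = f, detections = lapply(seq_len(nrow(d)), function(i) {
      list(bbox = c(d$x0[i], d$y0[i], d$x1[i], d$y1[i]),
           label = d$label[i], score = d$score[i], cost = d$cost[i],
           prelim_index = d$prelim_index[i],
           region_index = d$region_index[i])
    }))
  })
  jsonlite::write_json(list(frames = frames), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map_dfr(obj$frames, function(f) {
    purrr::map_dfr(f$detections, function(d) {
      bb <- as.numeric(unlist(d$bbox))
      tibble::tibble(frame_id = f$frame_id, x0 = bb[1], y0 = bb[2],
                     x1 = bb[3], y1 = bb[4], label = d$label,
                     score = d$score, cost = d$cost,
                     prelim_index = as.integer(d$prelim_index),
                     region_index = as.integer(d$region_index))
    })
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(frame_id = character(), x0 = numeric(),
                           y0 = numeric(), x1 = numeric(), y1 = numeric(),
                           label = character(), score = numeric(),
                           cost = numeric(), prelim_index = integer(),
                           region_index = integer())
  }
  rows
}
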