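one_class_fixture <- function() {
  gt <- boxes(c(10, 100, 200), c(10, 100, 30),
              c(60, 150, 250), c(60, 150, 80), label = "gallbladder")
  gt$frame_id <- "f1"
  gt
}

test_that("TP/FP assignment consumes each ground truth once", {
  gt <- one_class_fixture()
  exact <- dplyr::mutate(gt[1, ], score = 0.9)
  a <- assign_detections(exact, gt[1, ], 0.5)
  expect_equal(sum(a$detections$tp), 1)
  expect_equal(a$fn, 0)

  twice <- dplyr::bind_rows(dplyr::mutate(gt[1, ], score = 0.9),
                            dplyr::mutate(gt[1, ], score = 0.8))
  a2 <- assign_detections(twice, gt[1, ], 0.5)
  expect_equal(sum(a2$detections$tp), 1)
  expect_equal(sum(!a2$detections$tp), 1)

  a3 <- assign_detections(twice[0, ], gt, 0.5)
  expect_equal(a3$fn, 3)
  # a detection cannot consume ground truth from another frame
  other <- dplyr::mutate(gt[1, ], score = 0.9, frame_id = "f2")
  expect_equal(assign_detections(other, gt, 0.5)$fn, 3)
})

test_that("TP + FN equals #GT and TP + FP equals #detections", {
  set.seed(51)
  for (rep in 1:10) {
    gt <- random_boxes(sample(2:6, 1), frame = c(200, 200))
    gt$label <- "x"; gt$frame_id <- "f1"
    det <- random_boxes(sample(1:8, 1), frame = c(200, 200), scored = TRUE)
    det$frame_id <- "f1"
    a <- assign_detections(det, gt, runif(1, 0.2, 0.8))
    expect_equal(sum(a$detections$tp) + a$fn, nrow(gt))
    expect_equal(sum(a$detections$tp) + sum(!a$detections$tp), nrow(det))
  }
})

test_that("average precision integrates the interpolated envelope", {
  gt <- one_class_fixture()
  perfect <- dplyr::mutate(gt, score = c(0.9, 0.8, 0.7))
  expect_equal(average_precision(perfect, gt, 0.5), 1)

  junk <- boxes(c(300, 300), c(200, 100), c(340, 340), c(240, 140),
                score = c(0.9, 0.8))
  junk$frame_id <- "f1"
  expect_equal(average_precision(junk, gt, 0.5), 0)

  # ranked [TP, FP, TP, TP] over 3 GTs: envelope area 5/6
  ranked <- dplyr::bind_rows(
    dplyr::mutate(gt[1, ], score = 0.9),
    dplyr::mutate(junk[1, ], score = 0.8),
    dplyr::mutate(gt[2, ], score = 0.7),
    dplyr::mutate(gt[3, ], score = 0.6))
  expect_equal(average_precision(ranked, gt, 0.5), 5 / 6)
  expect_true(is.na(average_precision(ranked, gt[0, ], 0.5)))
})

test_that("average recall doubles the trapezoid area over [0.5, 1]", {
  gt <- one_class_fixture()
  perfect <- dplyr::mutate(gt, score = c(0.9, 0.8, 0.7))
  expect_equal(average_recall(perfect, gt), 1)  # r = 1 on the whole range
  none <- perfect[0, ]
  expect_equal(average_recall(none, gt), 0)

  # recall 1 up to IoU 0.7, 0 above: 2 * (0.2 + 0.025) = 0.45.
  # A detection nested inside its GT with fraction f of the width has
  # IoU = f; put it between the 0.70 and 0.75 grid points.
  f <- 0.72
  shrunk <- gt
  shrunk$x1 <- gt$x0 + f * (gt$x1 - gt$x0)
  shrunk <- dplyr::mutate(shrunk, score = c(0.9, 0.8, 0.7))
  expect_equal(average_recall(shrunk, gt), 0.45)
})

test_that("macro means cover only classes with ground truth", {
  gt <- dplyr::bind_rows(
    one_class_fixture(),
    {
      g <- boxes(300, 120, 380, 200, label = "grasper")
      g$frame_id <- "f1"; g
    })
  ann <- make_annotations(gt)
  # perfect on gallbladder, nothing on grasper: mAP = (1 + 0) / 2
  det <- dplyr::mutate(gt[gt$label == "gallbladder", ],
                       score = c(0.9, 0.8, 0.7))
  rep <- evaluate_detections(det, ann)
  expect_equal(rep$mAP, 0.5)
  expect_equal(tidy(rep)$ap[tidy(rep)$label == "gallbladder"], 1)
  g <- glance(rep)
  expect_equal(g$n_classes, 2)

  det_all <- dplyr::mutate(gt, score = 0.9)
  rep2 <- evaluate_detections(det_all, ann, taxonomy = cholec_taxonomy())
  expect_equal(rep2$mAP, 1)
  expect_equal(rep2$mAR, 1)
  expect_equal(rep2$instrument$mAP, 1)
  expect_error(evaluate_detections(det, make_annotations(gt[0, ])), "ground")
  expect_error(
    evaluate_detections(dplyr::mutate(det, label = "spaceship"), ann),
    "outside")
})

test_that("metrics are invariant to frame order and detection permutation", {
  set.seed(52)
  gt <- dplyr::bind_rows(lapply(1:4, function(f) {
    g <- random_boxes(2, frame = c(200, 200))
    g$label <- "x"; g$frame_id <- paste0("f", f); g
  }))
  det <- dplyr::bind_rows(lapply(1:4, function(f) {
    d <- random_boxes(3, frame = c(200, 200), scored = TRUE)
    d$label <- "x"; d$frame_id <- paste0("f", f); d
  }))
  det$score <- seq(0.9, 0.1, length.out = nrow(det))  # distinct scores
  ann <- make_annotations(gt, 200, 200)
  base <- evaluate_detections(det, ann)
  shuf <- evaluate_detections(det[sample(nrow(det)), ], ann)
  expect_equal(shuf$mAP, base$mAP)
  expect_equal(shuf$mAR, base$mAR)
})

test_that("average recall degrades monotonically under growing jitter", {
  gt <- one_class_fixture()
  ar <- vapply(c(0, 4, 10, 20, 40), function(off) {
    det <- dplyr::mutate(gt, x0 = x0 + off, x1 = x1 + off, score = 0.9)
    average_recall(det, gt)
  }, numeric(1))
  expect_true(all(diff(ar) <= 0))
  expect_equal(ar[1], 1)
})

test_that("annotation sets round-trip through JSON", {
  gt <- one_class_fixture()
  ann <- make_annotations(gt)
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, path, video_id = "vid7")
  back <- read_annotations(path)
  expect_equal(back$video_id, "vid7")
  expect_equal(as.data.frame(back$gt),
               as.data.frame(gt[c("frame_id", "x0", "y0", "x1", "y1",
                                  "label")]))
  expect_equal(back$classes, "gallbladder")
})
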