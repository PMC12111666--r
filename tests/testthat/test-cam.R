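test_that("forward-direction shift points from the dominant blob toward the grid center", {
  m <- matrix(-0.1, 8, 14)
  m[7, 13] <- 1                              # row 6, col 12 (0-based)
  s <- infer_forward_shift(m, 2, 2)          # bottom-right blob
  expect_equal(c(s$kh, s$kv), c(-2L, -2L))   # shift left and up
  expect_false(s$no_activation)

  center <- matrix(-0.1, 9, 15); center[5, 8] <- 1   # exact grid center
  s <- infer_forward_shift(center, 2, 2)
  expect_equal(c(s$kh, s$kv), c(0L, 0L))

  two <- matrix(-0.1, 8, 14)
  two[2, 2] <- 0.9                           # dominant, top-left
  two[7, 13] <- 0.2
  s <- infer_forward_shift(two, 2, 2)
  expect_equal(c(s$kh, s$kv), c(2L, 2L))     # toward bottom-right

  s <- infer_forward_shift(matrix(-1, 8, 14), 2, 2)
  expect_true(s$no_activation)
  expect_equal(c(s$kh, s$kv), c(0L, 0L))
})

test_that("cyclic shift moves single activations by modular arithmetic", {
  m <- matrix(0, 8, 14)
  m[8, 14] <- 5                              # (x = 13, y = 7) 0-based
  cam <- one_channel_cam(m)
  out <- agc_shift(cam, c(2, 1))
  expect_equal(out$values[1, 2, 1], 5)       # lands at (x = 1, y = 0)
  expect_equal(sum(out$values != 0), 1)
})

test_that("cyclic shift conserves activation mass and inverts exactly", {
  set.seed(21)
  for (rep in 1:20) {
    H <- sample(3:10, 1); W <- sample(3:16, 1); C <- sample(1:4, 1)
    cam <- cam_grid(array(rnorm(H * W * C), c(H, W, C)),
                    paste0("ch", seq_len(C)), c(H * 16, W * 16))
    sh <- tibble::tibble(channel = seq_len(C),
                         kh = sample(-W:W, C, replace = TRUE),
                         kv = sample(-H:H, C, replace = TRUE))
    out <- agc_shift(cam, sh)
    expect_equal(apply(out$values, 3, sum), apply(cam$values, 3, sum))
    back <- agc_shift(out, dplyr::mutate(sh, kh = -kh, kv = -kv))
    expect_identical(back$values, cam$values)
    full <- agc_shift(cam, tibble::tibble(channel = seq_len(C),
                                          kh = W, kv = H))
    expect_identical(full$values, cam$values)
    ident <- agc_shift(cam, c(0, 0))
    expect_identical(ident$values, cam$values)
  }
})

test_that("clip_wrap discards mass shifted past a grid edge", {
  m <- matrix(0, 8, 14); m[8, 14] <- 5
  cam <- one_channel_cam(m)
  out <- agc_shift(cam, c(2, 1), clip_wrap = TRUE)
  expect_equal(sum(out$values), 0)           # the lone cell wrapped
  m2 <- matrix(0, 8, 14); m2[4, 7] <- 3      # interior cell, no wrap
  out2 <- agc_shift(one_channel_cam(m2), c(2, 1), clip_wrap = TRUE)
  expect_equal(out2$values[5, 9, 1], 3)
})

test_that("preliminary boxes lift component cell bounds to frame pixels", {
  v <- matrix(-1, 8, 14)
  v[3:4, 6:8] <- 1                           # cells rows 2..3, cols 5..7
  pb <- extract_prelim_boxes(one_channel_cam(v))
  expect_equal(nrow(pb), 1)
  expect_equal(c(pb$x0, pb$y0, pb$x1, pb$y1), c(160, 64, 256, 128))
  expect_equal(pb$mean_activation, 1)
  expect_equal(pb$label, "grasper")

  expect_equal(nrow(extract_prelim_boxes(one_channel_cam(matrix(-1, 8, 14)))), 0)

  two <- matrix(-1, 8, 14)
  two[2, 2] <- 1; two[7, 12] <- 0.5          # two far-apart blobs
  pb2 <- extract_prelim_boxes(one_channel_cam(two))
  expect_equal(nrow(pb2), 2)
  expect_equal(pb2$mean_activation, c(1, 0.5))  # NMS order: score desc
})

test_that("preliminary boxes respect count, positivity and frame bounds", {
  set.seed(22)
  for (rep in 1:15) {
    v <- matrix(rnorm(8 * 14, -0.4, 0.6), 8, 14)
    cam <- one_channel_cam(v)
    pb <- extract_prelim_boxes(cam, nms_threshold = 1)  # keep all comps
    n_peaks <- sum(camcrm:::local_maxima(v))
    expect_lte(nrow(pb), n_peaks)
    if (nrow(pb)) {
      expect_true(all(pb$mean_activation > 0))
      expect_true(all(pb$x0 >= 0 & pb$y0 >= 0 &
                        pb$x1 <= 448 & pb$y1 <= 256))
      # every box contains its seeding peak's positive cell
      expect_true(all(v[cbind(pb$peak_row + 1, pb$peak_col + 1)] > 0))
    }
  }
})

test_that("box extraction commutes with seam-free shifts", {
  set.seed(23)
  for (rep in 1:10) {
    v <- matrix(-1, 8, 14)
    v[3:5, 4:6] <- runif(9, 0.2, 1)          # interior blob
    cam <- one_channel_cam(v)
    kh <- sample(-3:3, 1); kv <- sample(-2:2, 1)
    shifted <- agc_shift(cam, c(kh, kv))
    a <- extract_prelim_boxes(shifted)
    b <- extract_prelim_boxes(cam)
    expect_equal(c(a$x0, a$x1), c(b$x0, b$x1) + kh * 32)
    expect_equal(c(a$y0, a$y1), c(b$y0, b$y1) + kv * 32)
    expect_equal(a$mean_activation, b$mean_activation)
  }
})

test_that("CAM containers round-trip through JSON", {
  set.seed(24)
  cam <- cam_grid(array(rnorm(8 * 14 * 3), c(8, 14, 3)),
                  c("grasper", "hook", "liver"), c(256, 448))
  path <- withr::local_tempfile(fileext = ".json")
  write_cam(cam, path, frame_id = "f1")
  back <- read_cam(path)
  expect_equal(back$values, cam$values)
  expect_equal(back$class_names, cam$class_names)
  expect_equal(back$frame_size, cam$frame_size)
  expect_equal(attr(back, "frame_id"), "f1")
})
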