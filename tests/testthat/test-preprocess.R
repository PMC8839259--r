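test_that("grayscale conversion applies the fixed channel weights", {
  rgb1 <- array(0, c(1, 1, 3))
  expect_equal(rgb_to_gray(rgb1)[1, 1], 0)
  rgb1[] <- 255
  expect_equal(rgb_to_gray(rgb1)[1, 1], 255)
  rgb1[1, 1, ] <- c(100, 200, 50)
  expect_equal(rgb_to_gray(rgb1)[1, 1], 136)
  expect_error(rgb_to_gray(matrix(1, 2, 2)), "3-channel")
  expect_error(rgb_to_gray(array(300, c(1, 1, 3))), "0, 255")
})

test_that("grayscale conversion is monotone in every channel", {
  set.seed(41)
  img <- array(runif(5 * 4 * 3, 0, 200), c(5, 4, 3))
  g0 <- rgb_to_gray(img)
  for (ch in 1:3) {
    img2 <- img
    img2[, , ch] <- img2[, , ch] + 20
    expect_true(all(rgb_to_gray(img2) >= g0))
  }
})

test_that("margin crop removes the printed pixel counts and scales with dpi", {
  m <- matrix(seq_len(2380 * 3), 2380, 3)
  cropped <- crop_margins(m)
  expect_equal(nrow(cropped), 1775)
  expect_equal(cropped[1, ], m[506, ])        # first kept row
  expect_equal(cropped[1775, ], m[2280, ])    # last kept row
  expect_identical(crop_margins(m, 0, 0), m)
  expect_error(crop_margins(matrix(0, 500, 3)), "exceeds")
  half <- crop_margins(matrix(0, 1200, 2), dpi = 300)
  expect_equal(nrow(half), 1200 - round(505 / 2) - round(100 / 2))
})

test_that("maximum lane width is the largest edge difference", {
  g <- lane_geometry(left_edge = c(0, 1, 0), right_edge = c(20, 19, 19))
  expect_equal(compute_wmax(g), 20)
  g2 <- lane_geometry(rep(5, 4), rep(25, 4))
  expect_equal(compute_wmax(g2), 20)
  g3 <- lane_geometry(3, 10, roi_top = 0, roi_bottom = 0.5)
  expect_equal(compute_wmax(g3), 7)
})

test_that("rectification centers the midline and flags empty borders", {
  H <- 12; W <- 30
  img <- matrix(runif(H * W, 0, 255), H, W)
  # constant edges at full width: pure copy, nothing missing
  g <- lane_geometry(rep(4, H), rep(4 + 20, H))
  lane <- rectify_lane(img, g)
  expect_equal(dim(lane$intensity), c(H, 20L))
  expect_equal(lane$intensity, img[, 5:24], ignore_attr = TRUE)
  expect_false(any(lane$missing))

  # one row 2 px narrower than wmax: exactly 2 missing border pixels there
  left <- rep(4, H); right <- rep(24, H)
  left[5] <- 5; right[5] <- 23
  lane2 <- rectify_lane(img, lane_geometry(left, right))
  expect_equal(sum(lane2$missing[5, ]), 2)
  expect_equal(sum(lane2$missing[-5, ]), 0)
  # non-missing pixels per row = xright - xleft
  expect_equal(rowSums(!lane2$missing), right - left, ignore_attr = TRUE)

  # smile midline offset +3 at one row shifts content -3 columns
  left3 <- rep(4, H); right3 <- rep(24, H)
  left3[7] <- 7; right3[7] <- 27
  lane3 <- rectify_lane(img, lane_geometry(left3, right3))
  expect_equal(lane3$intensity[7, ], img[7, 8:27], ignore_attr = TRUE)

  expect_error(rectify_lane(img, lane_geometry(rep(1, 5), rep(9, 5))),
               "rows")
})

test_that("rectification honors the region of interest rows", {
  img <- matrix(1:100, 10, 10)
  g <- lane_geometry(rep(1, 10), rep(9, 10), roi_top = 2, roi_bottom = 6)
  lane <- rectify_lane(img, g)
  expect_equal(nrow(lane$intensity), 5)
  expect_equal(lane$intensity[1, 1], img[3, 2])
})

test_that("artifact masking is a union and idempotent", {
  lane <- lane_image(matrix(1, 8, 8))
  expect_identical(apply_artifact_mask(lane, matrix(FALSE, 8, 8)), lane)
  mask <- matrix(FALSE, 8, 8); mask[3:5, 3:5] <- TRUE
  m1 <- apply_artifact_mask(lane, mask)
  expect_equal(m1$missing, mask)
  expect_identical(apply_artifact_mask(m1, mask), m1)
  expect_error(apply_artifact_mask(lane, matrix(FALSE, 4, 4)), "shape")
})

test_that("lane geometry files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# roi_top 2", "# roi_bottom 8", "left right",
               paste(0:9, 10:19)), path)
  g <- read_lane_geometry(path)
  expect_equal(g$roi_top, 2L)
  expect_equal(g$roi_bottom, 8L)
  expect_equal(g$left_edge, as.numeric(0:9))
})
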