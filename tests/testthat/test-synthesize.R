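test_that("band parameters follow their stated laws", {
  set.seed(100)
  counts <- integer(0); fwhm <- numeric(0)
  while (length(fwhm) < 10000) {
    b <- sample_bands(480)
    counts <- c(counts, nrow(b))
    fwhm <- c(fwhm, b$fwhm)
  }
  fwhm <- fwhm[1:10000]
  expect_true(all(fwhm >= 7))
  expect_equal(mean(fwhm), 14, tolerance = 0.5 / 14)
  # band count uniform on 1..12 (chi-square), offsets exponential mean 7
  expect_gt(chisq.test(table(factor(counts, levels = 1:12)))$p.value, 0.001)
  expect_gt(suppressWarnings(
    ks.test(fwhm - 7, "pexp", 1 / 7))$p.value, 0.001)
  # deterministic under seed
  set.seed(5); b1 <- sample_bands(480)
  set.seed(5); b2 <- sample_bands(480)
  expect_identical(b1, b2)
})

test_that("rendered bands have exact Gaussian profiles on the background", {
  bg <- rep(0, 200)
  bands <- data.frame(position = 100, fwhm = 14, amplitude = 50)
  lane <- render_lane(200, 10, bands, background = bg)
  expect_equal(lane$intensity[101, 1], 50)            # peak at the position
  expect_equal(lane$intensity[101 + 7, 1], 25, tolerance = 1e-6)  # half max
  expect_equal(lane$intensity[101 - 7, 1], 25, tolerance = 1e-6)
  expect_equal(14 / (2 * sqrt(2 * log(2))), 5.9447, tolerance = 1e-4)
  # constant across columns
  expect_true(all(apply(lane$intensity, 1, function(r) all(r == r[1]))))
  # no bands: pure background
  none <- render_lane(200, 4, bands[0, ], background = bg + 3)
  expect_true(all(none$intensity == 3))
})

test_that("sampled deformations are smooth, bounded and seed-stable", {
  expect_true(all(field_matrix(sample_deformation(50, 20, 0, 10)) == 0))
  set.seed(300)
  f <- field_matrix(sample_deformation(200, 120, 6, 40))
  expect_equal(max(abs(f)), 6)
  expect_lt(max(abs(f[, -1] - f[, -ncol(f)])), 1)
  expect_lt(max(abs(f[-1, ] - f[-nrow(f), ])), 1)
  set.seed(300); f1 <- sample_deformation(50, 20, 3, 15)
  set.seed(300); f2 <- sample_deformation(50, 20, 3, 15)
  set.seed(301); f3 <- sample_deformation(50, 20, 3, 15)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
})

test_that("degradation adds the requested artifacts and unbiased speckle", {
  lane <- lane_image(matrix(100, 200, 100))
  expect_identical(degrade_lane(lane, artifact_count = 0, speckle_var = 0),
                   lane)
  # one disk: missing pixels are exactly those within the drawn radius
  set.seed(42)
  d1 <- degrade_lane(lane, artifact_count = 1, speckle_var = 0)
  set.seed(42)
  cy <- runif(1, 0, 199); cx <- runif(1, 0, 99); r <- runif(1, 2, 10)
  disk <- outer(0:199, 0:99, function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
  expect_equal(d1$missing, disk)
  # multiplicative speckle has unit mean
  set.seed(43)
  d2 <- degrade_lane(lane, artifact_count = 0, speckle_var = 0.01)
  ratio <- d2$intensity / 100
  expect_equal(mean(ratio), 1, tolerance = 0.01)
  expect_equal(sd(ratio)^2, 0.01, tolerance = 0.35)
})

test_that("full lane generation is reproducible with consistent ground truth", {
  s1 <- simulate_lane(seed = 77, height = 160, width = 60)
  s2 <- simulate_lane(seed = 77, height = 160, width = 60)
  expect_identical(s1$lane$intensity, s2$lane$intensity)
  expect_identical(field_matrix(s1$truth_field),
                   field_matrix(s2$truth_field))
  expect_equal(length(s1$truth_annotations), nrow(s1$bands))
  # annotation SD equals the SD of the truth field along the band row
  for (b in seq_len(nrow(s1$bands))) {
    row_shift <- field_at(s1$truth_field, 0:59,
                          rep(s1$bands$position[b], 60))
    expect_equal(band_sd(s1$truth_annotations[[b]]),
                 sqrt(mean((row_shift - mean(row_shift))^2)),
                 tolerance = 1e-12)
  }
  # band-free request yields no bands and no annotations
  s0 <- simulate_lane(seed = 1, height = 100, width = 30, n_bands = 0)
  expect_equal(nrow(s0$bands), 0L)
  expect_equal(length(s0$truth_annotations), 0L)
})

test_that("twelve-band lanes occur within 1000 generated lanes", {
  set.seed(7)
  counts <- replicate(1000, nrow(sample_bands(480)))
  expect_true(all(counts >= 1 & counts <= 12))
  expect_equal(max(counts), 12L)
})
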