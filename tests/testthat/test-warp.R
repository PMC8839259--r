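test_that("warping by a zero field is the identity", {
  set.seed(3)
  lane <- lane_image(matrix(runif(60, 0, 100), 10, 6))
  out <- apply_deformation(lane, matrix(0, 10, 6))
  expect_equal(out$intensity, lane$intensity)
  expect_false(any(out$missing))
})

test_that("integer column shifts move content exactly and flag vacated rows", {
  set.seed(4)
  I <- matrix(runif(80, 0, 100), 16, 5)
  lane <- lane_image(I)
  shifts <- c(0, 2, 0, 0, 0)
  field <- matrix(rep(shifts, each = 16), 16, 5)
  out <- apply_deformation(lane, field)
  oracle <- integer_shift_oracle(I, shifts)
  expect_equal(out$missing, is.na(oracle))
  expect_equal(out$intensity[!out$missing], oracle[!is.na(oracle)])
  expect_equal(sum(out$missing[, 2]), 2)  # two vacated pixels at the top
  expect_error(apply_deformation(lane, matrix(0, 4, 4)), "shape")
})

test_that("a field and its negation round-trip within interpolation loss", {
  sim <- simulate_lane(seed = 9, height = 120, width = 40, n_bands = 5,
                       deformation_amplitude = 0, artifact_mean = 0,
                       speckle_var = 0, amplitude_range = c(10, 40))
  lane <- sim$lane
  set.seed(55)
  field <- field_matrix(sample_deformation(120, 40, 3, 40))
  there <- apply_deformation(lane, field)
  back <- apply_deformation(there, -field)
  ok <- !back$missing
  dyn <- diff(range(lane$intensity))
  expect_lt(max(abs(back$intensity[ok] - lane$intensity[ok])), 0.02 * dyn)
})

test_that("column correlations respect the missing-value masking rule", {
  set.seed(5)
  v <- runif(20, 0, 10)
  lane <- lane_image(cbind(v, v, -v + 10))
  cc <- column_correlation_matrix(lane, min_overlap = 2)
  expect_equal(cc$r[1, 2], 1)
  expect_equal(cc$r[1, 3], -1)
  expect_true(is.na(cc$r[1, 1]))

  # columns equal on shared rows but different under one column's mask
  a <- v
  b <- v; b[1:5] <- 99
  miss <- cbind(rep(FALSE, 20), c(rep(TRUE, 5), rep(FALSE, 15)))
  lane2 <- lane_image(cbind(a, b), miss)
  cc2 <- column_correlation_matrix(lane2, min_overlap = 2)
  expect_equal(cc2$r[1, 2], 1)
  expect_equal(cc2$r[1, 2],
               masked_cor_oracle(a, b, miss[, 1], miss[, 2]))

  expect_error(column_correlation_matrix(lane_image(matrix(1, 5, 1))),
               "2 columns")
})

test_that("pairs with low overlap or zero variance are invalid", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(2, 4, 6, 8, 10, 12)
  miss <- cbind(rep(FALSE, 6), c(rep(TRUE, 4), FALSE, FALSE))
  cc <- column_correlation_matrix(lane_image(cbind(a, b), miss),
                                  min_overlap = 3)
  expect_false(cc$valid[1, 2])
  cc2 <- column_correlation_matrix(lane_image(cbind(a, rep(7, 6))),
                                   min_overlap = 2)
  expect_false(cc2$valid[1, 2])
})

test_that("external energy hits its endpoints and rewards shared structure", {
  straight <- straight_lane(H = 80, W = 12)
  expect_equal(external_energy(straight), 0)

  set.seed(6)
  noise <- lane_image(matrix(runif(80 * 12, 0, 100), 80, 12))
  e_noise <- external_energy(noise)
  expect_gt(e_noise, 0.8)
  # adding a common band to the noise raises correlation, lowering energy
  sig <- 40 * exp(-((0:79) - 40)^2 / 18)
  shared <- lane_image(noise$intensity + matrix(sig, 80, 12))
  expect_lt(external_energy(shared), e_noise)

  expect_warning(
    e1 <- external_energy(lane_image(matrix(5, 30, 4))), "no valid")
  expect_equal(e1, 1)
})

test_that("internal energy equals the finite-difference oracle", {
  p0 <- energy_params(wx = 1, wy = 0)
  expect_equal(internal_energy(matrix(0, 4, 4), p0), 0)
  expect_equal(internal_energy(matrix(3.7, 4, 4), p0), 0)
  fx <- matrix(rep(0:3, each = 4), 4, 4)   # DY(x, y) = x
  expect_equal(internal_energy(fx, p0), 12)
  # random field against an explicit double loop
  set.seed(8)
  f <- matrix(rnorm(35), 5, 7)
  sx <- 0; sy <- 0
  for (y in 1:5) for (x in 1:6) sx <- sx + abs(f[y, x + 1] - f[y, x])
  for (y in 1:4) for (x in 1:7) sy <- sy + abs(f[y + 1, x] - f[y, x])
  pp <- energy_params(wx = 0.3, wy = 0.7)
  expect_equal(internal_energy(f, pp), 0.3 * sx + 0.7 * sy)
})

test_that("total energy decomposes into its external and internal parts", {
  sim <- simulate_lane(seed = 13, height = 96, width = 24, n_bands = 4,
                       deformation_amplitude = 3, artifact_mean = 0)
  lane <- sim$lane
  f <- field_matrix(sample_deformation(96, 24, 2, 20))
  f <- f - rowMeans(f)   # satisfy the row constraint
  p1 <- energy_params(wx = 0.2, wy = 0.1)
  p0 <- energy_params(wx = 0, wy = 0)
  expect_equal(total_energy(lane, f, p1) - total_energy(lane, f, p0),
               internal_energy(f, p1))
  expect_equal(total_energy(lane, matrix(0, 96, 24), p1),
               external_energy(lane, p1))
  expect_error(total_energy(lane, f + 1, p1), "constraint")
})

test_that("grid interpolation is exact at nodes and reproduces planes", {
  g0 <- deformation_grid(3, 4, c(20, 15))
  expect_true(all(field_matrix(grid_to_field(g0)) == 0))

  # a 2x2 grid with planar node shifts reproduces the plane everywhere
  H <- 17; W <- 11
  plane <- function(y, x) 2 + 0.3 * y - 0.15 * x
  S <- matrix(c(plane(0, 0), plane(H - 1, 0),
                plane(0, W - 1), plane(H - 1, W - 1)), 2, 2)
  g <- deformation_grid(2, 2, c(H, W), S)
  f <- field_matrix(grid_to_field(g))
  expected <- outer(0:(H - 1), 0:(W - 1), plane)
  expect_equal(f, expected, tolerance = 1e-12, ignore_attr = TRUE)

  # node exactness for a random grid
  set.seed(9)
  S2 <- matrix(rnorm(12), 3, 4)
  g2 <- deformation_grid(3, 4, c(21, 13), S2)
  f2 <- field_matrix(grid_to_field(g2))
  ny <- round(g2$node_y) + 1; nx <- round(g2$node_x) + 1
  expect_equal(f2[ny, nx], S2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("node moves redistribute within the grid row and keep row sums 0", {
  g <- deformation_grid(2, 3, c(30, 30))
  moved <- propose_move(g, c(1, 1), +1, 3)
  expect_equal(moved$shifts[1, ], c(3, -1.5, -1.5))
  expect_equal(moved$shifts[2, ], c(0, 0, 0))
  expect_equal(rowMeans(moved$shifts), c(0, 0))
  expect_identical(propose_move(g, c(2, 2), -1, 0)$shifts, g$shifts)

  # the constraint projection makes every pixel-row mean of the field zero
  f <- field_matrix(grid_to_field(moved, center_rows = TRUE))
  expect_lt(max(abs(rowMeans(f))), 1e-6)
})

test_that("block-mean downsampling ignores missing pixels", {
  lane <- lane_image(matrix(runif(64), 8, 8))
  expect_equal(downsample_lane(lane, 1, 1)$intensity, lane$intensity)
  const <- lane_image(matrix(4, 16, 8))
  expect_true(all(downsample_lane(const, 4, 4)$intensity == 4))
  chk <- lane_image(outer(1:8, 1:8, function(i, j) (i + j) %% 2) * 10)
  ds <- downsample_lane(chk, 8, 8)
  expect_equal(dim(ds$intensity), c(1L, 1L))
  expect_equal(ds$intensity[1, 1], mean(chk$intensity))

  miss <- matrix(FALSE, 4, 4); miss[1, 1] <- TRUE
  I <- matrix(1:16, 4, 4) * 1.0
  ds2 <- downsample_lane(lane_image(I, miss), 2, 2)
  expect_equal(ds2$intensity[1, 1], mean(I[1:2, 1:2][-1]))
  allmiss <- matrix(FALSE, 4, 4); allmiss[1:2, 1:2] <- TRUE
  ds4 <- downsample_lane(lane_image(I, allmiss), 2, 2)
  expect_true(ds4$missing[1, 1])
  expect_false(any(ds4$missing[-1]))
  expect_error(downsample_lane(const, 20, 1), "exceeds")
})

test_that("masking a disk leaves correlations of untouched column pairs", {
  sim <- simulate_lane(seed = 17, height = 100, width = 30, n_bands = 4,
                       artifact_mean = 0)
  cc0 <- column_correlation_matrix(sim$lane, min_overlap = 4)
  mask <- matrix(FALSE, 100, 30)
  mask[40:48, 10:16] <- TRUE
  cc1 <- column_correlation_matrix(apply_artifact_mask(sim$lane, mask),
                                   min_overlap = 4)
  outside <- setdiff(1:30, 10:16)
  expect_equal(cc1$r[outside, outside], cc0$r[outside, outside])
})
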