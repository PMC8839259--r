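test_that("an already-straight lane is left essentially untouched", {
  lane <- straight_lane(H = 160, W = 48)
  res <- straighten_lane(lane, schedule = small_schedule(), seed = 1)
  expect_lt(introduced_deformation(res$field), 1.5)
  expect_lte(res$energy_final, res$energy_zero + 1e-12)
})

test_that("a known smooth deformation of high-contrast bands is recovered", {
  sim <- simulate_lane(seed = 31, n_bands = 6, deformation_amplitude = 6,
                       amplitude_range = c(30, 80))
  res <- process_lane(sim$lane, seed = 31)
  sd_after <- vapply(sim$truth_annotations, band_sd, numeric(1),
                     field = res$field)
  expect_true(all(sd_after < 2))
})

test_that("accepted-move energies decrease strictly and beat the zero field", {
  sim <- simulate_lane(seed = 12, height = 160, width = 48, n_bands = 5,
                       deformation_amplitude = 5)
  flat <- remove_background(sim$lane, ellipsoid_params(8, 120, 30))
  res <- straighten_lane(flat, schedule = small_schedule(), seed = 2)
  for (tr in res$trajectory) {
    seq_e <- c(tr$e_init, tr$accepted)
    expect_true(all(diff(seq_e) < 0))
  }
  expect_lte(res$energy_final, res$energy_zero)
  # the returned field satisfies the row-zero constraint
  expect_lt(max(abs(rowMeans(field_matrix(res$field)))), 1e-6)
})

test_that("identical lane, seed and config give a bit-identical field", {
  sim <- simulate_lane(seed = 14, height = 160, width = 48)
  flat <- remove_background(sim$lane, ellipsoid_params(8, 120, 30))
  r1 <- straighten_lane(flat, schedule = small_schedule(), seed = 7)
  r2 <- straighten_lane(flat, schedule = small_schedule(), seed = 7)
  expect_identical(field_matrix(r1$field), field_matrix(r2$field))
  r3 <- straighten_lane(flat, schedule = small_schedule(), seed = 8)
  expect_false(identical(field_matrix(r1$field), field_matrix(r3$field)))
})

test_that("the optimizer does not disturb the caller's RNG stream", {
  sim <- simulate_lane(seed = 14, height = 120, width = 30)
  set.seed(99)
  draws_ref <- runif(3)
  set.seed(99)
  invisible(straighten_lane(sim$lane, schedule = small_schedule(), seed = 3))
  expect_identical(runif(3), draws_ref)
})

test_that("fused energy evaluation equals the composed module operations", {
  sim <- simulate_lane(seed = 23, height = 96, width = 24, n_bands = 4)
  lane <- sim$lane
  H <- 96; W <- 24
  set.seed(10)
  S <- matrix(rnorm(12, sd = 2), 3, 4)
  g <- deformation_grid(3, 4, c(H, W), S)
  field <- grid_to_field(g, center_rows = TRUE)
  wx <- 0.05 / (H * W); wy <- 0.025 / (H * W)
  fused <- gelwarp:::cpp_total_energy(lane$intensity, lane$missing,
                                      g$node_y, g$node_x, S, wx, wy, 1, 8L)
  composed <- external_energy(apply_deformation(lane, field),
                              energy_params(min_overlap = 8)) +
    internal_energy(field, energy_params(wx = wx, wy = wy))
  expect_equal(fused, composed, tolerance = 1e-9)
})

test_that("greedy search matches exhaustive enumeration on a tiny instance", {
  # 24 x 6 lane, one tilted high-contrast band; a single 2x2 grid whose
  # row-constrained configurations (+/- delta per row) are enumerable
  H <- 24; W <- 6; delta <- 2
  tilt <- 0.5
  y <- 0:(H - 1)
  I <- sapply(0:(W - 1), function(x) {
    30 * exp(-(y - (12 + tilt * (x - (W - 1) / 2)))^2 / 8)
  })
  lane <- lane_image(I)
  sched <- hierarchy_schedule(factors = list(c(1, 1)), deltas = delta,
                              moves = list(list(c(2, 2))))
  res <- straighten_lane(lane, schedule = sched,
                         params = energy_params(min_overlap = 4), seed = 0)

  wx_eff <- 0.05 / (H * W); wy_eff <- 0.025 / (H * W)
  enum_energy <- function(a1, a2) {
    S <- matrix(c(a1, a2, -a1, -a2), 2, 2)
    g <- deformation_grid(2, 2, c(H, W), S)
    gelwarp:::cpp_total_energy(lane$intensity, lane$missing, g$node_y,
                               g$node_x, S, wx_eff, wy_eff, 1, 4L)
  }
  grid_vals <- expand.grid(a1 = c(-delta, 0, delta),
                           a2 = c(-delta, 0, delta))
  energies <- mapply(enum_energy, grid_vals$a1, grid_vals$a2)
  expect_lte(res$energy_final, min(energies) + 1e-9)
})

test_that("degenerate inputs are rejected", {
  expect_error(straighten_lane(lane_image(matrix(1, 50, 1))), "2 px")
  expect_error(straighten_lane(lane_image(matrix(1, 8, 20))), "shorter")
})
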