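#' Hierarchical optimization schedule
#'
#' The straightening search runs four coarse-to-fine steps. Step `j`
#' downsamples the lane by `(fr_j, fc_j)` = (8,8), (4,8), (2,8), (1,4)
#' (columns are reduced more aggressively than rows because the column
#' correlation dominates the cost), moves grid nodes by `delta_j` full
#' resolution pixels (applied as `delta_j / fr_j` at the downsampled
#' level), and sweeps an ordered list of deformation-grid sizes, refining
#' the grid within the step.
#'
#' @param factors list of `c(fr, fc)` per step.
#' @param deltas node shift magnitudes per step, in full-resolution
#'   pixels; strictly decreasing.
#' @param moves list (one entry per step) of lists of `c(rg, cg)` grid
#'   sizes, finest last.
#' @return An object of class `hierarchy_schedule`.
#' @export
hierarchy_schedule <- function(
    factors = list(c(8, 8), c(4, 8), c(2, 8), c(1, 4)),
    deltas = c(8, 4, 2, 1),
    moves = list(list(c(2, 3), c(3, 3)),
                 list(c(3, 5), c(4, 5)),
                 list(c(5, 7), c(6, 9)),
                 list(c(8, 9), c(10, 11)))) {
  if (length(factors) != length(deltas) || length(deltas) != length(moves)) {
    stop("factors, deltas and moves must have one entry per step")
  }
  if (length(deltas) > 1 && any(diff(deltas) >= 0)) {
    stop("node shift magnitudes must be strictly decreasing over steps")
  }
  for (m in moves) {
    sizes <- vapply(m, prod, numeric(1))
    if (length(sizes) > 1 && any(diff(sizes) < 0)) {
      stop("within a step, grids must only get finer")
    }
  }
  structure(list(factors = factors, deltas = deltas, moves = moves),
            class = "hierarchy_schedule")
}

# Bilinear evaluation of grid node shifts (normalized coordinates in
# [0,1]) at new normalized node positions; used to transfer the running
# deformation between grid sizes.
resample_grid <- function(u_old, v_old, S, u_new, v_new) {
  interp1 <- function(knots, vals_mat, targets) {
    # piecewise-linear interpolation along rows of vals_mat
    out <- matrix(0, length(targets), ncol(vals_mat))
    for (t in seq_along(targets)) {
      x <- targets[t]
      i <- max(1, min(length(knots) - 1, findInterval(x, knots)))
      h <- knots[i + 1] - knots[i]
      a <- if (h > 0) min(1, max(0, (x - knots[i]) / h)) else 0
      out[t, ] <- (1 - a) * vals_mat[i, ] + a * vals_mat[i + 1, ]
    }
    out
  }
  tmp <- interp1(u_old, S, u_new)          # rows -> new u
  t(interp1(v_old, t(tmp), v_new))         # cols -> new v
}

#' Straighten a lane by hierarchical energy minimization
#'
#' The core algorithm. Starting from a zero deformation, each hierarchical
#' step downsamples the (background-subtracted, signal-polarity) lane,
#' and for each scheduled deformation-grid size greedily sweeps the grid
#' nodes in seeded random order: a node is moved down then up by the
#' step's shift magnitude (with the counter-shift of its grid row keeping
#' the row mean at zero); a move is kept only if it strictly decreases the
#' total energy, in which case the node's 4-neighbours are re-queued and
#' half / one-and-a-half sized variants of the shift are tried, the best
#' of the three winning (ties toward the smaller shift). Sweeps repeat
#' until a full pass accepts nothing, then the grid is refined. The field
#' evaluated at every proposal is the bilinear interpolation of the node
#' shifts with each pixel row mean-centered, so the zero-mean-shift-per-
#' row constraint holds exactly throughout.
#'
#' @param lane a background-subtracted [lane_image] in signal polarity.
#' @param schedule a [hierarchy_schedule].
#' @param params an [energy_params]. The weights `wx`, `wy` are divided by
#'   the pixel count of the image at each level.
#' @param seed integer seed for the node-permutation stream (the only
#'   source of randomness; identical lane + seed + config give a
#'   bit-identical field).
#' @param max_passes safety cap on sweeps per grid size.
#' @return A list of class `straighten_result` with elements `lane` (the
#'   straightened [lane_image]), `field` (the full-resolution
#'   [deformation_field]), `energy_zero` and `energy_final` (full-
#'   resolution total energies of the zero and returned fields),
#'   `trajectory` (per move type: accepted-move energy sequences), and
#'   `seed`.
#' @export
straighten_lane <- function(lane, schedule = hierarchy_schedule(),
                            params = energy_params(), seed = 0,
                            max_passes = 100L) {
  assert_lane(lane)
  stopifnot(inherits(schedule, "hierarchy_schedule"),
            inherits(params, "energy_params"))
  H <- nrow(lane$intensity); W <- ncol(lane$intensity)
  if (W < 2) stop("lane must be at least 2 px wide")
  coarsest_rows <- max(vapply(schedule$moves[[1]], `[`, numeric(1), 1))
  if (floor(H / schedule$factors[[1]][1]) < coarsest_rows) {
    stop("lane is shorter than the coarsest deformation grid")
  }

  # seeded generator owned by the optimizer; global RNG state restored
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  u <- v <- NULL       # normalized node coordinates of the running grid
  shifts <- NULL       # node shifts in full-resolution pixels
  trajectory <- list()

  for (j in seq_along(schedule$factors)) {
    fr <- schedule$factors[[j]][1]; fc <- schedule$factors[[j]][2]
    ds <- downsample_lane(lane, fr, fc)
    Hl <- nrow(ds$intensity); Wl <- ncol(ds$intensity)
    wx_eff <- params$wx / (Hl * Wl)
    wy_eff <- params$wy / (Hl * Wl)
    delta_level <- schedule$deltas[j] / fr

    for (g in schedule$moves[[j]]) {
      rg <- g[1]; cg <- g[2]
      u_new <- seq(0, 1, length.out = rg)
      v_new <- seq(0, 1, length.out = cg)
      S <- if (is.null(shifts)) matrix(0, rg, cg)
           else resample_grid(u, v, shifts, u_new, v_new)
      S <- S - rowMeans(S)               # keep grid-row means at zero
      u <- u_new; v <- v_new; shifts <- S

      node_y <- u * (Hl - 1); node_x <- v * (Wl - 1)
      S_level <- shifts / fr
      E <- cpp_total_energy(ds$intensity, ds$missing, node_y, node_x,
                            S_level, wx_eff, wy_eff, params$p,
                            params$min_overlap)
      e_init <- E
      accepted <- numeric(0)
      passes <- 0L
      repeat {
        passes <- passes + 1L
        perm <- sample.int(rg * cg) - 1L
        res <- cpp_run_pass(ds$intensity, ds$missing, node_y, node_x,
                            S_level, delta_level, wx_eff, wy_eff,
                            params$p, params$min_overlap, perm, E)
        S_level <- res$shifts
        E <- res$energy
        accepted <- c(accepted, res$accepted)
        if (res$n_accept == 0L || passes >= max_passes) break
      }
      shifts <- S_level * fr
      trajectory[[length(trajectory) + 1]] <-
        list(step = j, fr = fr, fc = fc, grid = c(rg, cg),
             passes = passes, e_init = e_init, accepted = accepted,
             energy = E)
    }
  }

  field <- deformation_field(cpp_grid_field(H, W, u * (H - 1), v * (W - 1),
                                            shifts, TRUE))
  warped <- apply_deformation(lane, field)
  wx_full <- params$wx / (H * W); wy_full <- params$wy / (H * W)
  energy_zero <- cpp_total_energy(lane$intensity, lane$missing,
                                  u * (H - 1), v * (W - 1),
                                  matrix(0, length(u), length(v)),
                                  wx_full, wy_full, params$p,
                                  params$min_overlap)
  energy_final <- cpp_total_energy(lane$intensity, lane$missing,
                                   u * (H - 1), v * (W - 1), shifts,
                                   wx_full, wy_full, params$p,
                                   params$min_overlap)
  structure(list(lane = warped, field = field, energy_zero = energy_zero,
                 energy_final = energy_final, trajectory = trajectory,
                 seed = seed, schedule = schedule, params = params),
            class = "straighten_result")
}

#' @export
print.straighten_result <- function(x, ...) {
  n_acc <- sum(vapply(x$trajectory, function(t) length(t$accepted),
                      numeric(1)))
  cat(sprintf(paste0("<straighten_result> %d x %d lane, %d accepted moves, ",
                     "energy %.4f -> %.4f\n"),
              nrow(x$lane$intensity), ncol(x$lane$intensity), n_acc,
              x$energy_zero, x$energy_final))
  invisible(x)
}
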