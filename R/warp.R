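#' Deformation field
#'
#' A per-pixel vertical shift \eqn{\Delta Y(x,y)} in pixels (positive =
#' downward), stored as a numeric matrix with the same shape as its lane.
#'
#' @param dy numeric matrix of shifts.
#' @return A matrix of class `deformation_field`.
#' @export
deformation_field <- function(dy) {
  dy <- as.matrix(dy)
  storage.mode(dy) <- "double"
  if (any(!is.finite(dy))) stop("deformation field must be finite everywhere")
  class(dy) <- c("deformation_field", class(dy))
  dy
}

#' @rdname deformation_field
#' @param field a [deformation_field] (or plain matrix).
#' @return `field_matrix` returns the underlying numeric matrix.
#' @export
field_matrix <- function(field) {
  m <- unclass(field)
  as.matrix(m)
}

#' Energy parameters
#'
#' Tunable constants of the straightening energy. The external term is
#' `f(cbar) = (1 - cbar)^p` where `cbar` is the mean of the valid
#' off-diagonal column correlations, each clamped to \[0, 1\] (so `f(0)=1`,
#' `f(1)=0`, strictly decreasing). `wx` weights the shear strain
#' `|dDY/dx|`, `wy` the normal strain `|dDY/dy|`, both per pixel of
#' absolute forward difference; the optimizer divides them by the pixel
#' count of the image it evaluates so energies are image-size invariant.
#' `min_overlap` is the minimum number of shared non-missing rows for a
#' column pair's correlation to enter the average.
#'
#' @param wx,wy non-negative regularizer weights.
#' @param p exponent of the decreasing function `f`.
#' @param min_overlap minimum shared rows per column pair.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(wx = 0.05, wy = 0.025, p = 1, min_overlap = 8) {
  if (wx < 0 || wy < 0) stop("energy weights must be non-negative")
  if (p <= 0) stop("f exponent must be positive")
  structure(list(wx = wx, wy = wy, p = p,
                 min_overlap = as.integer(min_overlap)),
            class = "energy_params")
}

#' Warp a lane with a deformation field
#'
#' Implements `I'(x, y + DY(x,y)) = I(x, y)`: each column is resampled
#' along y by linear interpolation of the inverse of the forward map
#' `t(y) = y + DY(x,y)` (first crossing from the top if the map folds).
#' Target pixels with no source support, or whose source interval touches
#' a missing pixel, are missing.
#'
#' @param lane a [lane_image].
#' @param field a [deformation_field] (or matrix) of the same shape.
#' @return The warped [lane_image].
#' @export
apply_deformation <- function(lane, field) {
  assert_lane(lane)
  f <- field_matrix(field)
  if (!identical(dim(f), dim(lane$intensity))) {
    stop("field shape does not match the lane")
  }
  res <- cpp_warp_columns(lane$intensity, lane$missing, f)
  int <- res$intensity
  int[res$missing] <- 0
  lane_image(int, res$missing)
}

#' Pairwise column correlation with missing-value masking
#'
#' Pearson correlation of every pair of lane columns computed over the
#' rows where both columns are non-missing. Pairs whose overlap is below
#' `min_overlap`, or where either column has zero variance on the shared
#' rows, are flagged invalid and excluded from the energy average.
#'
#' @param lane a [lane_image] with at least 2 columns.
#' @param min_overlap minimum shared non-missing rows.
#' @return A list with `r` (symmetric correlation matrix, `NA` where
#'   invalid, diagonal `NA`) and `valid` (logical matrix).
#' @export
column_correlation_matrix <- function(lane, min_overlap = 8) {
  assert_lane(lane)
  W <- ncol(lane$intensity)
  if (W < 2) stop("lane must have at least 2 columns")
  R <- matrix(NA_real_, W, W)
  valid <- matrix(FALSE, W, W)
  I <- lane$intensity
  M <- !lane$missing
  for (i in seq_len(W - 1)) {
    for (j in seq.int(i + 1, W)) {
      sh <- M[, i] & M[, j]
      n <- sum(sh)
      if (n < max(2, min_overlap)) next
      a <- I[sh, i]
      b <- I[sh, j]
      va <- sum(a^2) * n - sum(a)^2
      vb <- sum(b^2) * n - sum(b)^2
      if (va <= 1e-12 * n^2 || vb <= 1e-12 * n^2) next
      r <- (n * sum(a * b) - sum(a) * sum(b)) / sqrt(va * vb)
      R[i, j] <- R[j, i] <- r
      valid[i, j] <- valid[j, i] <- TRUE
    }
  }
  list(r = R, valid = valid)
}

#' External (image-driven) energy of a lane
#'
#' `f(cbar)` with `f(c) = (1 - c)^p`, where `cbar` is the mean of the
#' valid off-diagonal column correlations, each clamped to \[0, 1\]
#' (negative correlations count as 0: anti-correlated noise must not
#' reward deformation). A perfectly straight multi-band lane has external
#' energy 0; independent-noise columns give approximately 1. When no
#' column pair is valid the energy is 1 (maximally uncorrelated) and a
#' warning is raised.
#'
#' @param lane a [lane_image].
#' @param params an [energy_params].
#' @return A scalar in \[0, 1\].
#' @export
external_energy <- function(lane, params = energy_params()) {
  cc <- column_correlation_matrix(lane, params$min_overlap)
  rs <- cc$r[upper.tri(cc$r)][cc$valid[upper.tri(cc$valid)]]
  if (!length(rs)) {
    warning("no valid column pair; external energy set to 1")
    return(1)
  }
  cbar <- mean(pmin(pmax(rs, 0), 1))
  (1 - cbar)^params$p
}

#' Internal (strain) energy of a deformation field
#'
#' `wx * sum |forward x-differences| + wy * sum |forward y-differences|`,
#' penalizing shear and normal strain of the vertical deformation.
#'
#' @param field a [deformation_field] or matrix.
#' @param params an [energy_params].
#' @return A non-negative scalar.
#' @export
internal_energy <- function(field, params = energy_params()) {
  f <- field_matrix(field)
  sx <- if (ncol(f) > 1) sum(abs(f[, -1, drop = FALSE] -
                                 f[, -ncol(f), drop = FALSE])) else 0
  sy <- if (nrow(f) > 1) sum(abs(f[-1, , drop = FALSE] -
                                 f[-nrow(f), , drop = FALSE])) else 0
  params$wx * sx + params$wy * sy
}

#' Total straightening energy
#'
#' External energy of the warped lane plus internal energy of the field.
#' The field must satisfy the zero-mean-shift-per-row constraint within
#' 1e-3 px.
#'
#' @param lane a [lane_image].
#' @param field a [deformation_field].
#' @param params an [energy_params].
#' @return A scalar.
#' @export
total_energy <- function(lane, field, params = energy_params()) {
  f <- field_matrix(field)
  if (max(abs(rowMeans(f))) > 1e-3) {
    stop("field violates the zero-mean-shift-per-row constraint")
  }
  external_energy(apply_deformation(lane, f), params) +
    internal_energy(f, params)
}

#' Deformation grid
#'
#' A coarse `rg x cg` grid of node shifts whose bilinear interpolation
#' yields the per-pixel deformation field. Nodes sit on all four lane
#' borders at the coordinates `node_y = seq(0, H-1, length.out = rg)`,
#' `node_x = seq(0, W-1, length.out = cg)` (0-based pixels).
#'
#' @param rg,cg grid rows and columns (both >= 2).
#' @param lane_dim `c(H, W)` of the lane the grid spans.
#' @param shifts optional `rg x cg` matrix of node shifts (default zeros).
#' @return An object of class `deformation_grid`.
#' @export
deformation_grid <- function(rg, cg, lane_dim, shifts = NULL) {
  if (rg < 2 || cg < 2) stop("deformation grid must be at least 2 x 2")
  if (is.null(shifts)) shifts <- matrix(0, rg, cg)
  shifts <- as.matrix(shifts)
  if (!identical(dim(shifts), c(as.integer(rg), as.integer(cg)))) {
    stop("shifts must be an rg x cg matrix")
  }
  structure(list(rg = as.integer(rg), cg = as.integer(cg),
                 node_y = seq(0, lane_dim[1] - 1, length.out = rg),
                 node_x = seq(0, lane_dim[2] - 1, length.out = cg),
                 lane_dim = as.integer(lane_dim),
                 shifts = shifts),
            class = "deformation_grid")
}

#' Interpolate a deformation grid to a per-pixel field
#'
#' Pure bilinear interpolation of the node shifts; exact at the nodes.
#' (The optimizer additionally mean-centers each pixel row of the
#' interpolated field to enforce the zero-mean-shift-per-row constraint;
#' see [straighten_lane()].)
#'
#' @param grid a [deformation_grid].
#' @param lane_dim optional `c(H, W)` overriding the grid's own span.
#' @param center_rows subtract each pixel row's mean (constraint
#'   projection); default `FALSE`.
#' @return A [deformation_field].
#' @export
grid_to_field <- function(grid, lane_dim = grid$lane_dim,
                          center_rows = FALSE) {
  stopifnot(inherits(grid, "deformation_grid"))
  H <- lane_dim[1]; W <- lane_dim[2]
  if (max(grid$node_y) < H - 1 || max(grid$node_x) < W - 1) {
    stop("grid nodes do not cover the lane")
  }
  deformation_field(cpp_grid_field(H, W, grid$node_y, grid$node_x,
                                   grid$shifts, center_rows))
}

#' Propose a constrained node move
#'
#' Shifts node `k` by `s * delta` and every other node in the same grid
#' row by `-s * delta / (cg - 1)`, so the grid row's mean shift stays 0.
#'
#' @param grid a [deformation_grid].
#' @param k node index: either a single 1-based linear index
#'   (column-major) or `c(row, col)`.
#' @param s shift sign, -1 or +1.
#' @param delta shift magnitude in pixels (> 0; 0 leaves the grid
#'   unchanged).
#' @return The candidate [deformation_grid].
#' @export
propose_move <- function(grid, k, s, delta) {
  stopifnot(inherits(grid, "deformation_grid"))
  if (grid$cg < 2) stop("degenerate deformation grid: fewer than 2 columns")
  if (!s %in% c(-1, 1)) stop("s must be -1 or +1")
  if (delta < 0) stop("delta must be non-negative")
  if (length(k) == 2) {
    gr <- k[1]; gc <- k[2]
  } else {
    gr <- (k - 1) %% grid$rg + 1
    gc <- (k - 1) %/% grid$rg + 1
  }
  d <- s * delta
  grid$shifts[gr, ] <- grid$shifts[gr, ] - d / (grid$cg - 1)
  grid$shifts[gr, gc] <- grid$shifts[gr, gc] + d + d / (grid$cg - 1)
  grid
}

#' Downsample a lane by block means
#'
#' Reduces the lane over `fr x fc` blocks, averaging the non-missing
#' pixels of each block; a block that is entirely missing stays missing.
#' Partial blocks at the bottom/right borders are averaged over their
#' available pixels.
#'
#' @param lane a [lane_image].
#' @param fr,fc row and column reduction factors (>= 1).
#' @return The reduced [lane_image] with `ceiling(H/fr)` rows.
#' @export
downsample_lane <- function(lane, fr, fc) {
  assert_lane(lane)
  res <- cpp_block_mean(lane$intensity, lane$missing, as.integer(fr),
                        as.integer(fc))
  int <- res$intensity
  int[res$missing] <- 0
  lane_image(int, res$missing)
}
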