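# Independent brute-force oracles and fixture builders. These deliberately
# re-derive results with naive loops so they share no code with the
# implementation paths they check.

# Brute-force rolling ellipsoid: for every center, erosion = min over the
# elliptical footprint of (surface - ellipsoid height), then dilation of
# the eroded surface; footprints truncated at borders.
roll_ellipsoid_oracle <- function(I, rx, ry, rz) {
  H <- nrow(I); W <- ncol(I)
  Rx <- floor(rx); Ry <- floor(ry)
  bfun <- function(dx, dy) rz * sqrt(max(0, 1 - dx^2 / rx^2 - dy^2 / ry^2))
  inside <- function(dx, dy) dx^2 / rx^2 + dy^2 / ry^2 <= 1
  one_pass <- function(src, sign) {
    out <- matrix(NA_real_, H, W)
    for (y in 1:H) for (x in 1:W) {
      best <- if (sign > 0) -Inf else Inf
      for (dx in -Rx:Rx) for (dy in -Ry:Ry) {
        if (!inside(dx, dy)) next
        yy <- y + dy; xx <- x + dx
        if (yy < 1 || yy > H || xx < 1 || xx > W) next
        v <- src[yy, xx] + sign * bfun(dx, dy)
        if (sign > 0) { if (v > best) best <- v } else if (v < best) best <- v
      }
      out[y, x] <- best
    }
    out
  }
  one_pass(one_pass(I, -1), +1)
}

# Naive per-column warp for integer, column-constant shifts: content moves
# down by `shift` rows, vacated target rows become missing.
integer_shift_oracle <- function(I, shifts_per_column) {
  H <- nrow(I); W <- ncol(I)
  out <- matrix(NA_real_, H, W)
  for (x in 1:W) {
    s <- shifts_per_column[x]
    for (y in 1:H) {
      src <- y - s
      if (src >= 1 && src <= H) out[y, x] <- I[src, x]
    }
  }
  out
}

# Pearson correlation of two columns over shared non-missing rows via
# stats::cor.
masked_cor_oracle <- function(a, b, miss_a, miss_b) {
  sh <- !miss_a & !miss_b
  stats::cor(a[sh], b[sh])
}

# A straight, high-contrast, noise-free synthetic lane.
straight_lane <- function(H = 160, W = 48, positions = c(30, 60, 90, 125),
                          amplitude = 40, fwhm = 10, base = 5) {
  y <- 0:(H - 1)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  prof <- rep(base, H)
  for (p in positions) prof <- prof + amplitude * exp(-(y - p)^2 / (2 * sig^2))
  lane_image(matrix(prof, H, W))
}

# A small schedule for fast optimizer tests on short lanes.
small_schedule <- function() {
  hierarchy_schedule(factors = list(c(4, 4), c(2, 4), c(1, 2)),
                     deltas = c(6, 3, 1),
                     moves = list(list(c(2, 3)), list(c(3, 3)),
                                  list(c(4, 5))))
}
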