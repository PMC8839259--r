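#' Band midline annotation
#'
#' Control points placed on a band's midline, linearly interpolated to a
#' continuous curve `y(x)` over the band's column extent. Coordinates are
#' 0-based pixels.
#'
#' @param x,y numeric vectors of control-point coordinates; `x` strictly
#'   increasing.
#' @return An object of class `band_annotation`.
#' @export
band_annotation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    stop("x and y must be equal-length, non-empty vectors")
  }
  if (length(x) > 1 && any(diff(x) <= 0)) {
    stop("control-point x coordinates must be strictly increasing")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 extent = range(x)), class = "band_annotation")
}

# midline y(x); constant extension beyond the annotated extent
midline_at <- function(band, xs) {
  if (length(band$x) == 1) return(rep(band$y, length(xs)))
  approx(band$x, band$y, xout = xs, rule = 2)$y
}

# integer sample columns of a band's extent
band_columns <- function(band) {
  seq.int(ceiling(band$extent[1]), floor(band$extent[2]))
}

#' Straighten a lane from expert band annotations
#'
#' The tracing-assistant warp: each annotated midline `y_b(x)` is mapped
#' to the horizontal line at its mean height, and the vertical shift at
#' any other pixel is linearly interpolated in y between the annotated
#' lines (constant extrapolation above the top line and below the bottom
#' line; midlines are extended with constant value beyond their annotated
#' column extent). Annotated bands have an SD of exactly 0 after warping.
#'
#' @param lane a [lane_image].
#' @param bands a list of [band_annotation] objects; they must not cross.
#' @return A list with `lane` (warped [lane_image]), `field` (the
#'   [deformation_field] applied, rasterized at pixel resolution) and
#'   `warped_bands` (the annotations mapped through the exact continuous
#'   warp: each is horizontal at its mean height, SD exactly 0; midline
#'   checks through the rasterized `field` are instead exact only to the
#'   interpolation resolution, since the continuous map is piecewise
#'   linear in y with breakpoints at the annotated lines).
#' @export
straighten_from_annotations <- function(lane, bands) {
  assert_lane(lane)
  if (inherits(bands, "band_annotation")) bands <- list(bands)
  if (!length(bands)) stop("at least one band annotation is required")
  H <- nrow(lane$intensity); W <- ncol(lane$intensity)
  xs <- 0:(W - 1)
  ylines <- vapply(bands, midline_at, numeric(W), xs = xs)  # W x nb
  ylines <- matrix(ylines, nrow = W)
  means <- vapply(bands, function(b) mean(midline_at(b, band_columns(b))),
                  numeric(1))
  ord <- order(means)
  ylines <- ylines[, ord, drop = FALSE]
  means <- means[ord]
  if (ncol(ylines) > 1 &&
      any(apply(ylines, 1, function(r) any(diff(r) <= 0)))) {
    stop("band annotations cross; midlines must keep their vertical order")
  }
  field <- matrix(0, H, W)
  ys <- 0:(H - 1)
  for (ix in seq_len(W)) {
    knots <- ylines[ix, ]
    s <- means - knots
    field[, ix] <- if (length(knots) == 1) rep(s, H)
                   else approx(knots, s, xout = ys, rule = 2)$y
  }
  field <- deformation_field(field)
  warped <- lapply(seq_along(bands), function(i) {
    b <- bands[[i]]
    m <- mean(midline_at(b, band_columns(b)))
    band_annotation(b$x, rep(m, length(b$x)))
  })
  list(lane = apply_deformation(lane, field), field = field,
       warped_bands = warped)
}

#' Read and write band annotation files
#'
#' Plain-text format: a header `band x y`, one line per control point,
#' points of a band consecutive and identified by the integer `band`
#' column.
#'
#' @param path file path.
#' @param bands list of [band_annotation] objects.
#' @return `read_annotations` returns a list of [band_annotation];
#'   `write_annotations` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  tab <- read.table(path, header = TRUE)
  if (!all(c("band", "x", "y") %in% names(tab))) {
    stop(sprintf("annotation file '%s' needs 'band', 'x', 'y' columns", path))
  }
  lapply(split(tab, tab$band), function(d) band_annotation(d$x, d$y))
}

#' @rdname read_annotations
#' @export
write_annotations <- function(bands, path) {
  tab <- do.call(rbind, lapply(seq_along(bands), function(i) {
    data.frame(band = i, x = bands[[i]]$x, y = bands[[i]]$y)
  }))
  write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
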