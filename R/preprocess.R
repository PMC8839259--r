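#' Convert an RGB membrane scan to grayscale
#'
#' Applies the fixed linear combination `0.16 R + 0.52 G + 0.32 B` used for
#' scanned IEF membranes; the weights sum to 1 so the output stays on the
#' input's 0-255 scale.
#'
#' @param image a numeric array `rows x cols x 3` with channel values in
#'   0-255, or a list with elements `R`, `G`, `B` (equal-shaped matrices).
#' @return A numeric matrix of grayscale values.
#' @export
rgb_to_gray <- function(image) {
  if (is.list(image) && all(c("R", "G", "B") %in% names(image))) {
    image <- simplify2array(image[c("R", "G", "B")])
  }
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L)) {
    stop("expected a 3-channel RGB image (rows x cols x 3)")
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  out <- 0.16 * image[, , 1] + 0.52 * image[, , 2] + 0.32 * image[, , 3]
  matrix(out, dim(image)[1], dim(image)[2])
}

#' Crop the sample-free margins of a membrane scan
#'
#' Scanned membranes carry blank margins above and below the sample area;
#' at 600 dpi these are 505 rows at the top and 100 at the bottom. For
#' other scan resolutions the defaults are scaled linearly and rounded to
#' the nearest row.
#'
#' @param gray numeric matrix (grayscale membrane).
#' @param top_px,bottom_px rows to remove; defaults are the 600-dpi values
#'   scaled by `dpi / 600`.
#' @param dpi scan resolution used to scale the defaults.
#' @return The cropped matrix.
#' @export
crop_margins <- function(gray, top_px = NULL, bottom_px = NULL, dpi = 600) {
  gray <- as.matrix(gray)
  if (is.null(top_px)) top_px <- round(505 * dpi / 600)
  if (is.null(bottom_px)) bottom_px <- round(100 * dpi / 600)
  if (top_px < 0 || bottom_px < 0) stop("crop sizes must be non-negative")
  if (top_px + bottom_px >= nrow(gray)) {
    stop(sprintf("crop of %d + %d rows exceeds image height %d",
                 top_px, bottom_px, nrow(gray)))
  }
  gray[seq.int(top_px + 1L, nrow(gray) - bottom_px), , drop = FALSE]
}

#' Lane geometry from upstream segmentation
#'
#' Per-row left/right edge columns of a segmented lane plus the rows
#' bounding the IgG migration zone (region of interest). Edges come from an
#' upstream active-contour lane segmentation and may be real-valued.
#' Coordinates are 0-based: row y, column x.
#'
#' @param left_edge,right_edge numeric vectors, one entry per image row.
#' @param roi_top,roi_bottom 0-based row indices bounding the region of
#'   interest (inclusive).
#' @return An object of class `lane_geometry`.
#' @export
lane_geometry <- function(left_edge, right_edge, roi_top = 0,
                          roi_bottom = length(left_edge) - 1) {
  if (length(left_edge) != length(right_edge)) {
    stop("edge vectors must have equal length")
  }
  if (any(left_edge >= right_edge)) {
    stop("left edge must lie strictly left of the right edge in every row")
  }
  if (roi_top >= roi_bottom) stop("roi_top must be above roi_bottom")
  structure(list(left_edge = as.numeric(left_edge),
                 right_edge = as.numeric(right_edge),
                 roi_top = as.integer(roi_top),
                 roi_bottom = as.integer(roi_bottom)),
            class = "lane_geometry")
}

#' Maximum lane width over rows
#'
#' The rectified lane width `wmax = max_y (xright(y) - xleft(y))`.
#'
#' @param geometry a [lane_geometry].
#' @return Integer column count.
#' @export
compute_wmax <- function(geometry) {
  stopifnot(inherits(geometry, "lane_geometry"))
  as.integer(ceiling(max(geometry$right_edge - geometry$left_edge)))
}

#' Rectify a segmented lane to constant width
#'
#' Each row of the lane is translated horizontally so that the midline
#' between the left and right edges maps to the center column of a
#' `wmax`-wide output; rows outside the region of interest are dropped.
#' Midline offsets are real-valued, so rows are resampled by linear
#' interpolation; columns outside the lane extent for a row are flagged
#' missing (empty borders).
#'
#' @param gray numeric matrix (grayscale membrane or pre-cut lane).
#' @param geometry a [lane_geometry] with one edge pair per row of `gray`.
#' @return A [lane_image] of width [compute_wmax()] and
#'   `roi_bottom - roi_top + 1` rows.
#' @export
rectify_lane <- function(gray, geometry) {
  gray <- as.matrix(gray)
  stopifnot(inherits(geometry, "lane_geometry"))
  if (length(geometry$left_edge) != nrow(gray)) {
    stop("geometry rows do not match image rows")
  }
  wmax <- compute_wmax(geometry)
  rows <- seq.int(geometry$roi_top + 1L, geometry$roi_bottom + 1L)
  # edges are half-open ([xleft, xright), width = xright - xleft), so the
  # geometric center of the output is wmax / 2
  center <- wmax / 2
  out <- matrix(0, length(rows), wmax)
  miss <- matrix(TRUE, length(rows), wmax)
  xs <- seq_len(wmax) - 1  # output columns, 0-based
  for (i in seq_along(rows)) {
    y <- rows[i]
    xl <- geometry$left_edge[y]
    xr <- geometry$right_edge[y]
    mid <- (xl + xr) / 2
    src <- xs + (mid - center)          # input column for each output column
    inside <- src >= xl & src < xr      # half-open lane extent
    ok <- inside & src >= 0 & src <= ncol(gray) - 1
    if (any(ok)) {
      v <- approx(x = 0:(ncol(gray) - 1), y = gray[y, ], xout = src[ok],
                  rule = 2)$y
      out[i, ok] <- v
      miss[i, ok] <- FALSE
    }
  }
  lane_image(out, miss)
}

#' Mask detected artifacts as missing values
#'
#' Marks the pixels of an externally supplied artifact mask as missing so
#' they cannot bias background removal or the column-correlation energy.
#' Intensities are left untouched; the operation is idempotent.
#'
#' @param lane a [lane_image].
#' @param mask logical matrix, same shape as the lane; `TRUE` = artifact.
#' @return The lane with `missing = missing | mask`.
#' @export
apply_artifact_mask <- function(lane, mask) {
  assert_lane(lane)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(lane$intensity))) {
    stop("artifact mask shape does not match the lane")
  }
  lane$missing <- lane$missing | (mask > 0)
  lane
}

#' Read lane geometry from a tabular file
#'
#' Expects a whitespace- or tab-separated file with a header row and
#' columns `left` and `right` (one line per image row), preceded by
#' optional comment lines `# roi_top <int>` and `# roi_bottom <int>`
#' (0-based, inclusive).
#'
#' @param path file path.
#' @return A [lane_geometry].
#' @export
read_lane_geometry <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "\\s"), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^#\\s*", key, "\\s+"), "", m[1]))
    else default
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  if (!all(c("left", "right") %in% names(tab))) {
    stop(sprintf("geometry file '%s' needs 'left' and 'right' columns", path))
  }
  lane_geometry(tab$left, tab$right,
                roi_top = get_num("roi_top", 0),
                roi_bottom = get_num("roi_bottom", nrow(tab) - 1))
}
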