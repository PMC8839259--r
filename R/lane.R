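#' Rectified grayscale lane image with a missing-value mask
#'
#' The central container of the package: a real-valued intensity grid
#' (rows = migration axis y, columns = x) plus a logical mask of the same
#' shape marking pixels that carry no data (empty rectification borders or
#' masked artifacts). Missing values are always encoded out-of-band in the
#' mask, never as sentinel intensities.
#'
#' @param intensity numeric matrix of grayscale values (0-255 scale).
#' @param missing logical matrix of the same shape; `TRUE` = no data.
#'   Defaults to all-`FALSE`.
#' @return An object of class `lane_image` with elements `intensity` and
#'   `missing`.
#' @export
lane_image <- function(intensity, missing = NULL) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (is.null(missing)) {
    missing <- matrix(FALSE, nrow(intensity), ncol(intensity))
  }
  missing <- as.matrix(missing)
  if (!is.logical(missing)) storage.mode(missing) <- "logical"
  if (!identical(dim(intensity), dim(missing))) {
    stop("intensity and missing mask must have identical dimensions")
  }
  if (any(!is.finite(intensity[!missing]))) {
    stop("intensity must be finite wherever not missing")
  }
  structure(list(intensity = intensity, missing = missing),
            class = "lane_image")
}

#' @export
print.lane_image <- function(x, ...) {
  cat(sprintf("<lane_image> %d rows x %d cols, %d missing (%.1f%%)\n",
              nrow(x$intensity), ncol(x$intensity), sum(x$missing),
              100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.lane_image <- function(x) dim(x$intensity)

is_lane <- function(x) inherits(x, "lane_image")

assert_lane <- function(x) {
  if (!is_lane(x)) stop("expected a lane_image object")
  invisible(x)
}

#' Convert a grayscale lane to signal polarity
#'
#' Bands are dark (low gray value) on a light membrane. All processing in
#' this package operates on "signal" polarity where bands are peaks, so
#' scanned lanes are inverted as `signal = 255 - gray` before background
#' removal and straightening.
#'
#' @param lane a [lane_image] in gray polarity (bands dark).
#' @param white white level of the scan (default 255).
#' @return A [lane_image] in signal polarity (bands are peaks).
#' @export
as_signal <- function(lane, white = 255) {
  assert_lane(lane)
  out <- lane
  out$intensity <- white - lane$intensity
  out$intensity[lane$missing] <- 0
  out
}

#' Read and write lane images
#'
#' Lanes are stored as 32-bit float grayscale TIFF (intensity scaled to
#' 0-1 by `max_value`) with the missing mask in a paired TIFF whose
#' basename gains a `_mask` suffix.
#'
#' @param path path of the intensity TIFF.
#' @param lane a [lane_image].
#' @param max_value intensity corresponding to 1.0 in the file
#'   (default 255).
#' @return `read_lane` returns a [lane_image]; `write_lane` returns `path`
#'   invisibly.
#' @export
write_lane <- function(lane, path, max_value = 255) {
  assert_lane(lane)
  img <- pmin(pmax(lane$intensity / max_value, 0), 1)
  img[lane$missing] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(matrix(as.numeric(lane$missing), nrow(lane$missing)),
                  mask_path(path), bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_lane
#' @export
read_lane <- function(path, max_value = 255) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mp <- mask_path(path)
  miss <- if (file.exists(mp)) {
    m <- tiff::readTIFF(mp)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m > 0.5
  } else NULL
  lane_image(img * max_value, miss)
}

mask_path <- function(path) {
  sub("(\\.[A-Za-z]+)$", "_mask\\1", path)
}
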