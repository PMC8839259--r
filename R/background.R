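#' Rolling-ellipsoid parameters
#'
#' Radii of the ellipsoid rolled beneath the lane's intensity surface:
#' `rx` along the lane width, `ry` along the migration axis, `rz` along the
#' intensity axis. `ry` must be much larger than the typical band FWHM
#' (~7-30 px) so the ellipsoid cannot enter the valleys between bands and
#' band peaks survive subtraction; `rx` is of the order of the band-width
#' scale so narrow along-x background irregularities are removed.
#'
#' @param rx,ry radii in pixels; `rz` in intensity units.
#' @return An object of class `ellipsoid_params`.
#' @export
ellipsoid_params <- function(rx = 15, ry = 300, rz = 40) {
  if (rx <= 0 || ry <= 0 || rz <= 0) stop("all radii must be positive")
  structure(list(rx = rx, ry = ry, rz = rz), class = "ellipsoid_params")
}

#' Estimate a lane's smooth background with a rolling ellipsoid
#'
#' Computes the upper envelope reachable by an ellipsoid with radii
#' `(rx, ry, rz)` rolling beneath the intensity surface, i.e. a grayscale
#' opening with a non-flat ellipsoidal structuring function. The lane must
#' be in signal polarity (bands are peaks, see [as_signal()]): the
#' background then satisfies `background <= intensity` everywhere
#' non-missing, and subtracting it preserves band peaks while removing
#' smooth background and narrow along-x irregularities.
#'
#' Missing pixels are filled by nearest-neighbour inpainting before the
#' morphology (so artifact holes do not carve artificial valleys) and
#' re-masked in the output.
#'
#' @param lane a [lane_image] in signal polarity.
#' @param params an [ellipsoid_params].
#' @return A [lane_image] holding the background estimate (same missing
#'   mask as the input).
#' @export
rolling_ellipsoid_background <- function(lane, params = ellipsoid_params()) {
  assert_lane(lane)
  stopifnot(inherits(params, "ellipsoid_params"))
  if (all(lane$missing)) stop("lane has no non-missing pixel")
  filled <- if (any(lane$missing)) {
    cpp_fill_nearest(lane$intensity, lane$missing)
  } else {
    lane$intensity
  }
  bg <- cpp_roll_ellipsoid(filled, params$rx, params$ry, params$rz)
  lane_image(bg, lane$missing)
}

#' Subtract a background estimate from a lane
#'
#' Pointwise difference clipped at zero; missing masks are propagated by
#' union.
#'
#' @param lane a [lane_image] in signal polarity.
#' @param background a [lane_image] (or matrix) of the same shape.
#' @return A [lane_image] holding the band signal above background.
#' @export
subtract_background <- function(lane, background) {
  assert_lane(lane)
  bgm <- if (is_lane(background)) background$intensity else as.matrix(background)
  bgmiss <- if (is_lane(background)) background$missing else NULL
  if (!identical(dim(bgm), dim(lane$intensity))) {
    stop("background shape does not match the lane")
  }
  miss <- lane$missing
  if (!is.null(bgmiss)) miss <- miss | bgmiss
  out <- lane$intensity - bgm
  out[out < 0] <- 0
  out[miss] <- 0
  lane_image(out, miss)
}

#' Remove the background of a lane in one call
#'
#' Convenience wrapper: [rolling_ellipsoid_background()] followed by
#' [subtract_background()].
#'
#' @inheritParams rolling_ellipsoid_background
#' @return The background-subtracted [lane_image].
#' @export
remove_background <- function(lane, params = ellipsoid_params()) {
  subtract_background(lane, rolling_ellipsoid_background(lane, params))
}
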