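# Population SD (divide by n): bands are fully observed curves, not
# samples, so no Bessel correction.
pop_sd <- function(v) {
  sqrt(mean((v - mean(v))^2))
}

#' Sample a deformation field at arbitrary positions
#'
#' Bilinear sampling of \eqn{\Delta Y} at real-valued 0-based `(x, y)`
#' positions, clamped to the field extent; used to follow band midlines
#' through a warp.
#'
#' @param field a [deformation_field] or matrix.
#' @param xs,ys equal-length coordinate vectors (0-based pixels).
#' @return Numeric vector of shifts in pixels.
#' @export
field_at <- function(field, xs, ys) {
  f <- field_matrix(field)
  H <- nrow(f); W <- ncol(f)
  xs <- pmin(pmax(xs, 0), W - 1)
  ys <- pmin(pmax(ys, 0), H - 1)
  x0 <- pmin(floor(xs), W - 2); y0 <- pmin(floor(ys), H - 2)
  if (W < 2) { x0 <- rep(0, length(xs)) }
  if (H < 2) { y0 <- rep(0, length(ys)) }
  tx <- xs - x0; ty <- ys - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  idx <- function(y, x) f[cbind(y + 1, x + 1)]
  (1 - ty) * ((1 - tx) * idx(y0, x0) + tx * idx(y0, x1)) +
    ty * ((1 - tx) * idx(y1, x0) + tx * idx(y1, x1))
}

#' Standard deviation of a band midline
#'
#' The deviation of a band from a horizontal line, measured as the
#' population SD over the integer columns of the band's extent of `y(x)`
#' (before straightening) or `y(x) + DY(x, y(x))` (after straightening,
#' when a field is supplied; the field is sampled bilinearly).
#'
#' @param band a [band_annotation] spanning at least 2 columns.
#' @param field optional [deformation_field].
#' @return SD in pixels.
#' @export
band_sd <- function(band, field = NULL) {
  stopifnot(inherits(band, "band_annotation"))
  xs <- band_columns(band)
  if (length(xs) < 2) stop("band extent must span at least 2 columns")
  y <- midline_at(band, xs)
  if (!is.null(field)) y <- y + field_at(field, xs, y)
  pop_sd(y)
}

#' Count bands exceeding deformation thresholds
#'
#' For each threshold `t`, the number of bands whose midline SD exceeds
#' `t` pixels. Counts are nested: the count at t = 5 is included in the
#' counts at t = 2, 3 and 4.
#'
#' @param sds numeric vector of band SDs in pixels.
#' @param thresholds thresholds in pixels.
#' @return A named integer vector (`t2`, `t3`, ...).
#' @export
threshold_counts <- function(sds, thresholds = c(2, 3, 4, 5)) {
  counts <- vapply(thresholds, function(t) sum(sds > t), integer(1))
  names(counts) <- paste0("t", thresholds)
  counts
}

#' Deformation-reduction ratio
#'
#' `rho_t = num_before(t) / num_after(t)`: how many times fewer bands
#' exceed the deformation threshold after straightening. `Inf` when all
#' such bands were straightened (`num_after = 0`, `num_before > 0`); `NA`
#' (absent) when neither count is positive.
#'
#' @param num_before,num_after counts of bands with SD above the
#'   threshold before/after straightening (vectorized).
#' @return Numeric ratio(s).
#' @export
rho_ratio <- function(num_before, num_after) {
  ifelse(num_before == 0 & num_after == 0, NA_real_,
         num_before / num_after)
}

#' Deformation introduced on a band-free lane
#'
#' Band-free lanes should not be deformed at all: any spread of the
#' vertical shift within an image row is unnecessary deformation. Measured
#' as the mean over rows of the per-row population SD of `DY(., y)`.
#'
#' @param field a [deformation_field] from straightening a band-free lane.
#' @return Mean per-row SD in pixels.
#' @export
introduced_deformation <- function(field) {
  f <- field_matrix(field)
  mean(apply(f, 1, pop_sd))
}

#' Evaluate straightening against band annotations
#'
#' Computes each band's midline SD before and after applying the
#' deformation field, excludes bands with `sd_before <= exclude_below`
#' (their pre-existing deformation is within annotation variability and
#' would not affect peak detection), counts the remaining bands exceeding
#' each threshold before and after, and reports the ratios.
#'
#' @param bands list of [band_annotation] (band midlines traced on the
#'   *unstraightened* lane).
#' @param field the [deformation_field] returned by straightening.
#' @param thresholds deformation thresholds in pixels.
#' @param exclude_below exclude bands with `sd_before <=` this value.
#' @return An object of class `straighten_eval`: list with `bands` (data
#'   frame of per-band `sd_before`, `sd_after`, `excluded`) and `summary`
#'   (data frame of `threshold`, `num_before`, `num_after`, `rho`).
#' @export
evaluate_straightening <- function(bands, field, thresholds = c(2, 3, 4, 5),
                                   exclude_below = 1) {
  if (inherits(bands, "band_annotation")) bands <- list(bands)
  sd_before <- vapply(bands, band_sd, numeric(1))
  sd_after <- vapply(bands, band_sd, numeric(1), field = field)
  excluded <- sd_before <= exclude_below
  nb <- threshold_counts(sd_before[!excluded], thresholds)
  na_ <- threshold_counts(sd_after[!excluded], thresholds)
  structure(list(
    bands = data.frame(band = seq_along(bands), sd_before = sd_before,
                       sd_after = sd_after, excluded = excluded),
    summary = data.frame(threshold = thresholds,
                         num_before = as.integer(nb),
                         num_after = as.integer(na_),
                         rho = rho_ratio(as.integer(nb), as.integer(na_)))
  ), class = "straighten_eval")
}

#' @export
print.straighten_eval <- function(x, ...) {
  cat(sprintf("<straighten_eval> %d band(s), %d excluded (SD <= 1 px)\n",
              nrow(x$bands), sum(x$bands$excluded)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Pool several evaluation reports
#'
#' Concatenates the per-band tables of multiple [evaluate_straightening()]
#' reports and recomputes the threshold counts and ratios over the pooled
#' bands.
#'
#' @param reports list of `straighten_eval` objects.
#' @param thresholds thresholds in pixels.
#' @return A pooled `straighten_eval`.
#' @export
pool_evaluations <- function(reports, thresholds = c(2, 3, 4, 5)) {
  bands <- do.call(rbind, lapply(reports, `[[`, "bands"))
  keep <- !bands$excluded
  nb <- threshold_counts(bands$sd_before[keep], thresholds)
  na_ <- threshold_counts(bands$sd_after[keep], thresholds)
  structure(list(
    bands = bands,
    summary = data.frame(threshold = thresholds,
                         num_before = as.integer(nb),
                         num_after = as.integer(na_),
                         rho = rho_ratio(as.integer(nb), as.integer(na_)))
  ), class = "straighten_eval")
}
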