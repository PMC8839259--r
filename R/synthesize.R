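#' Sample synthetic band parameters
#'
#' Band count is drawn from the discrete uniform distribution on 1..12,
#' positions uniformly over the lane height, and the full width at half
#' maximum as `7 + r` px where `r` is exponential with mean 7 px (so the
#' minimum FWHM is exactly 7 px and the mean 14 px). Peak amplitudes are
#' log-uniform over `amplitude_range`, covering faint to strong bands.
#' Draws use R's global RNG; seed at the call site for reproducibility.
#'
#' @param height lane height in pixels.
#' @param n optional fixed band count (default: random 1..12).
#' @param amplitude_range range of peak amplitudes (intensity units).
#' @return A data frame with columns `position`, `fwhm`, `amplitude`.
#' @export
sample_bands <- function(height, n = NULL, amplitude_range = c(8, 80)) {
  if (height <= 0) stop("height must be positive")
  if (is.null(n)) n <- sample.int(12L, 1L)
  data.frame(
    position = runif(n, 0, height),
    fwhm = 7 + rexp(n, rate = 1 / 7),
    amplitude = exp(runif(n, log(amplitude_range[1]),
                          log(amplitude_range[2])))
  )
}

# Procedural smooth lane background: a 1-D vertical profile made of a base
# level plus 3-6 broad Gaussians (amplitudes <= 25 units), mildly smoothed.
# A stand-in for real negative (band-free) grayscale profiles, which a
# user hook can supply instead.
make_background_profile <- function(height, base = 12) {
  k <- sample(3:6, 1)
  y <- 0:(height - 1)
  prof <- rep(base, height)
  for (i in seq_len(k)) {
    a <- runif(1, 5, 25)
    mu <- runif(1, -0.2, 1.2) * height
    sg <- runif(1, height / 8, height / 3)
    prof <- prof + a * exp(-(y - mu)^2 / (2 * sg^2))
  }
  gaussian_smooth_vec(prof, sigma = 8)
}

gaussian_smooth_vec <- function(v, sigma) {
  n <- length(v)
  K <- outer(seq_len(n), seq_len(n),
             function(i, j) dnorm(j - i, sd = sigma))
  K <- K / rowSums(K)
  as.numeric(K %*% v)
}

# Separable 2-D Gaussian smoothing with border renormalization.
gaussian_smooth_mat <- function(m, sigma) {
  H <- nrow(m); W <- ncol(m)
  Ky <- outer(seq_len(H), seq_len(H), function(i, j) dnorm(j - i, sd = sigma))
  Ky <- Ky / rowSums(Ky)
  Kx <- outer(seq_len(W), seq_len(W), function(i, j) dnorm(j - i, sd = sigma))
  Kx <- Kx / rowSums(Kx)
  Ky %*% m %*% t(Kx)
}

#' Render a clean synthetic lane
#'
#' Signal-polarity lane: a smooth low-frequency background profile
#' (constant across columns) plus horizontal Gaussian-profile bands,
#' `signal(x, y) = bg(y) + sum_b amplitude_b * exp(-(y - position_b)^2 /
#' (2 sigma_b^2))` with `sigma_b = fwhm_b / (2 sqrt(2 ln 2))`.
#'
#' @param height,width lane dimensions in pixels.
#' @param bands data frame as returned by [sample_bands()].
#' @param background optional numeric vector of length `height` (a real
#'   negative profile); default: procedural smooth profile.
#' @return A [lane_image].
#' @export
render_lane <- function(height, width, bands,
                        background = NULL) {
  if (is.null(background)) background <- make_background_profile(height)
  if (length(background) != height) {
    stop("background profile length must equal the lane height")
  }
  y <- 0:(height - 1)
  prof <- background
  if (nrow(bands)) {
    sig <- bands$fwhm / (2 * sqrt(2 * log(2)))
    for (b in seq_len(nrow(bands))) {
      prof <- prof + bands$amplitude[b] *
        exp(-(y - bands$position[b])^2 / (2 * sig[b]^2))
    }
  }
  lane_image(matrix(prof, height, width))
}

#' Sample a smooth random deformation field
#'
#' Independent per-pixel uniform shifts smoothed by a large 2-D Gaussian
#' kernel and rescaled so the maximum absolute shift equals
#' `amplitude_px`; emulates smooth, non-uniform vertical band
#' deformations.
#'
#' @param height,width field dimensions.
#' @param amplitude_px maximum absolute shift (>= 0).
#' @param smoothing_sigma Gaussian kernel SD in pixels.
#' @return A [deformation_field].
#' @export
sample_deformation <- function(height, width, amplitude_px,
                               smoothing_sigma) {
  if (amplitude_px < 0) stop("amplitude must be non-negative")
  if (amplitude_px == 0) {
    return(deformation_field(matrix(0, height, width)))
  }
  raw <- matrix(runif(height * width, -1, 1), height, width)
  sm <- gaussian_smooth_mat(raw, smoothing_sigma)
  deformation_field(sm * (amplitude_px / max(abs(sm))))
}

#' Degrade a lane with artifacts and speckle noise
#'
#' Adds `artifact_count` randomly placed missing-value disks with radii
#' uniform in `radius_range`, then multiplicative speckle noise with unit
#' mean and variance `speckle_var` on the non-missing pixels.
#'
#' @param lane a [lane_image].
#' @param artifact_count number of disks.
#' @param radius_range disk radius range in pixels.
#' @param speckle_var speckle noise variance.
#' @return The degraded [lane_image].
#' @export
degrade_lane <- function(lane, artifact_count = 3, radius_range = c(2, 10),
                         speckle_var = 0.01) {
  assert_lane(lane)
  H <- nrow(lane$intensity); W <- ncol(lane$intensity)
  if (artifact_count > 0) {
    for (i in seq_len(artifact_count)) {
      cy <- runif(1, 0, H - 1); cx <- runif(1, 0, W - 1)
      r <- runif(1, radius_range[1], radius_range[2])
      ys <- 0:(H - 1); xs <- 0:(W - 1)
      disk <- outer(ys, xs, function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
      lane$missing <- lane$missing | disk
    }
  }
  if (speckle_var > 0) {
    a <- sqrt(3 * speckle_var)   # uniform multiplier: mean 1, var speckle_var
    noise <- matrix(1 + runif(H * W, -a, a), H, W)
    lane$intensity <- lane$intensity * noise
  }
  lane$intensity[lane$missing] <- 0
  lane
}

#' Generate a synthetic lane with ground truth
#'
#' Full simulation protocol: sample bands, render the clean lane, sample a
#' smooth deformation field, warp the lane with it, then degrade with
#' missing-value disks and speckle noise. The ground-truth annotations are
#' the deformed band midlines `y_b(x) = position_b + DY(x, position_b)`.
#'
#' @param seed integer seed (fully determines the lane); `NULL` uses the
#'   current RNG state.
#' @param height,width lane dimensions in pixels.
#' @param n_bands fixed band count, or `NULL` for the random 1..12 law;
#'   0 gives a band-free lane.
#' @param deformation_amplitude max absolute shift in px, or `NULL` for
#'   the default Uniform(2, 10) draw.
#' @param smoothing_sigma deformation smoothing SD in px, or `NULL` for
#'   Uniform(30, 80).
#' @param artifact_mean mean of the Poisson disk count.
#' @param radius_range artifact disk radius range.
#' @param speckle_var speckle noise variance.
#' @param amplitude_range band peak amplitude range (log-uniform).
#' @param background optional fixed background profile.
#' @return An object of class `synthetic_lane`: list with `lane`
#'   (degraded [lane_image]), `clean` (pre-deformation lane), `bands`,
#'   `truth_field`, `truth_annotations` (list of [band_annotation]) and
#'   `seed`.
#' @export
simulate_lane <- function(seed = NULL, height = 480, width = 190,
                          n_bands = NULL, deformation_amplitude = NULL,
                          smoothing_sigma = NULL, artifact_mean = 3,
                          radius_range = c(2, 10), speckle_var = 0.01,
                          amplitude_range = c(8, 80), background = NULL) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
  }
  bands <- if (!is.null(n_bands) && n_bands == 0) {
    data.frame(position = numeric(0), fwhm = numeric(0),
               amplitude = numeric(0))
  } else {
    sample_bands(height, n = n_bands, amplitude_range = amplitude_range)
  }
  clean <- render_lane(height, width, bands, background = background)
  if (is.null(deformation_amplitude)) deformation_amplitude <- runif(1, 2, 10)
  if (is.null(smoothing_sigma)) smoothing_sigma <- runif(1, 30, 80)
  truth <- sample_deformation(height, width, deformation_amplitude,
                              smoothing_sigma)
  deformed <- apply_deformation(clean, truth)
  n_disks <- rpois(1, artifact_mean)
  degraded <- degrade_lane(deformed, artifact_count = n_disks,
                           radius_range = radius_range,
                           speckle_var = speckle_var)
  xs <- 0:(width - 1)
  annotations <- lapply(seq_len(nrow(bands)), function(b) {
    yb <- bands$position[b] + field_at(truth, xs, rep(bands$position[b],
                                                      width))
    band_annotation(xs, yb)
  })
  structure(list(lane = degraded, clean = clean, bands = bands,
                 truth_field = truth, truth_annotations = annotations,
                 deformation_amplitude = deformation_amplitude,
                 smoothing_sigma = smoothing_sigma, seed = seed),
            class = "synthetic_lane")
}

#' @export
print.synthetic_lane <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_lane> %d x %d, %d band(s), deformation ",
                     "amplitude %.2f px (sigma %.0f px)\n"),
              nrow(x$lane$intensity), ncol(x$lane$intensity),
              nrow(x$bands), x$deformation_amplitude, x$smoothing_sigma))
  invisible(x)
}
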