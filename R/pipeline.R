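#' Default run configuration
#'
#' Every tunable default of the package in one nested list, round-
#' trippable through YAML ([read_config()] / [write_config()]). Unknown
#' keys are rejected on merge so typos cannot silently fall back to
#' defaults.
#'
#' @return A named list of class `gelwarp_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 0L,
    preprocess = list(dpi = 600, crop_top = 505L, crop_bottom = 100L),
    background = list(rx = 15, ry = 300, rz = 40),
    energy = list(wx = 0.05, wy = 0.025, p = 1, min_overlap = 8L),
    schedule = list(
      factors = list(c(8L, 8L), c(4L, 8L), c(2L, 8L), c(1L, 4L)),
      deltas = c(8, 4, 2, 1),
      moves = list(list(c(2L, 3L), c(3L, 3L)),
                   list(c(3L, 5L), c(4L, 5L)),
                   list(c(5L, 7L), c(6L, 9L)),
                   list(c(8L, 9L), c(10L, 11L)))),
    simulate = list(n_lanes = 5L, height = 480L, width = 190L,
                    artifact_mean = 3, radius_min = 2, radius_max = 10,
                    speckle_var = 0.01, amplitude_min = 8,
                    amplitude_max = 80),
    evaluate = list(thresholds = c(2, 3, 4, 5), exclude_below = 1)
  ), class = "gelwarp_config")
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop(sprintf("unknown configuration key '%s'", full))
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' @rdname default_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  override <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_config()), override)
  # YAML turns the schedule vectors into lists of lists; normalize
  cfg$schedule$factors <- lapply(cfg$schedule$factors, unlist)
  cfg$schedule$moves <- lapply(cfg$schedule$moves,
                               function(s) lapply(s, unlist))
  cfg$schedule$deltas <- unlist(cfg$schedule$deltas)
  structure(cfg, class = "gelwarp_config")
}

#' @rdname default_config
#' @param config a `gelwarp_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_schedule <- function(config) {
  hierarchy_schedule(factors = config$schedule$factors,
                     deltas = config$schedule$deltas,
                     moves = config$schedule$moves)
}

config_params <- function(config) {
  energy_params(wx = config$energy$wx, wy = config$energy$wy,
                p = config$energy$p,
                min_overlap = config$energy$min_overlap)
}

#' Straighten one lane end to end
#'
#' Background subtraction (rolling ellipsoid) followed by hierarchical
#' correlation-optimized warping.
#'
#' @param lane a [lane_image] in signal polarity.
#' @param config a `gelwarp_config` (see [default_config()]).
#' @param seed optimizer seed (default: the config's).
#' @return A `straighten_result` (see [straighten_lane()]).
#' @export
process_lane <- function(lane, config = default_config(),
                         seed = config$seed) {
  flat <- remove_background(lane, ellipsoid_params(config$background$rx,
                                                   config$background$ry,
                                                   config$background$rz))
  straighten_lane(flat, schedule = config_schedule(config),
                  params = config_params(config), seed = seed)
}

#' Run the simulate / straighten / evaluate pipeline
#'
#' Generates `config$simulate$n_lanes` synthetic lanes (per-lane seed =
#' `config$seed + lane index - 1`), straightens each with
#' [process_lane()], evaluates against the ground-truth band midlines,
#' and (optionally) writes per-lane artifacts: the straightened lane
#' (TIFF + mask), the deformation field (TSV), the truth annotations, and
#' a summary table.
#'
#' @param config a `gelwarp_config`.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return Invisibly, a list with `lanes` (per-lane result lists),
#'   `report` (pooled `straighten_eval`) and `summary` (per-lane data
#'   frame).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  n <- config$simulate$n_lanes
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  lanes <- vector("list", n)
  rows <- vector("list", n)
  reports <- list()
  for (i in seq_len(n)) {
    lane_seed <- config$seed + i - 1L
    sim <- simulate_lane(
      seed = lane_seed, height = config$simulate$height,
      width = config$simulate$width,
      artifact_mean = config$simulate$artifact_mean,
      radius_range = c(config$simulate$radius_min,
                       config$simulate$radius_max),
      speckle_var = config$simulate$speckle_var,
      amplitude_range = c(config$simulate$amplitude_min,
                          config$simulate$amplitude_max))
    res <- process_lane(sim$lane, config, seed = lane_seed)
    ev <- if (length(sim$truth_annotations)) {
      evaluate_straightening(sim$truth_annotations, res$field,
                             thresholds = config$evaluate$thresholds,
                             exclude_below = config$evaluate$exclude_below)
    } else NULL
    if (!is.null(ev)) reports[[length(reports) + 1]] <- ev
    lanes[[i]] <- list(sim = sim, result = res, eval = ev)
    rows[[i]] <- data.frame(
      lane = i, seed = lane_seed, n_bands = nrow(sim$bands),
      deformation_amplitude = sim$deformation_amplitude,
      energy_zero = res$energy_zero, energy_final = res$energy_final,
      mean_sd_before = if (!is.null(ev)) mean(ev$bands$sd_before) else NA,
      mean_sd_after = if (!is.null(ev)) mean(ev$bands$sd_after) else NA)
    if (!is.null(out_dir)) {
      write_lane(res$lane, file.path(out_dir,
                                     sprintf("lane%03d.tif", i)))
      write.table(field_matrix(res$field),
                  file.path(out_dir, sprintf("lane%03d_field.tsv", i)),
                  row.names = FALSE, col.names = FALSE)
      if (length(sim$truth_annotations)) {
        write_annotations(sim$truth_annotations,
                          file.path(out_dir,
                                    sprintf("lane%03d_truth.txt", i)))
      }
    }
  }
  summary <- do.call(rbind, rows)
  report <- if (length(reports)) {
    pool_evaluations(reports, thresholds = config$evaluate$thresholds)
  } else NULL
  if (!is.null(out_dir)) {
    write.table(summary, file.path(out_dir, "summary.tsv"),
                row.names = FALSE, quote = FALSE, sep = "\t")
    if (!is.null(report)) {
      write.table(report$summary, file.path(out_dir, "report.tsv"),
                  row.names = FALSE, quote = FALSE, sep = "\t")
    }
  }
  invisible(list(lanes = lanes, report = report, summary = summary))
}
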