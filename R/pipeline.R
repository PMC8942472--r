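# End-to-end orchestration: simulate (or read) -> optical flow -> segment
# -> track -> directionality -> morphometrics, with artifact output.
#
# Coordinate convention in all outputs: (x, y) = (column, row), origin at
# the top-left pixel, angles in radians from +x toward +y (downward rows).

#' Experiment configuration
#'
#' Exactly one of `movie_path` or `sim` must be given. All stage tunables
#' are collected here so a run is fully reproducible from its config echo.
#'
#' @param sim a [sim_params()] object, or `NULL`.
#' @param movie_path path to a multi-page TIFF, or `NULL`.
#' @param pixel_size,frame_interval calibration, required with
#'   `movie_path` (taken from `sim` otherwise).
#' @param lk an [lk_params()] object.
#' @param k intensity clusters for segmentation.
#' @param min_size minimum component size (px).
#' @param coherence_tol edge-coherence threshold (rad) for structure
#'   division.
#' @param window direction-analysis window, frames.
#' @param ridge_axis ridge orientation (rad) used for dimension
#'   measurements (taken from `sim` when present).
#' @param ef_schedule `NULL` or `list(on_s, reversal_s, cathode_axis)`:
#'   field-on time, reversal time (s), and the pre-reversal cathode
#'   direction (rad).
#' @param out_dir output directory, or `NULL` to skip writing artifacts.
#' @param seed integer seed for the run.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(sim = NULL, movie_path = NULL,
                              pixel_size = NULL, frame_interval = NULL,
                              lk = lk_params(), k = 3L, min_size = 9L,
                              coherence_tol = pi / 2, window = 12L,
                              ridge_axis = NULL, ef_schedule = NULL,
                              out_dir = NULL, seed = 1L) {
  if (is.null(sim) == is.null(movie_path)) {
    stop("exactly one of `sim` and `movie_path` must be set")
  }
  if (!is.null(movie_path) &&
      (is.null(pixel_size) || is.null(frame_interval))) {
    stop("`pixel_size` and `frame_interval` are required with `movie_path`")
  }
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_params"))
    pixel_size <- sim$pixel_size
    frame_interval <- sim$frame_interval
    if (is.null(ridge_axis)) ridge_axis <- sim$ridge_axis
  }
  if (is.null(ridge_axis)) ridge_axis <- 0
  if (!is.null(ef_schedule)) {
    stopifnot(is.list(ef_schedule),
              all(c("on_s", "reversal_s", "cathode_axis") %in%
                    names(ef_schedule)))
  }
  structure(
    list(sim = sim, movie_path = movie_path, pixel_size = pixel_size,
         frame_interval = frame_interval, lk = lk, k = as.integer(k),
         min_size = as.integer(min_size), coherence_tol = coherence_tol,
         window = as.integer(window), ridge_axis = ridge_axis,
         ef_schedule = ef_schedule, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# config echo with non-serializable members flattened
config_echo <- function(config) {
  ec <- list(
    source = if (is.null(config$movie_path)) "simulation" else
      config$movie_path,
    pixel_size_um = config$pixel_size,
    frame_interval_s = config$frame_interval,
    lk = config$lk[c("smooth_sigma", "window_size", "window_sigma",
                     "reliability_quantile_frac")],
    k = config$k, min_size = config$min_size,
    coherence_tol_rad = config$coherence_tol,
    window_frames = config$window,
    ridge_axis_rad = config$ridge_axis,
    seed = config$seed,
    coordinates = "(x, y) = (column, row), origin top-left, angles rad from +x toward +y"
  )
  if (!is.null(config$sim)) {
    ec$sim <- config$sim[setdiff(names(config$sim), "reversal")]
    ec$sim$surface <- config$sim$surface
  }
  if (!is.null(config$ef_schedule)) ec$ef_schedule <- config$ef_schedule
  ec
}

#' Run the full wave-quantification pipeline
#'
#' Simulates (or reads) the movie, computes reliability-gated optical flow,
#' segments and tracks waves, fits the direction mixture per analysis
#' window (whole-cell, plus front/back regions when an EF schedule is
#' given), builds the orientation kymograph, measures occupancy over time,
#' and fits the area-duration boundary when the tracked population allows
#' it. When `out_dir` is set, per-stage artifacts (track table, fits,
#' kymograph as CSV; summary and config echo as JSON/YAML) are written.
#'
#' @param config an [experiment_config()].
#' @param cell_mask logical matrix delimiting the cell; defaults to the
#'   simulation's cell mask, or to all pixels for movie input.
#' @return list of class `wave_report`: `tracks`, `track_table`, `fits`,
#'   `kymograph`, `occupancy` (per-frame fraction), `boundary` (a
#'   `boundary_fit` or `NULL`), `response` (front/back response times or
#'   `NULL`), `truth` (for simulated input), `summary` (plain list).
#' @export
run_pipeline <- function(config, cell_mask = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)

  if (!is.null(config$movie_path)) {
    if (!file.exists(config$movie_path)) {
      stop("input movie not found: ", config$movie_path)
    }
    movie <- read_movie_tiff(config$movie_path, config$pixel_size,
                             config$frame_interval)
    truth <- NULL
  } else {
    sim <- generate_movie(config$sim)
    movie <- sim$movie
    truth <- sim$truth
    if (is.null(cell_mask)) cell_mask <- truth$cell_mask
  }
  dm <- dim(movie$frames)
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, dm[1], dm[2])
  cell <- cell_geometry(cell_mask, config$pixel_size)

  flows <- movie_flow(movie, config$lk)
  seg <- segment_waves(movie, flows, k = config$k,
                       min_size = config$min_size,
                       coherence_tol = config$coherence_tol)
  tracks <- link_by_overlap(seg, config$pixel_size, config$frame_interval)
  ttab <- track_table(tracks, flows)

  fits <- fit_direction_windows(flows, config$frame_interval,
                                window = config$window)
  kymo <- orientation_kymograph(flows, config$frame_interval,
                                window = config$window)
  occupancy <- vapply(seg, function(s) {
    occupancy_ratio(s$labels > 0L, cell)
  }, numeric(1))

  # tracks whose maximum area stays at the minimum component size are
  # debris at the segmentation resolution limit, not waves; they would
  # otherwise populate the lower envelope of the area-duration plane
  area_floor <- 2 * config$min_size * config$pixel_size^2
  pop <- ttab[ttab$max_area >= area_floor, , drop = FALSE]
  boundary <- tryCatch(
    fit_area_duration_boundary(pop$duration, pop$max_area),
    error = function(e) NULL
  )

  response <- NULL
  if (!is.null(config$ef_schedule)) {
    new_dir <- wrap_angle(config$ef_schedule$cathode_axis + pi)
    halves <- front_back_split(cell, new_dir)
    # "new front" faces the post-reversal cathode, "old front" the original
    fits_new <- fit_direction_windows(flows, config$frame_interval,
                                      window = config$window,
                                      region = halves$front)
    fits_old <- fit_direction_windows(flows, config$frame_interval,
                                      window = config$window,
                                      region = halves$back)
    response <- list(
      new_front = response_time(fits_new, config$ef_schedule$reversal_s,
                                new_dir),
      old_front = response_time(fits_old, config$ef_schedule$reversal_s,
                                new_dir),
      whole_cell = response_time(fits, config$ef_schedule$reversal_s,
                                 new_dir),
      fits_new_front = fits_new, fits_old_front = fits_old
    )
  }

  pref <- lapply(fits, function(f) {
    if (is.null(f)) NA_real_ else preferential_direction(f)
  })
  summary <- list(
    n_frames = dm[3],
    n_tracks = length(tracks),
    occupancy = unname(occupancy),
    preferential_direction = unlist(pref),
    window_centers_s = vapply(
      seq_along(fits),
      function(i) (i - 0.5) * config$window * config$frame_interval,
      numeric(1)),
    boundary = if (is.null(boundary)) NULL else
      list(C = boundary$C, T = boundary$T, r_squared = boundary$r_squared),
    response_s = if (is.null(response)) NULL else
      response[c("new_front", "old_front", "whole_cell")],
    config = config_echo(config)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ttab, file.path(config$out_dir, "tracks.csv"),
                     row.names = FALSE)
    write_fits_csv(fits, file.path(config$out_dir, "direction_fits.csv"))
    write_kymograph_csv(kymo, file.path(config$out_dir, "kymograph.csv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    yaml::write_yaml(config_echo(config),
                     file.path(config$out_dir, "config.yaml"))
  }

  structure(
    list(movie = movie, flows = flows, segmentation = seg, tracks = tracks,
         track_table = ttab, fits = fits, kymograph = kymo,
         occupancy = occupancy, boundary = boundary, response = response,
         truth = truth, cell = cell, summary = summary),
    class = "wave_report"
  )
}

#' @export
print.wave_report <- function(x, ...) {
  cat(sprintf("<wave_report> %d frames, %d tracks, mean occupancy %.3f\n",
              x$summary$n_frames, x$summary$n_tracks,
              mean(x$occupancy)))
  if (!is.null(x$boundary)) print(x$boundary)
  if (!is.null(x$response)) {
    cat(sprintf("  response: new front %.0f s, old front %.0f s\n",
                x$response$new_front, x$response$old_front))
  }
  invisible(x)
}
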