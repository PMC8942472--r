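# Overlap tracking, track measurements, and cluster-based wave speed.

# build wave_mask_frame list from a list of logical matrices
as_mask_frames <- function(masks) {
  lapply(seq_along(masks), function(t) {
    structure(list(labels = EBImage::bwlabel(masks[[t]]), frame_index = t),
              class = "wave_mask_frame")
  })
}

blob <- function(rows, cols, r0, c0, h = 4, w = 6) {
  m <- matrix(FALSE, rows, cols)
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

test_that("one persistent blob gives one track with the right duration", {
  masks <- lapply(0:6, function(t) blob(40, 60, 10, 5 + 2 * t))
  tracks <- link_by_overlap(as_mask_frames(masks), 0.21, 10)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$duration, 70)
  expect_equal(tracks[[1]]$frames, 1:7)
  expect_equal(nrow(tracks[[1]]$centroid_path), 7)
  expect_true(all(tracks[[1]]$areas > 0))
})

test_that("disjoint blobs give distinct tracks and gaps are not closed", {
  two <- lapply(1:5, function(t) {
    blob(40, 60, 5, 5 + 2 * t) | blob(40, 60, 30, 40)
  })
  tracks <- link_by_overlap(as_mask_frames(two), 0.21, 10)
  expect_length(tracks, 2)
  expect_false(identical(tracks[[1]]$id, tracks[[2]]$id))

  # blob vanishes at frame 3, a new one appears elsewhere at frame 4
  gap <- list(blob(40, 60, 5, 5), blob(40, 60, 5, 7),
              matrix(FALSE, 40, 60), blob(40, 60, 30, 40))
  tracks <- link_by_overlap(as_mask_frames(gap), 0.21, 10)
  expect_length(tracks, 2)
  expect_equal(tracks[[1]]$frames, 1:2)
  expect_equal(tracks[[2]]$frames, 4L)
})

test_that("every labelled pixel belongs to exactly one track", {
  sp <- sim_params(rows = 128, cols = 128, cell_radius = 55, n_frames = 16,
                   wave_rate = 0.8, seed = 9)
  sim <- generate_movie(sp)
  flows <- movie_flow(sim$movie, lk_params(reliability_threshold = 2))
  seg <- segment_waves(sim$movie, flows)
  tracks <- link_by_overlap(seg, sp$pixel_size, sp$frame_interval)
  # conservation per frame
  for (t in seq_along(seg)) {
    lab_px <- sum(seg[[t]]$labels > 0)
    track_px <- sum(vapply(tracks, function(tr) {
      k <- match(t, tr$frames)
      if (is.na(k)) 0L else length(tr$masks[[k]])
    }, integer(1)))
    expect_equal(track_px, lab_px)
  }
  # duration additivity
  total_components <- sum(vapply(seg, function(s) max(s$labels), integer(1)))
  expect_equal(sum(vapply(tracks, `[[`, numeric(1), "duration")),
               sp$frame_interval * total_components)
})

test_that("track table has the documented shape", {
  expect_equal(nrow(track_table(list())), 0)
  expect_named(track_table(list()),
               c("id", "birth", "duration", "mean_area", "max_area", "speed",
                 "mean_direction", "centroid_x", "centroid_y"))
  masks <- lapply(0:3, function(t) blob(30, 30, 10, 5 + 2 * t))
  tracks <- link_by_overlap(as_mask_frames(masks), 0.21, 10)
  tab <- track_table(tracks)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$duration, tracks[[1]]$duration)
  expect_equal(tab$birth, 0)
})

test_that("a translating streak's speed is recovered within 10 percent", {
  sp <- sim_params(surface = "ridged", n_frames = 16, wave_rate = 0.15,
                   boundary_law = c(C = 1, T = 48),
                   duration_mean_frames = 12, duration_max_frames = 12,
                   speed = c(mean = 0.042, sd = 1e-6),
                   direction_law = c(0, 8, 1), seed = 1)
  sim <- generate_movie(sp)
  flows <- movie_flow(sim$movie, lk_params(reliability_threshold = 2))
  seg <- segment_waves(sim$movie, flows)
  tracks <- link_by_overlap(seg, sp$pixel_size, sp$frame_interval)
  mt <- match_tracks_to_truth(sim, tracks)
  i <- which.max(sim$truth$waves$duration)
  spd <- wave_speed(tracks[[mt[i]]], flows)
  expect_lt(abs(spd - sim$truth$waves$speed[i]) / sim$truth$waves$speed[i],
            0.10)
})

test_that("two counter-propagating waves both recover their speeds", {
  sp <- sim_params(surface = "ridged", n_frames = 16, wave_rate = 0.3,
                   boundary_law = c(C = 1, T = 48),
                   duration_mean_frames = 12, duration_max_frames = 12,
                   speed = c(mean = 0.042, sd = 1e-6),
                   direction_law = c(0, 12, 0.5), seed = 2)
  sim <- generate_movie(sp)
  flows <- movie_flow(sim$movie, lk_params(reliability_threshold = 2))
  seg <- segment_waves(sim$movie, flows)
  tracks <- link_by_overlap(seg, sp$pixel_size, sp$frame_interval)
  mt <- match_tracks_to_truth(sim, tracks)
  w <- sim$truth$waves
  long <- which(w$duration >= 40)
  # the two longest-lived waves run in roughly opposite directions
  expect_gt(max(abs(cortwave:::ang_diff(w$direction[long][1],
                                        w$direction[long][2]))), pi / 2)
  for (i in long) {
    spd <- wave_speed(tracks[[mt[i]]], flows)
    expect_lt(abs(spd - w$speed[i]) / w$speed[i], 0.15)
  }
})

test_that("a flickering static blob has near-zero speed", {
  rows <- 60L; cols <- 60L
  tex <- 1 + 0.3 * make_texture(rows, cols, 1, seed = 5)
  base <- matrix(0, rows, cols); base[25:35, 20:40] <- tex[25:35, 20:40]
  frames <- vapply(1:6, function(t) {
    500 + 1500 * (1 + 0.15 * (-1)^t) * base
  }, matrix(0, rows, cols))
  movie <- wave_movie(frames, 0.21, 10)
  flows <- movie_flow(movie, lk_params(reliability_threshold = 2))
  idx <- which(base > 0)
  track <- structure(
    list(id = 1L, frames = 1:5, masks = rep(list(idx), 5),
         areas = rep(length(idx) * 0.21^2, 5), duration = 50,
         pixel_size = 0.21, frame_interval = 10),
    class = "wave_track")
  spd <- wave_speed(track, flows)
  # under 0.2 px/frame equivalent (0.0042 um/s)
  expect_true(is.na(spd) || spd < 0.2 * 0.21 / 10)
})

test_that("short tracks yield the undefined-speed sentinel", {
  masks <- list(blob(30, 30, 10, 10))
  tracks <- link_by_overlap(as_mask_frames(masks), 0.21, 10)
  expect_true(is.na(wave_speed(tracks[[1]], list())))
})
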