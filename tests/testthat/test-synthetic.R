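# Synthetic movie generator: edge cases, determinism, and the generative
# laws it must realize (direction law, boundary law, duration accounting).

test_that("no-signal case gives constant-background frames", {
  sp <- sim_params(rows = 40, cols = 40, n_frames = 4, wave_rate = 0,
                   noise_sd = 0, seed = 1)
  sim <- generate_movie(sp)
  expect_true(all(sim$movie$frames == sp$background))
  expect_equal(nrow(sim$truth$waves), 0L)
})

test_that("identical seeds give bit-identical movies and ground truth", {
  sp <- sim_params(rows = 96, cols = 96, cell_radius = 40, n_frames = 12,
                   wave_rate = 0.6, seed = 42)
  a <- generate_movie(sp)
  b <- generate_movie(sp)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$waves, b$truth$waves)
  expect_identical(a$truth$masks, b$truth$masks)
})

test_that("generator rejects an empty cell mask and oversized waves", {
  expect_error(generate_movie(sim_params(rows = 40, cols = 40,
                                         cell_radius = 0, seed = 1)),
               "empty")
  # a boundary prefactor far above what the grid can hold
  sp <- sim_params(rows = 48, cols = 48, cell_radius = 20,
                   boundary_law = c(C = 500, T = 48), wave_rate = 2, seed = 1)
  expect_error(generate_movie(sp), "exceed")
})

test_that("ground-truth accounting is internally consistent", {
  sp <- sim_params(rows = 128, cols = 128, cell_radius = 55, n_frames = 24,
                   wave_rate = 0.8, seed = 7)
  sim <- generate_movie(sp)
  w <- sim$truth$waves
  expect_gt(nrow(w), 3)
  expect_equal(w$duration, (w$death - w$birth + 1) * sp$frame_interval)
  # every true mask pixel lies inside the cell mask, masks match union
  for (i in seq_len(nrow(w))) {
    for (f in names(sim$truth$masks[[i]])) {
      idx <- sim$truth$masks[[i]][[f]]
      expect_true(all(sim$truth$cell_mask[idx]))
      expect_true(all(sim$truth$union[, , as.integer(f)][idx]))
    }
  }
})

test_that("no wave lies below the minimum-area boundary", {
  px_area <- 0.21^2
  for (s in 1:3) {
    sp <- sim_params(rows = 128, cols = 128, cell_radius = 55, n_frames = 24,
                     wave_rate = 0.8, seed = s)
    sim <- generate_movie(sp)
    w <- sim$truth$waves
    bound <- sp$boundary_law[["C"]] * exp(w$duration / sp$boundary_law[["T"]])
    expect_true(all(w$area >= bound - px_area))
  }
})

test_that("true directions follow the antipodal bimodal von Mises law", {
  mu1 <- 0; kappa <- 2; p1 <- 0.7
  dirs <- c()
  for (s in 1:6) {
    sp <- sim_params(rows = 128, cols = 128, cell_radius = 55, n_frames = 36,
                     wave_rate = 1.2, direction_law = c(mu1, kappa, p1),
                     seed = s)
    dirs <- c(dirs, generate_movie(sp)$truth$waves$direction)
  }
  expect_gt(length(dirs), 250)
  nb <- 8L
  edges <- seq(0, 2 * pi, length.out = nb + 1L)
  counts <- tabulate(pmin(findInterval(dirs, edges), nb), nbins = nb)
  probs <- vapply(seq_len(nb), function(b) {
    integrate(function(th) {
      p1 * vm_pdf(th, mu1, kappa) + (1 - p1) * vm_pdf(th, mu1 + pi, kappa)
    }, edges[b], edges[b + 1L])$value
  }, numeric(1))
  gof <- suppressWarnings(chisq.test(counts, p = probs / sum(probs)))
  expect_gt(gof$p.value, 0.01)
})

test_that("circular mean of directions recovers mu1 modulo pi", {
  withr::with_seed(3, {
    th <- rbimodal_vm(2000, 1.3, 2, 0.7)
  })
  axial <- atan2(mean(sin(2 * th)), mean(cos(2 * th))) / 2
  d <- abs(((axial - 1.3) + pi / 2) %% pi - pi / 2)
  expect_lt(d, 0.1)
})

test_that("area-duration population traces the exponential envelope", {
  sp <- sim_params(boundary_law = c(C = 10, T = 50), seed = 5)
  pop <- area_duration_population(sp, 400)
  expect_equal(nrow(pop), 400)
  expect_true(all(pop$duration %% sp$frame_interval == 0))
  bound <- 10 * exp(pop$duration / 50)
  expect_true(all(pop$area >= bound))
  # single draw stays above its boundary value
  one <- area_duration_population(sim_params(seed = 8), 1)
  expect_gte(one$area, 2 * exp(one$duration / 48))
  # degenerate scatter: infinite rate collapses onto the boundary exactly
  sp0 <- sim_params(boundary_law = c(C = 10, T = 50),
                    area_scatter_rate = Inf, seed = 5)
  pop0 <- area_duration_population(sp0, 50)
  expect_equal(pop0$area, 10 * exp(pop0$duration / 50), tolerance = 1e-12)
})

test_that("movie TIFF round-trip preserves pixel data exactly", {
  sp <- sim_params(rows = 64, cols = 64, cell_radius = 26, n_frames = 6,
                   wave_rate = 0.8, seed = 2)
  sim <- generate_movie(sp)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(sim$movie, path)
  back <- read_movie_tiff(path, sp$pixel_size, sp$frame_interval)
  expect_identical(back$frames, sim$movie$frames)
})
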