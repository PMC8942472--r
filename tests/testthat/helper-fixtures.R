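# Shared fixtures: small in-code synthetic scenes and ground-truth matching.

# band-limited random texture (smoothed white noise), reproducible
make_texture <- function(rows, cols, sigma = 2, seed = 9) {
  withr::with_seed(seed, {
    cortwave:::conv2_reflect(matrix(rnorm(rows * cols), rows, cols),
                             cortwave:::gauss_kernel2d(sigma))
  })
}

# translate matrix content by (dx cols, dy rows), zero-filled borders
shift_frame <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- 1:(nrow(m) - abs(dy))
  src_c <- 1:(ncol(m) - abs(dx))
  out[src_r + max(dy, 0), src_c + max(dx, 0)] <-
    m[src_r - min(dy, 0), src_c - min(dx, 0)]
  out
}

# best-overlap track id for every ground-truth wave (0 = unmatched)
match_tracks_to_truth <- function(sim, tracks) {
  vapply(seq_len(nrow(sim$truth$waves)), function(i) {
    m <- sim$truth$masks[[i]]
    best <- 0L; besto <- 0L
    for (j in seq_along(tracks)) {
      ov <- 0L
      for (k in seq_along(tracks[[j]]$frames)) {
        f <- as.character(tracks[[j]]$frames[k])
        if (f %in% names(m)) {
          ov <- ov + length(intersect(tracks[[j]]$masks[[k]], m[[f]]))
        }
      }
      if (ov > besto) { besto <- ov; best <- j }
    }
    best
  }, integer(1))
}

# per-frame Jaccard between detected wave pixels and ground truth
frame_jaccard <- function(seg, sim) {
  vapply(seq_along(seg), function(t) {
    det <- seg[[t]]$labels > 0L
    tru <- sim$truth$union[, , t]
    if (!any(tru)) return(NA_real_)
    sum(det & tru) / sum(det | tru)
  }, numeric(1))
}

# one fused structure whose two halves move apart in opposite x
# directions (a composite dividing into two waves); returns the fused
# component, its flow field, and the true dividing column
make_colliding_pair <- function(seed = 4) {
  rows <- 60L; cols <- 120L
  texL <- 1 + 0.3 * make_texture(rows, cols, 1, seed)
  texR <- 1 + 0.3 * make_texture(rows, cols, 1, seed + 100)
  blockL <- matrix(0, rows, cols); blockL[25:35, 20:59] <- texL[25:35, 20:59]
  blockR <- matrix(0, rows, cols); blockR[25:35, 60:99] <- texR[25:35, 60:99]
  f1 <- 500 + 1500 * (blockL + blockR)
  f2 <- 500 + 1500 * (shift_frame(blockL, -2, 0) + shift_frame(blockR, 2, 0))
  fl <- lucas_kanade(smooth_frame(f1, 3), smooth_frame(f2, 3),
                     lk_params(reliability_threshold = 1))
  comp <- which(blockL + blockR > 0)
  list(component = comp, flow = fl, true_split_col = 59.5, dim = c(rows, cols))
}
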