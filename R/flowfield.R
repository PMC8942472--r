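# Lucas-Kanade optical flow with Gaussian-weighted structure tensor and
# smallest-eigenvalue reliability gating.

#' Lucas-Kanade parameters
#'
#' Bundle the tunables of the optical-flow stage. The defaults reproduce the
#' standard analysis settings for confocal limE movies: frames pre-smoothed
#' with a 2D Gaussian of sd 3 px, a 19 x 19 Gaussian weight window of sd
#' 2 px (0.42 um at 0.21 um/px), and a data-adaptive reliability cutoff.
#'
#' @param smooth_sigma sd (px) of the Gaussian pre-filter applied to each
#'   frame before differentiation.
#' @param window_size side (px, odd) of the Gaussian weight window `w` used
#'   to accumulate the structure tensor.
#' @param window_sigma sd (px) of the weight window.
#' @param reliability_threshold cutoff on the smallest eigenvalue of the
#'   weighted structure tensor, in squared-intensity units. `NULL` selects
#'   `reliability_quantile_frac` times the 95th percentile of the observed
#'   reliabilities (per movie, or per frame pair when fields are computed
#'   singly).
#' @param reliability_quantile_frac fraction of the 95th reliability
#'   percentile used when `reliability_threshold` is `NULL`.
#' @return an object of class `lk_params`.
#' @export
#' @examples
#' lk_params()
lk_params <- function(smooth_sigma = 3,
                      window_size = 19L,
                      window_sigma = 2,
                      reliability_threshold = NULL,
                      reliability_quantile_frac = 0.1) {
  window_size <- as.integer(window_size)
  if (window_size < 3L || window_size %% 2L == 0L) {
    stop("`window_size` must be odd and >= 3")
  }
  if (smooth_sigma <= 0 || window_sigma <= 0) stop("sigmas must be positive")
  if (!is.null(reliability_threshold) && reliability_threshold < 0) {
    stop("`reliability_threshold` must be >= 0")
  }
  structure(
    list(smooth_sigma = smooth_sigma,
         window_size = window_size,
         window_sigma = window_sigma,
         reliability_threshold = reliability_threshold,
         reliability_quantile_frac = reliability_quantile_frac),
    class = "lk_params"
  )
}

#' Gaussian-smooth a frame
#'
#' 2D Gaussian filtering with reflective boundary handling. Constant frames
#' are preserved exactly and the kernel integrates to one.
#'
#' @param frame numeric matrix of intensities.
#' @param sigma Gaussian sd in pixels (> 0).
#' @return smoothed matrix, same shape.
#' @export
smooth_frame <- function(frame, sigma) {
  if (!is.matrix(frame) || !all(is.finite(frame))) {
    stop("`frame` must be a finite numeric matrix")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive scalar")
  }
  conv2_reflect(frame, gauss_kernel2d(sigma))
}

#' Per-pixel Lucas-Kanade optical flow between two frames
#'
#' Solves, at every pixel, the weighted least-squares flow equation
#' `A^T w A [u v]' = -A^T w b` where `A` holds the spatial intensity
#' gradients over the weight window, `b` the temporal differences, and `w`
#' the Gaussian window weights. The per-pixel reliability is the smallest
#' eigenvalue of the structure tensor `A^T w A`; pixels with a singular
#' tensor receive zero flow and zero reliability. `u` is the displacement
#' along `+x` (columns), `v` along `+y` (rows), both in px/frame.
#'
#' @param prev,next_frame consecutive frames (same shape), already smoothed
#'   (see [smooth_frame()]); `lucas_kanade()` does not smooth internally so
#'   the pre-filter remains a separate, testable stage.
#' @param params an [lk_params()] object.
#' @return an object of class `flow_field` with elements `u`, `v`,
#'   `reliability`, `valid_mask`, and `threshold` (the cutoff actually
#'   applied).
#' @export
lucas_kanade <- function(prev, next_frame, params = lk_params()) {
  if (!is.matrix(prev) || !is.matrix(next_frame) ||
      !all(dim(prev) == dim(next_frame))) {
    stop("`prev` and `next_frame` must be matrices of identical shape")
  }
  g <- gradient_xy((prev + next_frame) / 2)
  it <- next_frame - prev
  w <- gauss_kernel2d(params$window_sigma, size = params$window_size)

  jxx <- conv2_reflect(g$gx * g$gx, w)
  jxy <- conv2_reflect(g$gx * g$gy, w)
  jyy <- conv2_reflect(g$gy * g$gy, w)
  jxt <- conv2_reflect(g$gx * it, w)
  jyt <- conv2_reflect(g$gy * it, w)

  half_tr <- (jxx + jyy) / 2
  disc <- sqrt(pmax((jxx - jyy)^2 / 4 + jxy^2, 0))
  lam_min <- pmax(half_tr - disc, 0)

  det <- jxx * jyy - jxy^2
  eps <- .Machine$double.eps * max(half_tr, 1e-300)
  singular <- det <= eps
  det_safe <- ifelse(singular, 1, det)
  u <- (-jyy * jxt + jxy * jyt) / det_safe
  v <- (jxy * jxt - jxx * jyt) / det_safe
  u[singular] <- 0
  v[singular] <- 0
  lam_min[singular] <- 0

  thr <- params$reliability_threshold
  if (is.null(thr)) {
    thr <- params$reliability_quantile_frac *
      stats::quantile(lam_min, 0.95, names = FALSE)
  }
  structure(
    list(u = u, v = v, reliability = lam_min,
         valid_mask = lam_min >= thr & thr > 0,
         threshold = thr,
         max_disp = (params$window_size - 1) / 2),
    class = "flow_field"
  )
}

# orientation-trustworthy vectors: reliable AND physically measurable.
# A two-frame LK solve cannot report displacements beyond its window
# half-width; larger solutions arise where an object appears or vanishes
# between the frames, and carry no direction information.
orient_valid <- function(flow) {
  flow$valid_mask & flow$u^2 + flow$v^2 <= flow$max_disp^2
}

#' Optical flow for every consecutive frame pair of a movie
#'
#' Smooths each frame once, computes Lucas-Kanade flow for all consecutive
#' pairs, and applies a single movie-wide reliability cutoff (by default a
#' stated fraction of the 95th percentile of all per-pixel reliabilities),
#' so that validity is comparable across frames.
#'
#' @param movie a `wave_movie` (see [generate_movie()] / [read_movie_tiff()]).
#' @param params an [lk_params()] object.
#' @return list of `flow_field` objects, one per consecutive frame pair
#'   (element `t` describes motion from frame `t` to `t + 1`).
#' @export
movie_flow <- function(movie, params = lk_params()) {
  stopifnot(inherits(movie, "wave_movie"))
  nf <- dim(movie$frames)[3]
  if (nf < 2L) stop("movie must have at least 2 frames")
  sm <- lapply(seq_len(nf), function(t) {
    smooth_frame(movie$frames[, , t], params$smooth_sigma)
  })
  # compute with threshold 0, then gate globally
  p0 <- params
  p0$reliability_threshold <- 0
  flows <- lapply(seq_len(nf - 1L), function(t) {
    lucas_kanade(sm[[t]], sm[[t + 1L]], p0)
  })
  thr <- params$reliability_threshold
  if (is.null(thr)) {
    all_rel <- unlist(lapply(flows, function(f) as.vector(f$reliability)))
    thr <- params$reliability_quantile_frac *
      stats::quantile(all_rel, 0.95, names = FALSE)
  }
  lapply(flows, function(f) {
    f$threshold <- thr
    f$valid_mask <- f$reliability >= thr & thr > 0
    f
  })
}

#' Orientations of reliable flow vectors
#'
#' Returns `atan2(v, u)` wrapped into `[0, 2*pi)` for every pixel of the
#' valid mask (optionally restricted to a region), unweighted by vector
#' magnitude. Vectors whose solved displacement exceeds the LK window
#' half-width are excluded: they occur where an object appears or vanishes
#' between the two frames and their direction is meaningless.
#'
#' @param flow a `flow_field`.
#' @param region optional logical matrix restricting the pixels considered.
#' @return numeric vector of angles in radians (possibly empty).
#' @export
flow_orientations <- function(flow, region = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  sel <- orient_valid(flow)
  if (!is.null(region)) sel <- sel & region
  wrap_angle(atan2(flow$v[sel], flow$u[sel]))
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d x %d px, %d reliable vectors (threshold %.3g)\n",
    nrow(x$u), ncol(x$u), sum(x$valid_mask), x$threshold
  ))
  invisible(x)
}
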