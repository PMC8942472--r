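# Internal helpers shared across modules.

#' Wrap angles into [0, 2*pi)
#' @param theta angles in radians.
#' @return wrapped angles.
#' @keywords internal
#' @noRd
wrap_angle <- function(theta) theta %% (2 * pi)

# Signed smallest difference a - b on the circle, in (-pi, pi].
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Absolute angular distance in [0, pi].
ang_dist <- function(a, b) abs(ang_diff(a, b))

# Circular mean of angles; NA for empty input.
circ_mean <- function(theta) {
  if (length(theta) == 0L) return(NA_real_)
  wrap_angle(atan2(mean(sin(theta)), mean(cos(theta))))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library internals never perturb user-level streams.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# 1D Gaussian kernel sampled on integers, radius ceiling(4*sigma), sum 1.
gauss_kernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 2D Gaussian kernel (outer product), odd size, sum 1.
gauss_kernel2d <- function(sigma, size = 2 * ceiling(4 * sigma) + 1) {
  stopifnot(size %% 2 == 1)
  r <- (size - 1) / 2
  k1 <- exp(-seq(-r, r)^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# Reflect-pad a matrix by `r` pixels on each side (mirror without repeating
# the border pixel when possible; falls back to edge replication for tiny
# inputs).
reflect_pad <- function(m, r) {
  idx <- function(n) {
    i <- seq(1 - r, n + r)
    # reflect about 0.5 and n + 0.5 repeatedly
    period <- 2 * n
    i <- ((i - 1) %% period + period) %% period + 1
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  m[idx(nrow(m)), idx(ncol(m)), drop = FALSE]
}

# Convolve with an odd-sized kernel under reflective boundary handling.
conv2_reflect <- function(m, kernel) {
  r <- (dim(kernel)[1] - 1) / 2
  padded <- reflect_pad(m, r)
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
}

# Central-difference spatial gradients (x = column, y = row); edges use
# one-sided differences.
gradient_xy <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  if (nc >= 3) gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  if (nc >= 2) {
    gx[, 1] <- m[, 2] - m[, 1]
    gx[, nc] <- m[, nc] - m[, nc - 1]
  }
  if (nr >= 3) gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  if (nr >= 2) {
    gy[1, ] <- m[2, ] - m[1, ]
    gy[nr, ] <- m[nr, ] - m[nr - 1, ]
  }
  list(gx = gx, gy = gy)
}

# Erode a logical mask with the 4-neighbour cross element, `n` times.
erode4 <- function(mask, n = 1L) {
  m <- mask
  for (i in seq_len(n)) {
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    down <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    left <- cbind(m[, -1, drop = FALSE], FALSE)
    right <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    m <- m & up & down & left & right
  }
  m
}

# row/col coordinates of TRUE pixels or linear indices; returns a matrix
# with columns (row, col).
pixel_coords <- function(idx, dim) {
  if (is.logical(idx)) idx <- which(idx)
  cbind(row = ((idx - 1) %% dim[1]) + 1, col = ((idx - 1) %/% dim[1]) + 1)
}
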