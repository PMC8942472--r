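# Wave-population morphometrics: dimensions relative to the ridge axis,
# the exponential minimum-area vs duration boundary fit, occupancy ratio,
# and subcellular spatial profiles with front/back splitting.

#' Cell geometry from a mask
#'
#' Centroid and equivalent-disk radius (the radius of the disk with the
#' same area) of a cell mask, in micrometres.
#'
#' @param mask logical matrix.
#' @param pixel_size um/px.
#' @return object of class `cell_geometry`: `mask`, `center` (`c(x, y)`,
#'   um), `radius` (um).
#' @export
cell_geometry <- function(mask, pixel_size) {
  if (!any(mask)) stop("cell mask is empty")
  co <- pixel_coords(mask, dim(mask))
  structure(
    list(mask = mask,
         center = c(x = mean(co[, "col"]), y = mean(co[, "row"])) * pixel_size,
         radius = sqrt(sum(mask) / pi) * pixel_size,
         pixel_size = pixel_size),
    class = "cell_geometry"
  )
}

#' Wave extents parallel and perpendicular to the ridge axis
#'
#' Projects the pixel centres of a wave mask onto the ridge axis and its
#' normal; each extent is the max-minus-min projection plus one pixel
#' footprint, in micrometres.
#'
#' @param mask logical matrix or linear pixel indices.
#' @param ridge_axis ridge orientation, radians.
#' @param pixel_size um/px.
#' @param dim matrix dimensions, required when `mask` is an index vector.
#' @return named numeric `c(parallel, perpendicular)` in um.
#' @export
wave_dimensions <- function(mask, ridge_axis, pixel_size, dim = NULL) {
  if (is.logical(mask)) {
    dm <- base::dim(mask)
    idx <- which(mask)
  } else {
    if (is.null(dim)) stop("`dim` is required for index input")
    dm <- dim
    idx <- mask
  }
  if (length(idx) == 0L) stop("empty wave mask")
  co <- pixel_coords(idx, dm)
  x <- co[, "col"]; y <- co[, "row"]
  par_ <- x * cos(ridge_axis) + y * sin(ridge_axis)
  perp <- -x * sin(ridge_axis) + y * cos(ridge_axis)
  c(parallel = (max(par_) - min(par_) + 1) * pixel_size,
    perpendicular = (max(perp) - min(perp) + 1) * pixel_size)
}

#' Fit the exponential minimum-area vs duration boundary
#'
#' Waves are grouped by their (frame-grid) duration; within each group the
#' `min(n_smallest, group size)` smallest areas are selected, and
#' `log(area) = log(C) + duration / T` is fitted to the selected points by
#' ordinary least squares. `T` is the characteristic timescale of the wave
#' system: the lower envelope of attainable areas grows as
#' `C * exp(duration / T)`, and a larger `T` indicates a system closer to
#' its excitability threshold.
#'
#' @param duration per-wave durations (s); must take at least 3 distinct
#'   values.
#' @param area per-wave areas (um^2); the per-wave maximum is the
#'   recommended scalar.
#' @param n_smallest boundary points kept per duration group.
#' @return object of class `boundary_fit`: `C` (um^2), `T` (s),
#'   `points_used` (data.frame of the selected pairs), `r_squared` (on the
#'   log scale, over the selected points).
#' @export
fit_area_duration_boundary <- function(duration, area, n_smallest = 5L) {
  stopifnot(length(duration) == length(area))
  keep <- is.finite(duration) & is.finite(area) & area > 0
  duration <- duration[keep]; area <- area[keep]
  if (length(unique(duration)) < 3L) {
    stop("need at least 3 distinct duration values to fit the boundary")
  }
  sel <- unlist(lapply(split(seq_along(duration), duration), function(ix) {
    ix[order(area[ix])][seq_len(min(n_smallest, length(ix)))]
  }), use.names = FALSE)
  d <- duration[sel]; la <- log(area[sel])
  fit <- stats::lm(la ~ d)
  slope <- stats::coef(fit)[["d"]]
  if (!is.finite(slope) || slope <= 0) {
    stop("boundary fit produced a non-positive slope; no exponential envelope")
  }
  ss_tot <- sum((la - mean(la))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(C = exp(stats::coef(fit)[["(Intercept)"]]),
         T = 1 / slope,
         points_used = data.frame(duration = d, area = area[sel]),
         r_squared = r2),
    class = "boundary_fit"
  )
}

#' @export
print.boundary_fit <- function(x, ...) {
  cat(sprintf(
    "<boundary_fit> area_min = %.3g * exp(duration / %.3g s), R^2 = %.3f (%d points)\n",
    x$C, x$T, x$r_squared, nrow(x$points_used)))
  invisible(x)
}

#' Fraction of the cell area occupied by waves
#'
#' @param wave_mask logical matrix of wave pixels.
#' @param cell a `cell_geometry` (or logical matrix).
#' @return fraction in `[0, 1]`.
#' @export
occupancy_ratio <- function(wave_mask, cell) {
  cmask <- if (inherits(cell, "cell_geometry")) cell$mask else cell
  stopifnot(all(dim(wave_mask) == dim(cmask)))
  if (!any(cmask)) stop("cell mask is empty")
  sum(wave_mask & cmask) / sum(cmask)
}

#' Mean wave area by normalized subcellular position
#'
#' Sections waves by their `x` position relative to the cell centre,
#' normalized by the cell radius and clipped to `[-1, 1]`, into bins of
#' width `bin_width` (default 0.25, i.e. 8 sections), and returns the mean
#' wave area per section.
#'
#' @param x per-wave centroid x positions (um).
#' @param area per-wave areas (um^2).
#' @param cell a `cell_geometry`.
#' @param bin_width bin width in normalized units; must divide 2 evenly.
#' @return `data.frame`: `bin_low`, `bin_high`, `mean_area` (NA for empty
#'   bins), `n`, `occupied`.
#' @export
spatial_profile <- function(x, area, cell, bin_width = 0.25) {
  stopifnot(inherits(cell, "cell_geometry"), length(x) == length(area))
  if (cell$radius <= 0) stop("cell radius must be > 0")
  nb <- 2 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("`bin_width` must divide 2 evenly")
  nb <- as.integer(round(nb))
  xn <- pmin(pmax((x - cell$center[["x"]]) / cell$radius, -1), 1)
  edges <- seq(-1, 1, length.out = nb + 1L)
  bin <- pmin(findInterval(xn, edges, rightmost.closed = TRUE), nb)
  out <- data.frame(bin_low = edges[-(nb + 1L)], bin_high = edges[-1L],
                    mean_area = NA_real_, n = 0L, occupied = FALSE)
  for (b in seq_len(nb)) {
    sel <- bin == b
    if (any(sel)) {
      out$mean_area[b] <- mean(area[sel])
      out$n[b] <- sum(sel)
      out$occupied[b] <- TRUE
    }
  }
  out
}

#' Split a cell into front and back halves relative to a field axis
#'
#' Partitions the cell mask by the line through the cell centre
#' perpendicular to `ef_axis`; the `front` half faces the cathode (the
#' direction `ef_axis` points to), the `back` half faces away. Reversing
#' the axis (`ef_axis + pi`) swaps the two masks.
#'
#' @param cell a `cell_geometry`.
#' @param ef_axis direction toward the cathode, radians.
#' @return list of logical matrices `front` and `back`.
#' @export
front_back_split <- function(cell, ef_axis) {
  stopifnot(inherits(cell, "cell_geometry"))
  dm <- dim(cell$mask)
  px <- cell$pixel_size
  xg <- matrix(rep(seq_len(dm[2]), each = dm[1]), dm[1], dm[2]) * px
  yg <- matrix(rep(seq_len(dm[1]), times = dm[2]), dm[1], dm[2]) * px
  dotp <- (xg - cell$center[["x"]]) * cos(ef_axis) +
    (yg - cell$center[["y"]]) * sin(ef_axis)
  list(front = cell$mask & dotp > 0, back = cell$mask & dotp <= 0)
}
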