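# Wave segmentation: intensity k-means for bright regions, reliability
# gating for motion, and flow-coherence division of composite structures.

#' Bright-region mask by intensity k-means
#'
#' Clusters the pixel intensities of one frame into `k` groups (k-means,
#' fixed internal seed, multiple restarts) and returns the pixels assigned
#' to the cluster with the highest centroid. Cluster ordering by centroid
#' makes the mask invariant under adding a constant to the frame.
#'
#' @param frame numeric intensity matrix.
#' @param k number of intensity clusters (default 3: background, dim halo,
#'   bright wave interior).
#' @param n_restarts k-means restarts.
#' @return logical matrix.
#' @export
bright_mask <- function(frame, k = 3L, n_restarts = 10L) {
  v <- as.vector(frame)
  if (length(unique(v)) < k) {
    stop(sprintf("degenerate frame: fewer than %d distinct intensities", k))
  }
  km <- with_seed(181101L, stats::kmeans(v, centers = k, nstart = n_restarts,
                                         iter.max = 50L))
  bright_cluster <- which.max(km$centers[, 1])
  matrix(km$cluster == bright_cluster, nrow(frame), ncol(frame))
}

#' Restrict a bright mask to reliably moving pixels
#'
#' Intersection of the bright mask with the optical-flow validity mask, so
#' that bright noise with no trackable structure is discarded. Reliability
#' measures image structure rather than motion, so a textured object that
#' does not move still passes the intersection; set `min_magnitude` above
#' zero to additionally require a minimum flow displacement.
#'
#' @param bright logical matrix from [bright_mask()].
#' @param flow a `flow_field` of the same shape.
#' @param min_magnitude minimum flow magnitude (px/frame) for a pixel to
#'   count as moving; 0 (the default) keeps the plain intersection.
#' @return logical matrix.
#' @export
moving_mask <- function(bright, flow, min_magnitude = 0) {
  stopifnot(inherits(flow, "flow_field"), all(dim(bright) == dim(flow$u)))
  out <- bright & flow$valid_mask
  if (min_magnitude > 0) {
    out <- out & (flow$u^2 + flow$v^2 >= min_magnitude^2)
  }
  out
}

#' Divide a connected structure into independently moving sub-waves
#'
#' Examines the flow orientation in the two edge bands of a connected
#' component at the opposite ends of its principal axis. If the two
#' circular-mean orientations agree to within `coherence_tol`, the
#' component is one coordinated wave and is returned intact; otherwise it
#' is split into parts by assigning every pixel to the edge whose mean
#' orientation (for pixels with reliable flow) or whose seed region (for
#' the rest) is closer. The returned pixel sets always partition the input.
#'
#' @param component linear pixel indices (or a logical matrix) of one
#'   connected component.
#' @param flow the frame's `flow_field`.
#' @param coherence_tol angular difference (rad) up to which the two edges
#'   count as coordinated.
#' @param band_px inward depth (px) of the edge bands.
#' @param min_size components smaller than this are returned intact.
#' @param min_band_vectors minimum orientation-trustworthy vectors each
#'   edge band must hold for the coherence decision; with less evidence
#'   (e.g. in the frame where a wave dissipates) the component is kept
#'   intact.
#' @return list of integer vectors of linear pixel indices.
#' @export
divide_structures <- function(component, flow, coherence_tol = pi / 2,
                              band_px = 2L, min_size = 9L,
                              min_band_vectors = 5L) {
  dm <- dim(flow$u)
  if (is.logical(component)) component <- which(component)
  if (length(component) < min_size) return(list(component))

  mask <- matrix(FALSE, dm[1], dm[2])
  mask[component] <- TRUE
  band <- mask & !erode4(mask, band_px)
  co <- pixel_coords(component, dm)
  x <- co[, "col"]; y <- co[, "row"]
  cx <- mean(x); cy <- mean(y)
  cv <- stats::cov(cbind(x, y))
  e1 <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- (x - cx) * e1[1] + (y - cy) * e1[2]

  in_band <- band[component]
  side_a <- in_band & proj > 0
  side_b <- in_band & proj <= 0
  # a component too thin to have two distinct edge bands stays intact
  if (!any(side_a) || !any(side_b)) return(list(component))

  valid <- orient_valid(flow)[component]
  u <- flow$u[component]; v <- flow$v[component]
  ang <- wrap_angle(atan2(v, u))
  # magnitude-weighted circular mean: near-static aperture vectors along the
  # structure's long sides carry no direction information and must not vote
  wmean <- function(sel) {
    sel <- sel & valid
    if (sum(sel) < min_band_vectors) return(NA_real_)
    wrap_angle(atan2(sum(v[sel]), sum(u[sel])))
  }
  ma <- wmean(side_a)
  mb <- wmean(side_b)
  if (is.na(ma) || is.na(mb)) return(list(component))
  if (ang_dist(ma, mb) <= coherence_tol) return(list(component))

  # incoherent edges: cut along the internal boundary, located as the
  # 1D changepoint on the principal axis that best separates pixels whose
  # flow orientation is closer to one edge mean from those closer to the
  # other; pixels without trustworthy flow follow the cut by position
  # near the internal boundary the two motions blend inside the LK window
  # into weak or sideways vectors; only vectors aligned with one of the
  # edge motions vote on where the cut lies
  da <- ang_dist(ang, ma)
  db <- ang_dist(ang, mb)
  voter <- valid & pmin(da, db) <= pi / 4
  is_a <- da <= db
  ord <- order(proj)
  va <- (voter & is_a)[ord]
  vb <- (voter & !is_a)[ord]
  n <- length(component)
  # cost of cutting after position k, for either side assignment; the cut
  # sits at the centre of the minimizing plateau (the ambiguous zone)
  cost_low_a <- cumsum(vb) + (sum(va) - cumsum(va))
  cost_low_b <- cumsum(va) + (sum(vb) - cumsum(vb))
  pick <- function(cost) {
    km <- which(cost[-n] == min(cost[-n]))
    km[ceiling(length(km) / 2)]
  }
  k_a <- pick(cost_low_a)
  k_b <- pick(cost_low_b)
  k <- if (cost_low_a[k_a] <= cost_low_b[k_b]) k_a else k_b
  parts <- list(component[ord][seq_len(k)],
                component[ord][(k + 1L):n])
  parts
}

#' Segment the waves of a movie, frame by frame
#'
#' For each frame pair `t -> t + 1`: k-means bright mask on frame `t`,
#' intersection with the flow validity mask, 4-connected labelling,
#' removal of components below `min_size`, and flow-coherence division of
#' composite structures ([divide_structures()]).
#'
#' @param movie a `wave_movie`.
#' @param flows per-pair flow fields from [movie_flow()].
#' @param k intensity clusters for [bright_mask()].
#' @param min_size minimum component size (px).
#' @param coherence_tol see [divide_structures()].
#' @return list of `wave_mask_frame` objects (`labels` matrix with 0 =
#'   background, `frame_index`), one per flow field.
#' @export
segment_waves <- function(movie, flows, k = 3L, min_size = 9L,
                          coherence_tol = pi / 2) {
  stopifnot(inherits(movie, "wave_movie"), length(flows) >= 1L)
  lapply(seq_along(flows), function(t) {
    frame <- movie$frames[, , t]
    # a frame with fewer than k intensity levels holds no waves
    bm <- tryCatch(bright_mask(frame, k),
                   error = function(e) matrix(FALSE, nrow(frame), ncol(frame)))
    mm <- moving_mask(bm, flows[[t]])
    lab <- EBImage::bwlabel(mm)
    labels <- matrix(0L, nrow(frame), ncol(frame))
    nid <- 0L
    for (cid in seq_len(max(lab))) {
      comp <- which(lab == cid)
      if (length(comp) < min_size) next
      for (part in divide_structures(comp, flows[[t]],
                                     coherence_tol = coherence_tol,
                                     min_size = min_size)) {
        nid <- nid + 1L
        labels[part] <- nid
      }
    }
    structure(list(labels = labels, frame_index = t),
              class = "wave_mask_frame")
  })
}
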