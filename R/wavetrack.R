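# Multi-object wave tracking by mask overlap between consecutive frames,
# and per-track measurements (duration, area, speed, direction).

#' Link per-frame wave components into tracks by mask overlap
#'
#' A component at frame `t + 1` joins the track of the frame-`t` component
#' with which it shares the largest pixel overlap (at least 1 px).
#' Assignments are resolved greedily in decreasing overlap order, ties by
#' lower track id then lower component label, so that at a split the
#' largest fragment keeps the identity and the rest start new tracks, and
#' at a merge the largest contributor continues while the others terminate.
#' There is no gap closing: a track with no overlapping successor ends.
#'
#' @param frames list of `wave_mask_frame` objects from [segment_waves()],
#'   ordered by frame index.
#' @param pixel_size um/px.
#' @param frame_interval s.
#' @return list of `wave_track` objects: `id`, `frames` (indices), `masks`
#'   (per-frame linear pixel indices), `areas` (um^2 per frame), `duration`
#'   (s), `mean_area`, `max_area` (um^2), `centroid_path` (n x 2 matrix,
#'   um), `mean_direction` (rad, from the net centroid displacement; `NA`
#'   for single-frame tracks).
#' @export
link_by_overlap <- function(frames, pixel_size, frame_interval) {
  stopifnot(length(frames) >= 1L, pixel_size > 0, frame_interval > 0)
  dm <- dim(frames[[1]]$labels)
  tracks <- list()          # id -> list(frames, masks)
  active <- integer(0)      # component label (prev frame) -> track id

  comp_indices <- function(lab) {
    n <- max(lab)
    if (n == 0L) return(list())
    split(which(lab > 0L), lab[lab > 0L])[as.character(seq_len(n))]
  }

  prev_lab <- NULL
  for (f in seq_along(frames)) {
    lab <- frames[[f]]$labels
    comps <- comp_indices(lab)
    assign_track <- integer(length(comps))

    if (!is.null(prev_lab) && length(comps) > 0L && length(active) > 0L) {
      both <- prev_lab > 0L & lab > 0L
      if (any(both)) {
        ov <- table(prev = prev_lab[both], cur = lab[both])
        cand <- as.data.frame(ov, stringsAsFactors = FALSE)
        cand <- cand[cand$Freq > 0L, , drop = FALSE]
        cand$track <- active[as.integer(cand$prev)]
        cand <- cand[order(-cand$Freq, cand$track, as.integer(cand$cur)), ,
                     drop = FALSE]
        used_track <- integer(0)
        for (r in seq_len(nrow(cand))) {
          cur <- as.integer(cand$cur[r]); trk <- cand$track[r]
          if (assign_track[cur] == 0L && !(trk %in% used_track)) {
            assign_track[cur] <- trk
            used_track <- c(used_track, trk)
          }
        }
      }
    }

    new_active <- integer(length(comps))
    for (ci in seq_along(comps)) {
      trk <- assign_track[ci]
      if (trk == 0L) {
        tracks[[length(tracks) + 1L]] <- list(frames = integer(0),
                                              masks = list())
        trk <- length(tracks)
      }
      tracks[[trk]]$frames <- c(tracks[[trk]]$frames,
                                frames[[f]]$frame_index)
      tracks[[trk]]$masks[[length(tracks[[trk]]$masks) + 1L]] <- comps[[ci]]
      new_active[ci] <- trk
    }
    active <- new_active
    prev_lab <- lab
  }

  lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    areas <- vapply(tr$masks, length, integer(1)) * pixel_size^2
    cent <- t(vapply(tr$masks, function(idx) {
      co <- pixel_coords(idx, dm)
      c(mean(co[, "col"]), mean(co[, "row"])) * pixel_size
    }, numeric(2)))
    colnames(cent) <- c("x", "y")
    nfr <- length(tr$frames)
    dirn <- if (nfr >= 2L) {
      d <- cent[nfr, ] - cent[1L, ]
      wrap_angle(atan2(d[2], d[1]))
    } else NA_real_
    structure(
      list(id = i, frames = tr$frames, masks = tr$masks, areas = areas,
           duration = nfr * frame_interval,
           mean_area = mean(areas), max_area = max(areas),
           centroid_path = cent, mean_direction = dirn,
           pixel_size = pixel_size, frame_interval = frame_interval),
      class = "wave_track"
    )
  })
}

#' @export
print.wave_track <- function(x, ...) {
  cat(sprintf(
    "<wave_track> id %d, frames %d-%d, duration %.0f s, mean area %.2f um^2\n",
    x$id, x$frames[1], x$frames[length(x$frames)], x$duration, x$mean_area))
  invisible(x)
}

# split sorted angles into circular clusters whose internal gaps are
# <= tol; returns an integer cluster id per input angle
circ_clusters <- function(theta, tol) {
  n <- length(theta)
  if (n == 0L) return(integer(0))
  o <- order(theta)
  s <- theta[o]
  gaps <- c(diff(s), s[1] + 2 * pi - s[n])
  cl <- integer(n)
  brk <- which(gaps > tol)
  if (length(brk) == 0L) {
    cl[o] <- 1L
    return(cl)
  }
  # start a new cluster after each large gap; wrap-around joins ends
  ids <- integer(n)
  cur <- 1L
  for (i in seq_len(n)) {
    ids[i] <- cur
    if (i %in% brk) cur <- cur + 1L
  }
  if (!(n %in% brk)) ids[ids == max(ids)] <- 1L  # wrap join
  cl[o] <- as.integer(factor(ids))
  cl
}

#' Propagation speed of a tracked wave
#'
#' Within each frame of the track, reliable flow vectors inside the wave
#' mask are grouped into orientation clusters (circular single-linkage with
#' an angular gap tolerance). Cluster centroids are matched between
#' consecutive frames by nearest mean orientation (within the same
#' tolerance), and the speed is the median matched centroid displacement
#' per frame, converted to um/s.
#'
#' @param track a `wave_track`.
#' @param flows per-pair flow fields from [movie_flow()] (indexed by frame).
#' @param angle_tol angular tolerance for orientation clustering (rad).
#' @return speed in um/s, or `NA` for tracks shorter than 2 frames or with
#'   no matchable clusters.
#' @export
wave_speed <- function(track, flows, angle_tol = pi / 4) {
  stopifnot(inherits(track, "wave_track"))
  if (length(track$frames) < 2L) return(NA_real_)
  dm <- dim(flows[[1]]$u)

  frame_clusters <- lapply(seq_along(track$frames), function(k) {
    t <- track$frames[k]
    if (t > length(flows)) return(NULL)
    fl <- flows[[t]]
    idx <- track$masks[[k]]
    idx <- idx[orient_valid(fl)[idx]]
    if (length(idx) == 0L) return(NULL)
    th <- wrap_angle(atan2(fl$v[idx], fl$u[idx]))
    cl <- circ_clusters(th, angle_tol)
    co <- pixel_coords(idx, dm)
    lapply(unique(cl), function(ci) {
      sel <- cl == ci
      list(angle = circ_mean(th[sel]),
           centroid = c(mean(co[sel, "col"]), mean(co[sel, "row"])))
    })
  })

  disp <- numeric(0)
  for (k in seq_len(length(frame_clusters) - 1L)) {
    a <- frame_clusters[[k]]; b <- frame_clusters[[k + 1L]]
    if (is.null(a) || is.null(b)) next
    if (track$frames[k + 1L] != track$frames[k] + 1L) next
    max_jump <- flows[[track$frames[k]]]$max_disp
    for (ca in a) {
      dists <- vapply(b, function(cb) ang_dist(ca$angle, cb$angle), numeric(1))
      j <- which.min(dists)
      if (length(j) == 1L && dists[j] <= angle_tol) {
        d <- sqrt(sum((b[[j]]$centroid - ca$centroid)^2))
        # a cluster cannot move farther per frame than the flow can measure
        if (d <= max_jump) disp <- c(disp, d)
      }
    }
  }
  if (length(disp) == 0L) return(NA_real_)
  stats::median(disp) * track$pixel_size / track$frame_interval
}

#' Summary table of a set of tracks
#'
#' @param tracks list of `wave_track` objects.
#' @param flows optional flow fields; if supplied, a `speed` column is
#'   computed with [wave_speed()].
#' @return `data.frame` with one row per track: `id`, `birth` (s),
#'   `duration` (s), `mean_area`, `max_area` (um^2), `speed` (um/s or NA),
#'   `mean_direction` (rad), `centroid_x`, `centroid_y` (um).
#' @export
track_table <- function(tracks, flows = NULL) {
  if (length(tracks) == 0L) {
    return(data.frame(id = integer(0), birth = numeric(0),
                      duration = numeric(0), mean_area = numeric(0),
                      max_area = numeric(0), speed = numeric(0),
                      mean_direction = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0)))
  }
  data.frame(
    id = vapply(tracks, `[[`, integer(1), "id"),
    birth = vapply(tracks, function(tr) {
      (tr$frames[1] - 1) * tr$frame_interval
    }, numeric(1)),
    duration = vapply(tracks, `[[`, numeric(1), "duration"),
    mean_area = vapply(tracks, `[[`, numeric(1), "mean_area"),
    max_area = vapply(tracks, `[[`, numeric(1), "max_area"),
    speed = if (is.null(flows)) NA_real_ else
      vapply(tracks, wave_speed, numeric(1), flows = flows),
    mean_direction = vapply(tracks, `[[`, numeric(1), "mean_direction"),
    centroid_x = vapply(tracks, function(tr) mean(tr$centroid_path[, "x"]),
                        numeric(1)),
    centroid_y = vapply(tracks, function(tr) mean(tr$centroid_path[, "y"]),
                        numeric(1))
  )
}
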