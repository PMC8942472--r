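# Seeded synthetic fluorescence-movie generator with per-wave ground truth.
# Emulates cortical actin waves on flat substrates (band-like fronts that
# translate radially outward from their nucleation site) and on nanoridged
# substrates (quasi-1D streaks elongated along the ridge axis), with wave
# durations and areas tied together by the exponential minimum-area
# boundary of an excitable system near threshold.

#' Parameters of the synthetic wave-movie generator
#'
#' The generator nucleates waves at a Poisson rate inside a disk-shaped
#' cell mask, draws each wave's propagation direction from an antipodal
#' bimodal von Mises law, its speed from a truncated normal, its lifetime
#' from a geometric law on the frame grid (memoryless death, as for an
#' excitable patch dissipating with constant hazard), and its area from the
#' exponential minimum-area boundary `C * exp(duration / T)` times a
#' log-exponential scatter factor `>= 1`. Waves are rendered as moving
#' textured patches, blurred by a Gaussian point-spread function, and
#' corrupted by additive Gaussian camera noise on a constant background.
#'
#' @param surface `"flat"` (band-like fronts) or `"ridged"` (quasi-1D
#'   streaks along `ridge_axis`).
#' @param rows,cols grid size in pixels.
#' @param pixel_size um per pixel; the default 0.21 makes a 2 px kernel sd
#'   equal 0.42 um.
#' @param frame_interval seconds between frames (default 10 s, i.e. 0.1
#'   frames/s).
#' @param n_frames number of frames.
#' @param wave_rate expected nucleations per frame; the default keeps the
#'   wave occupancy of the frame in the several-percent range typical of
#'   giant-cell movies, which also anchors the data-adaptive optical-flow
#'   reliability cutoff (see [lk_params()]) well above the noise floor.
#' @param direction_law `c(mu1, kappa, p1)` of the antipodal bimodal von
#'   Mises law for propagation directions.
#' @param speed `c(mean, sd)` in um/s.
#' @param boundary_law `c(C, T)`: prefactor (um^2) and characteristic time
#'   (s) of the minimum-area boundary.
#' @param duration_mean_frames,duration_max_frames mean and cap of the
#'   geometric lifetime (frames).
#' @param area_scatter_rate rate of the exponential scatter of `log(area)`
#'   above the boundary; larger values hug the boundary more tightly.
#' @param ridge_axis ridge orientation (rad), used when `surface = "ridged"`.
#' @param ridge_spacing ridge pitch in um (default 1.6); ridged streaks
#'   nucleate with their axis on the ridge grid.
#' @param cell_center `c(x, y)` px, or `NULL` for the grid centre.
#' @param cell_radius px, or `NULL` for 0.42 of the smaller grid side.
#' @param background constant background level (camera counts).
#' @param signal wave amplitude above background (counts); the
#'   signal-to-background ratio is deliberately a free parameter.
#' @param noise_sd sd of the additive Gaussian noise (counts).
#' @param texture_amp relative amplitude of the static intensity texture
#'   carried by each wave (actin speckle); gives the interior of a wave
#'   trackable image structure.
#' @param texture_sigma correlation length (px, Gaussian sd) of the
#'   speckle texture.
#' @param psf_sigma sd (px) of the Gaussian point-spread function.
#' @param streak_width full width (px) of ridged streaks perpendicular to
#'   the ridge axis.
#' @param reversal `NULL`, or `list(frame, lag_new_frames, lag_old_frames)`:
#'   from `frame + lag` onward (lag depending on whether a wave nucleates in
#'   the half of the cell facing the new cathode or the old one), newly born
#'   waves draw their direction from the law with `mu1` rotated by `pi`.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(surface = c("flat", "ridged"),
                       rows = 192L, cols = 192L,
                       pixel_size = 0.21,
                       frame_interval = 10,
                       n_frames = 72L,
                       wave_rate = 1.2,
                       direction_law = c(mu1 = 0, kappa = 2, p1 = 0.7),
                       speed = c(mean = 0.04, sd = 0.008),
                       boundary_law = c(C = 2, T = 48),
                       duration_mean_frames = 4,
                       duration_max_frames = 10L,
                       area_scatter_rate = 6,
                       ridge_axis = 0,
                       ridge_spacing = 1.6,
                       cell_center = NULL,
                       cell_radius = NULL,
                       background = 500,
                       signal = 1500,
                       noise_sd = 50,
                       texture_amp = 0.2,
                       texture_sigma = 0.8,
                       psf_sigma = 1,
                       streak_width = 5L,
                       reversal = NULL,
                       seed = 1L) {
  surface <- match.arg(surface)
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  dl <- unname(direction_law)
  if (length(dl) != 3L || dl[2] < 0 || dl[3] < 0 || dl[3] > 1) {
    stop("`direction_law` must be c(mu1, kappa >= 0, p1 in [0, 1])")
  }
  bl <- unname(boundary_law)
  if (length(bl) != 2L || bl[1] <= 0 || bl[2] <= 0) {
    stop("`boundary_law` must be c(C > 0, T > 0)")
  }
  if (is.null(cell_center)) cell_center <- c((cols + 1) / 2, (rows + 1) / 2)
  if (is.null(cell_radius)) cell_radius <- 0.42 * min(rows, cols)
  if (!is.null(reversal)) {
    stopifnot(is.list(reversal),
              all(c("frame", "lag_new_frames", "lag_old_frames") %in%
                    names(reversal)))
  }
  structure(
    list(surface = surface, rows = as.integer(rows), cols = as.integer(cols),
         pixel_size = pixel_size, frame_interval = frame_interval,
         n_frames = as.integer(n_frames), wave_rate = wave_rate,
         direction_law = c(mu1 = dl[1], kappa = dl[2], p1 = dl[3]),
         speed = c(mean = unname(speed[1]), sd = unname(speed[2])),
         boundary_law = c(C = bl[1], T = bl[2]),
         duration_mean_frames = duration_mean_frames,
         duration_max_frames = as.integer(duration_max_frames),
         area_scatter_rate = area_scatter_rate,
         ridge_axis = ridge_axis, ridge_spacing = ridge_spacing,
         cell_center = cell_center, cell_radius = cell_radius,
         background = background, signal = signal, noise_sd = noise_sd,
         texture_amp = texture_amp, texture_sigma = texture_sigma,
         psf_sigma = psf_sigma,
         streak_width = as.integer(streak_width),
         reversal = reversal, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Construct a calibrated movie object
#'
#' @param frames numeric array `rows x cols x n_frames`.
#' @param pixel_size um/px.
#' @param frame_interval s.
#' @return object of class `wave_movie`.
#' @export
wave_movie <- function(frames, pixel_size, frame_interval) {
  stopifnot(length(dim(frames)) == 3L, pixel_size > 0, frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "wave_movie")
}

#' @export
print.wave_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<wave_movie> %d x %d px, %d frames, %.3g um/px, %.3g s/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

# geometric lifetime in frames, mean `mean_frames`, capped
draw_lifetimes <- function(n, mean_frames, max_frames) {
  pmin(1L + stats::rgeom(n, 1 / mean_frames), max_frames)
}

# areas (um^2) on/above the exponential boundary for given durations (s)
draw_areas <- function(duration_s, C, T, scatter_rate) {
  C * exp(duration_s / T) * exp(stats::rexp(length(duration_s), scatter_rate))
}

#' Synthetic wave population on the area-duration plane
#'
#' Draws `n_waves` (duration, area) pairs from the generator's lifetime and
#' boundary laws without rendering a movie: durations are multiples of the
#' frame interval and each area is the boundary value `C * exp(D / T)`
#' times a scatter factor `>= 1`, so the population's lower envelope traces
#' the boundary.
#'
#' @param params a [sim_params()] object (its `boundary_law`, lifetime law,
#'   and `seed` are used).
#' @param n_waves population size (>= 1).
#' @return `data.frame` with columns `duration` (s) and `area` (um^2).
#' @export
area_duration_population <- function(params, n_waves) {
  stopifnot(inherits(params, "sim_params"), n_waves >= 1)
  with_seed(params$seed, {
    dur <- draw_lifetimes(n_waves, params$duration_mean_frames,
                          params$duration_max_frames) * params$frame_interval
    area <- draw_areas(dur, params$boundary_law[["C"]],
                       params$boundary_law[["T"]], params$area_scatter_rate)
    data.frame(duration = dur, area = area)
  })
}

# pixel mask of an oriented rectangle: centre (x, y) px, half-length hl
# along `angle`, half-width hw across; returns linear indices plus local
# (par, perp) offsets for texture lookup
rect_mask <- function(center, hl, hw, angle, rows, cols) {
  e1 <- c(cos(angle), sin(angle))
  r <- ceiling(sqrt(hl^2 + hw^2)) + 1L
  x0 <- round(center[1]); y0 <- round(center[2])
  xs <- max(1L, x0 - r):min(cols, x0 + r)
  ys <- max(1L, y0 - r):min(rows, y0 + r)
  if (length(xs) == 0L || length(ys) == 0L) {
    return(list(idx = integer(0), dpar = numeric(0), dperp = numeric(0)))
  }
  dx <- rep(xs - x0, each = length(ys))
  dy <- rep(ys - y0, times = length(xs))
  dpar <- dx * e1[1] + dy * e1[2]
  dperp <- -dx * e1[2] + dy * e1[1]
  inside <- abs(dpar) <= hl & abs(dperp) <= hw
  rowi <- rep(ys, times = length(xs))[inside]
  coli <- rep(xs, each = length(ys))[inside]
  list(idx = (coli - 1L) * rows + rowi,
       dpar = dpar[inside], dperp = dperp[inside])
}

#' Generate a synthetic wave movie with ground truth
#'
#' Renders the process described in [sim_params()]: waves nucleate inside
#' the cell mask, translate at their drawn speed along their drawn
#' direction, keep a constant footprint whose pixel area is at least the
#' boundary-law value for their realized duration, and die either when
#' their drawn lifetime ends, when they would cross the cell boundary, or
#' at the end of the movie. The binary union of wave masks (carrying a
#' per-wave static speckle texture) is blurred with a Gaussian PSF, scaled
#' to the signal amplitude, added to the constant background, and corrupted
#' with additive Gaussian noise; frames are rounded to integer camera
#' counts in `[0, 65535]`.
#'
#' @param params a [sim_params()] object.
#' @return list of class `wave_sim` with elements
#'   \describe{
#'     \item{movie}{a `wave_movie`.}
#'     \item{truth}{ground truth: `waves` (data.frame: `id`, `birth`,
#'       `death`, `duration`, `direction`, `speed`, `area`, `front`),
#'       `masks` (per wave, a list of per-frame linear pixel indices),
#'       `union` (logical `rows x cols x n_frames` array), and
#'       `cell_mask` (logical matrix).}
#'   }
#' @export
generate_movie <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  rows <- p$rows; cols <- p$cols; nf <- p$n_frames
  xg <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  yg <- matrix(rep(seq_len(rows), times = cols), rows, cols)
  cell <- (xg - p$cell_center[1])^2 + (yg - p$cell_center[2])^2 <=
    p$cell_radius^2
  if (!any(cell)) stop("cell mask is empty")
  cell_idx <- which(cell)
  mu1 <- p$direction_law[["mu1"]]
  px_area <- p$pixel_size^2

  with_seed(p$seed, {
    # --- draw the wave population ---------------------------------------
    births <- rep(seq_len(nf), stats::rpois(nf, p$wave_rate))
    n <- length(births)
    waves <- list()
    id <- 0L
    for (i in seq_len(n)) {
      birth <- births[i]
      life <- draw_lifetimes(1L, p$duration_mean_frames, p$duration_max_frames)
      death <- min(birth + life - 1L, nf)
      dur <- (death - birth + 1L) * p$frame_interval
      area <- draw_areas(dur, p$boundary_law[["C"]], p$boundary_law[["T"]],
                         p$area_scatter_rate)
      target_px <- area / px_area

      # direction law, possibly reversed for late-born waves
      nuc <- cell_idx[sample.int(length(cell_idx), 1L)]
      nx <- ((nuc - 1L) %/% rows) + 1L
      ny <- ((nuc - 1L) %% rows) + 1L
      law_mu1 <- mu1
      front <- NA_character_
      if (!is.null(p$reversal)) {
        new_dir <- wrap_angle(mu1 + pi)
        side <- (nx - p$cell_center[1]) * cos(new_dir) +
          (ny - p$cell_center[2]) * sin(new_dir)
        front <- if (side >= 0) "new" else "old"
        lag <- if (front == "new") p$reversal$lag_new_frames else
          p$reversal$lag_old_frames
        if (birth >= p$reversal$frame + lag) law_mu1 <- new_dir
      }
      theta <- rbimodal_vm(1L, law_mu1, p$direction_law[["kappa"]],
                           p$direction_law[["p1"]])
      spd <- max(stats::rnorm(1, p$speed[["mean"]], p$speed[["sd"]]),
                 0.25 * p$speed[["mean"]])
      step <- spd * p$frame_interval / p$pixel_size  # px/frame

      # footprint: quasi-1D streak along the ridge axis, or a band-like
      # front elongated perpendicular to its propagation direction
      if (p$surface == "ridged") {
        W <- p$streak_width
        L <- max(W, ceiling(target_px / W))
        shape_angle <- p$ridge_axis
      } else {
        L <- max(3, ceiling(sqrt(3 * target_px)))
        W <- max(3, ceiling(target_px / L))
        shape_angle <- theta + pi / 2
      }
      if (L > min(rows, cols)) {
        stop(sprintf("wave dimensions (%d px) exceed the grid", L))
      }
      hw <- (W - 1) / 2 + 0.01
      hl0 <- (L - 1) / 2 + 0.01

      # nucleation position: retry until the footprint fits at birth;
      # on ridges, snap the streak axis onto the ridge grid
      pitch <- p$ridge_spacing / p$pixel_size
      snap <- function(pos) {
        if (p$surface != "ridged") return(pos)
        ep <- c(-sin(p$ridge_axis), cos(p$ridge_axis))
        dp <- sum((pos - p$cell_center) * ep)
        pos + (round(dp / pitch) * pitch - dp) * ep
      }
      # the footprint must fit inside the cell AND reach the boundary-law
      # pixel target, so no realized area dips below the boundary; the
      # half-length grows in half-pixel steps to absorb pixelation loss
      ok <- FALSE
      for (try in seq_len(100L)) {
        cen0 <- snap(c(nx, ny))
        hl <- hl0
        m <- rect_mask(cen0, hl, hw, shape_angle, rows, cols)
        while (length(m$idx) > 0L && all(cell[m$idx]) &&
               length(m$idx) < target_px && hl < hl0 + 6) {
          hl <- hl + 0.5
          m <- rect_mask(cen0, hl, hw, shape_angle, rows, cols)
        }
        if (length(m$idx) >= target_px && all(cell[m$idx])) {
          ok <- TRUE
          break
        }
        nuc <- cell_idx[sample.int(length(cell_idx), 1L)]
        nx <- ((nuc - 1L) %/% rows) + 1L
        ny <- ((nuc - 1L) %% rows) + 1L
      }
      if (!ok) next

      # static speckle texture in wave-local coordinates
      tex <- conv2_reflect(
        matrix(stats::rnorm((2 * ceiling(hl) + 5) * (2 * ceiling(hw) + 5)),
               2 * ceiling(hw) + 5, 2 * ceiling(hl) + 5),
        gauss_kernel2d(p$texture_sigma)
      )
      tex <- p$texture_amp * tex / max(stats::sd(tex), 1e-12)

      # walk the wave until drawn death or first boundary clip
      frames_alive <- integer(0)
      masks <- list()
      for (t in birth:death) {
        cen <- cen0 + step * (t - birth) * c(cos(theta), sin(theta))
        mt <- rect_mask(cen, hl, hw, shape_angle, rows, cols)
        if (length(mt$idx) < length(m$idx) || !all(cell[mt$idx])) break
        frames_alive <- c(frames_alive, t)
        masks[[length(masks) + 1L]] <- mt
      }
      if (length(frames_alive) == 0L) next
      id <- id + 1L
      waves[[id]] <- list(
        id = id, birth = frames_alive[1],
        death = frames_alive[length(frames_alive)],
        direction = theta, speed = spd,
        area = length(masks[[1]]$idx) * px_area,
        front = front, hl = hl, hw = hw, tex = tex, masks = masks
      )
    }

    # --- render ----------------------------------------------------------
    frames <- array(0, dim = c(rows, cols, nf))
    union <- array(FALSE, dim = c(rows, cols, nf))
    for (w in waves) {
      for (k in seq_along(w$masks)) {
        t <- w$birth + k - 1L
        m <- w$masks[[k]]
        ti <- round(m$dperp) + ceiling(w$hw) + 3L
        tj <- round(m$dpar) + ceiling(w$hl) + 3L
        val <- 1 + w$tex[cbind(ti, tj)]
        sl <- frames[, , t]
        sl[m$idx] <- pmax(sl[m$idx], val)
        frames[, , t] <- sl
        un <- union[, , t]
        un[m$idx] <- TRUE
        union[, , t] <- un
      }
    }
    for (t in seq_len(nf)) {
      sig <- if (any(frames[, , t] > 0)) {
        conv2_reflect(frames[, , t], gauss_kernel2d(p$psf_sigma))
      } else {
        frames[, , t]
      }
      img <- p$background + p$signal * sig
      if (p$noise_sd > 0) img <- img + stats::rnorm(rows * cols, 0, p$noise_sd)
      frames[, , t] <- pmin(pmax(round(img), 0), 65535)
    }

    truth_df <- if (id > 0L) {
      data.frame(
        id = vapply(waves, `[[`, integer(1), "id"),
        birth = vapply(waves, `[[`, integer(1), "birth"),
        death = vapply(waves, `[[`, integer(1), "death"),
        direction = vapply(waves, `[[`, numeric(1), "direction"),
        speed = vapply(waves, `[[`, numeric(1), "speed"),
        area = vapply(waves, `[[`, numeric(1), "area"),
        front = vapply(waves, function(w) as.character(w$front), character(1))
      )
    } else {
      data.frame(id = integer(0), birth = integer(0), death = integer(0),
                 direction = numeric(0), speed = numeric(0),
                 area = numeric(0), front = character(0))
    }
    truth_df$duration <- (truth_df$death - truth_df$birth + 1L) *
      p$frame_interval

    structure(
      list(
        movie = wave_movie(frames, p$pixel_size, p$frame_interval),
        truth = list(
          waves = truth_df,
          masks = lapply(waves, function(w) {
            stats::setNames(lapply(w$masks, `[[`, "idx"),
                            as.character(w$birth + seq_along(w$masks) - 1L))
          }),
          union = union,
          cell_mask = cell
        ),
        params = p
      ),
      class = "wave_sim"
    )
  })
}

#' @export
print.wave_sim <- function(x, ...) {
  cat(sprintf("<wave_sim> %s surface, %d waves, ", x$params$surface,
              nrow(x$truth$waves)))
  print(x$movie)
  invisible(x)
}
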