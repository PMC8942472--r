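# Circular statistics for wave directionality: the antipodal bimodal
# von Mises mixture, its maximum-likelihood fit, orientation kymographs,
# and reversal response times.

#' von Mises density
#'
#' `f(theta | mu, kappa) = exp(kappa * cos(theta - mu)) / (2 * pi * I0(kappa))`
#' where `I0` is the modified Bessel function of the first kind, order zero.
#' Evaluated with exponential scaling so large concentrations stay finite.
#'
#' @param theta angle(s), radians.
#' @param mu peak location, radians.
#' @param kappa concentration (>= 0); `kappa = 0` is the circular uniform.
#' @return density value(s).
#' @export
#' @examples
#' vm_pdf(0, 0, 0)            # 1 / (2 * pi)
#' integrate(vm_pdf, 0, 2 * pi, mu = 1, kappa = 2)
vm_pdf <- function(theta, mu, kappa) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  # log I0(kappa) = log(besselI(kappa, 0, expon.scaled)) + kappa
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  exp(kappa * cos(theta - mu) - log_i0) / (2 * pi)
}

# log-density of the antipodal mixture
# p1 * vM(mu1, kappa) + (1 - p1) * vM(mu1 + pi, kappa)
bimodal_vm_logpdf <- function(theta, mu1, kappa, p1) {
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  c1 <- kappa * cos(theta - mu1)
  # cos(theta - mu1 - pi) = -cos(theta - mu1)
  m <- pmax(c1, -c1)
  log(p1 * exp(c1 - m) + (1 - p1) * exp(-c1 - m)) + m - log_i0 - log(2 * pi)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampling; uses the current RNG stream so callers
#' control reproducibility via `set.seed()`.
#'
#' @param n sample size.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return angles in `[0, 2*pi)`.
#' @export
rvm <- function(n, mu, kappa) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (kappa < 1e-9) return(wrap_angle(stats::runif(n, 0, 2 * pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      u3 <- stats::runif(1)
      out[i] <- wrap_angle(sign(u3 - 0.5) * acos(f) + mu)
    }
  }
  out
}

#' Sample from the antipodal bimodal von Mises mixture
#'
#' @param n sample size.
#' @param mu1 first peak, radians; the second peak is `mu1 + pi`.
#' @param kappa shared concentration.
#' @param p1 proportion of the first component, in `[0, 1]`.
#' @return angles in `[0, 2*pi)`.
#' @export
rbimodal_vm <- function(n, mu1, kappa, p1) {
  if (p1 < 0 || p1 > 1) stop("`p1` must be in [0, 1]")
  comp1 <- stats::runif(n) < p1
  th <- rvm(n, mu1, kappa)
  wrap_angle(th + ifelse(comp1, 0, pi))
}

#' Fit the antipodal bimodal von Mises mixture by maximum likelihood
#'
#' Fits `p1 * vM(mu1, kappa) + p2 * vM(mu1 + pi, kappa)` with `p1 + p2 = 1`
#' and peaks constrained `pi` apart, to a set of flow-vector orientations.
#' The likelihood is maximized by bounded quasi-Newton ascent from a grid of
#' `n_starts` equally spaced `mu1` starting points (the bimodal surface has
#' local optima); the label convention `p1 >= p2` is enforced by swapping
#' components when needed.
#'
#' @param orientations angles, radians; at least 10 required.
#' @param n_starts number of `mu1` starting points.
#' @param kappa_max upper bound on the concentration.
#' @param window optional numeric length-2 `(start, end)` time in seconds,
#'   recorded in the result for bookkeeping.
#' @return object of class `vm_fit`: `mu1`, `mu2`, `kappa`, `p1`, `p2`,
#'   `loglik`, `n`, `window`.
#' @export
fit_bimodal_vm <- function(orientations, n_starts = 8L, kappa_max = 500,
                           window = c(NA_real_, NA_real_)) {
  th <- wrap_angle(as.numeric(orientations))
  th <- th[is.finite(th)]
  if (length(th) < 10L) {
    stop("need at least 10 orientations to fit the mixture")
  }
  negll <- function(par) {
    -sum(bimodal_vm_logpdf(th, par[1], par[2], par[3]))
  }
  # moment start for kappa from the axial (doubled-angle) resultant length
  rbar <- sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2)
  kappa0 <- min(max(
    if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
    else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
    else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar),
    0.01), kappa_max)

  best <- NULL
  for (mu0 in seq(0, 2 * pi, length.out = n_starts + 1L)[seq_len(n_starts)]) {
    for (p0 in c(0.5, 0.7)) {
      opt <- try(stats::optim(
        c(mu0, kappa0, p0), negll, method = "L-BFGS-B",
        lower = c(mu0 - pi, 0, 1e-9), upper = c(mu0 + pi, kappa_max, 1 - 1e-9)
      ), silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  if (is.null(best)) stop("mixture fit failed from every starting point")
  mu1 <- wrap_angle(best$par[1])
  kappa <- best$par[2]
  p1 <- best$par[3]
  if (p1 < 0.5) {            # label convention: first component dominates
    mu1 <- wrap_angle(mu1 + pi)
    p1 <- 1 - p1
  }
  structure(
    list(mu1 = mu1, mu2 = wrap_angle(mu1 + pi), kappa = kappa,
         p1 = p1, p2 = 1 - p1, loglik = -best$value,
         n = length(th), window = window),
    class = "vm_fit"
  )
}

#' Preferential direction of a fitted mixture
#'
#' The peak `mu` of the component with the larger proportion `p`; ties
#' return `mu1`.
#'
#' @param fit a `vm_fit`.
#' @return angle in radians.
#' @export
preferential_direction <- function(fit) {
  stopifnot(inherits(fit, "vm_fit"))
  if (fit$p1 >= fit$p2) fit$mu1 else fit$mu2
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf(
    "<vm_fit> mu1 = %.3f rad, kappa = %.3f, p1 = %.3f (n = %d, loglik = %.1f)\n",
    x$mu1, x$kappa, x$p1, x$n, x$loglik
  ))
  invisible(x)
}

#' Fit the direction mixture in disjoint time windows
#'
#' Pools the reliable flow orientations of each disjoint window of
#' `window` consecutive frame pairs (default 12 frames, i.e. 2 min at a
#' 10 s frame interval) and fits [fit_bimodal_vm()] to each. Windows with
#' fewer than 10 reliable vectors yield `NULL` entries.
#'
#' @param flows list of `flow_field`s as from [movie_flow()].
#' @param frame_interval seconds between frames.
#' @param window frames per window.
#' @param region optional logical matrix restricting vectors to a
#'   subcellular region.
#' @return list of `vm_fit` (or `NULL`) objects with their `window` slots
#'   set to `(start, end)` seconds.
#' @export
fit_direction_windows <- function(flows, frame_interval, window = 12L,
                                  region = NULL) {
  nw <- length(flows) %/% window
  if (nw < 1L) stop("movie shorter than one analysis window")
  lapply(seq_len(nw), function(i) {
    ix <- ((i - 1L) * window + 1L):(i * window)
    th <- unlist(lapply(flows[ix], flow_orientations, region = region))
    win <- c((ix[1] - 1L), ix[length(ix)]) * frame_interval
    if (length(th) < 10L) return(NULL)
    fit_bimodal_vm(th, window = win)
  })
}

#' Orientation kymograph of reliable flow vectors
#'
#' For each disjoint window of `window` frame pairs, the histogram of
#' reliable flow-vector orientations over `n_bins` equal bins covering
#' `[0, 2*pi)`, normalized to proportions. Rows of windows without any
#' reliable vector are `NA` and flagged invalid.
#'
#' @inheritParams fit_direction_windows
#' @param n_bins number of orientation bins (default 36, i.e. 10 degrees).
#' @return object of class `orientation_kymograph`: `time_bins` (window
#'   centers, s), `angle_bins` (bin edges, rad), `proportions`
#'   (time x angle matrix), `valid` (logical per row).
#' @export
orientation_kymograph <- function(flows, frame_interval, window = 12L,
                                  n_bins = 36L, region = NULL) {
  nw <- length(flows) %/% window
  if (nw < 1L) stop("movie shorter than one kymograph window")
  edges <- seq(0, 2 * pi, length.out = n_bins + 1L)
  prop <- matrix(NA_real_, nw, n_bins)
  centers <- numeric(nw)
  valid <- logical(nw)
  for (i in seq_len(nw)) {
    ix <- ((i - 1L) * window + 1L):(i * window)
    th <- unlist(lapply(flows[ix], flow_orientations, region = region))
    centers[i] <- mean(c(ix[1] - 1L, ix[length(ix)])) * frame_interval
    if (length(th) > 0L) {
      counts <- tabulate(pmin(findInterval(th, edges), n_bins), nbins = n_bins)
      prop[i, ] <- counts / sum(counts)
      valid[i] <- TRUE
    }
  }
  structure(
    list(time_bins = centers, angle_bins = edges, proportions = prop,
         valid = valid),
    class = "orientation_kymograph"
  )
}

#' Response time to a direction reversal
#'
#' The lag between `reversal_time` and the first window center at which the
#' preferential direction lies within `pi/2` of `new_direction` and stays
#' there for `persistence` consecutive windows.
#'
#' @param fits time-ordered list of `vm_fit` (or `NULL`) objects whose
#'   `window` slots are set (e.g. from [fit_direction_windows()]).
#' @param reversal_time seconds.
#' @param new_direction target direction, radians.
#' @param capture_tol angular capture tolerance (rad).
#' @param persistence number of consecutive captured windows required.
#' @return response time in seconds, or `NA` if the switch never happens.
#' @export
response_time <- function(fits, reversal_time, new_direction,
                          capture_tol = pi / 2, persistence = 2L) {
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  if (length(fits) == 0L) return(NA_real_)
  centers <- vapply(fits, function(f) mean(f$window), numeric(1))
  if (max(centers) <= reversal_time) {
    stop("fits do not span the reversal time")
  }
  pref <- vapply(fits, preferential_direction, numeric(1))
  captured <- ang_dist(pref, new_direction) <= capture_tol
  after <- which(centers > reversal_time)
  for (j in after) {
    run <- j:min(j + persistence - 1L, length(fits))
    if (length(run) == persistence && all(captured[run])) {
      return(centers[j] - reversal_time)
    }
  }
  NA_real_
}
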