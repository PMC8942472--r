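# Standard-format I/O: multi-page TIFF movies, CSV tables, JSON/YAML
# sidecars. All writers state the coordinate convention in a header
# comment where the format allows one.

#' Read a single-channel multi-page TIFF movie
#'
#' Accepts 8- or 16-bit unsigned single-channel stacks; pixel values are
#' returned as stored (integer counts). Pixels are assumed square.
#'
#' @param path TIFF file.
#' @param pixel_size um/px (isotropic). Supply a single value; anisotropic
#'   calibrations are rejected.
#' @param frame_interval s.
#' @return a `wave_movie`.
#' @export
read_movie_tiff <- function(path, pixel_size, frame_interval) {
  if (length(pixel_size) != 1L) {
    stop("anisotropic calibration is not supported: `pixel_size` must be a single value")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0L) stop("no pages in TIFF: ", path)
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L) {
      stop(sprintf("page %d of %s is multi-channel; expected single-channel",
                   i, path))
    }
    if (!all(dim(pg) == dim(pages[[1]]))) {
      stop(sprintf("page %d of %s has inconsistent dimensions", i, path))
    }
    if (any(pg != round(pg)) || min(pg) < 0) {
      stop(sprintf(
        "page %d of %s is not 8/16-bit unsigned integer data", i, path))
    }
  }
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  wave_movie(frames, pixel_size, frame_interval)
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Values are stored as 16-bit unsigned integers; frames must lie in
#' `[0, 65535]` (they are rounded). Reading the file back with
#' [read_movie_tiff()] reproduces the rounded pixel data exactly.
#'
#' @param movie a `wave_movie`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "wave_movie"))
  nf <- dim(movie$frames)[3]
  if (min(movie$frames) < 0 || max(movie$frames) > 65535) {
    stop("frame values must lie in [0, 65535] for 16-bit output")
  }
  pages <- lapply(seq_len(nf), function(t) round(movie$frames[, , t]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write per-frame label masks as a 16-bit multi-page TIFF
#'
#' @param frames list of `wave_mask_frame` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(frames, path) {
  pages <- lapply(frames, function(f) f$labels / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Export window-wise direction fits as CSV
#'
#' Columns: window start/end (s), `mu1`, `kappa`, `p1`, `loglik`, `n`.
#' Windows that could not be fitted are omitted.
#'
#' @param fits list of `vm_fit` (or `NULL`).
#' @param path output file.
#' @return the written `data.frame`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  keep <- !vapply(fits, is.null, logical(1))
  df <- do.call(rbind, lapply(fits[keep], function(f) {
    data.frame(window_start = f$window[1], window_end = f$window[2],
               mu1 = f$mu1, kappa = f$kappa, p1 = f$p1,
               loglik = f$loglik, n = f$n)
  }))
  if (is.null(df)) {
    df <- data.frame(window_start = numeric(0), window_end = numeric(0),
                     mu1 = numeric(0), kappa = numeric(0), p1 = numeric(0),
                     loglik = numeric(0), n = integer(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export an orientation kymograph as CSV
#'
#' One row per time window; first column the window centre (s), remaining
#' columns the orientation-bin proportions labelled by bin centre (rad).
#'
#' @param kymo an `orientation_kymograph`.
#' @param path output file.
#' @return the written `data.frame`, invisibly.
#' @export
write_kymograph_csv <- function(kymo, path) {
  nb <- ncol(kymo$proportions)
  centers <- (kymo$angle_bins[-(nb + 1L)] + kymo$angle_bins[-1L]) / 2
  df <- data.frame(time_s = kymo$time_bins, kymo$proportions)
  names(df)[-1] <- sprintf("angle_%.3f", centers)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
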