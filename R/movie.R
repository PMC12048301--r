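#' Optical movie container
#'
#' A 3-D stack of fluorescence (or voltage) frames with physical metadata.
#' Internal layout is `frames[row, col, time]`; physical coordinates are
#' `(index - 1) * dx_mm` at pixel centers.
#'
#' @param frames numeric array (rows x cols x time), finite
#' @param dx_mm pixel pitch, mm
#' @param frame_ms frame interval, ms
#' @param t0_ms time of the first frame, ms
#' @return object of class `vf_movie`
#' @export
vf_movie <- function(frames, dx_mm, frame_ms, t0_ms = 0) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2,
            dx_mm > 0, frame_ms > 0)
  structure(list(frames = frames, dx_mm = dx_mm, frame_ms = frame_ms,
                 t0_ms = t0_ms), class = "vf_movie")
}

#' @export
print.vf_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<vf_movie> %d x %d px (%.2f mm), %d frames @ %g ms, t0 = %g ms\n",
              d[1], d[2], x$dx_mm, d[3], x$frame_ms, x$t0_ms))
  invisible(x)
}

#' Frame times of a movie
#' @param movie `vf_movie`
#' @return numeric vector of frame times, ms
#' @export
movie_times <- function(movie) {
  movie$t0_ms + (seq_len(dim(movie$frames)[3]) - 1) * movie$frame_ms
}

#' Fluorescence acquisition model
#'
#' Parameters of the camera/dye forward model applied to the voltage movie:
#' spatial blur (optics and dye diffusion), additive white noise, slow
#' multiplicative amplitude rundown (photobleaching under continuous
#' illumination), and a fraction of dead pixels carrying noise only.
#'
#' @param frame_ms frame interval, ms (<= 2 ms)
#' @param blur_sigma_px Gaussian blur sigma, pixels
#' @param noise_sd additive noise sd, fraction of the AP amplitude
#' @param rundown_per_min fractional amplitude loss per minute, in [0, 1)
#' @param dead_pixel_frac fraction of pixels replaced by noise only
#' @return list of class `vf_acq`
#' @export
acquisition_model <- function(frame_ms = 1, blur_sigma_px = 0.75,
                              noise_sd = 0.02, rundown_per_min = 0.05,
                              dead_pixel_frac = 0.01) {
  stopifnot(frame_ms > 0, frame_ms <= 2, blur_sigma_px >= 0, noise_sd >= 0,
            rundown_per_min >= 0, rundown_per_min < 1,
            dead_pixel_frac >= 0, dead_pixel_frac < 1)
  structure(list(frame_ms = frame_ms, blur_sigma_px = blur_sigma_px,
                 noise_sd = noise_sd, rundown_per_min = rundown_per_min,
                 dead_pixel_frac = dead_pixel_frac), class = "vf_acq")
}

#' Render a fluorescence movie from a voltage movie
#'
#' Applies, in order: per-frame Gaussian blur, min-max amplitude
#' normalization taken from the early part of the recording, multiplicative
#' rundown over time, additive white noise, and dead pixels (noise only).
#'
#' @param vmovie voltage `vf_movie` (finite values)
#' @param acq `vf_acq`
#' @param seed RNG seed for noise and dead-pixel placement
#' @return fluorescence `vf_movie`; attributes `dead_mask` (logical matrix)
#'   and `acq` record the acquisition truth
#' @export
render_fluorescence <- function(vmovie, acq = acquisition_model(), seed = 1) {
  stopifnot(inherits(vmovie, "vf_movie"), all(is.finite(vmovie$frames)))
  set.seed(seed)
  fr <- vmovie$frames
  d <- dim(fr)
  if (acq$blur_sigma_px > 0)
    fr <- EBImage::gblur(fr, sigma = acq$blur_sigma_px,
                         boundary = "replicate")
  rng <- range(fr)
  if (diff(rng) < .Machine$double.eps) {
    fr[] <- 0
  } else {
    fr <- (fr - rng[1]) / (rng[2] - rng[1])
  }
  if (acq$rundown_per_min > 0) {
    tmin <- movie_times(vmovie) / 60000
    gain <- (1 - acq$rundown_per_min)^tmin
    fr <- sweep(fr, 3, gain, "*")
  }
  dead <- matrix(FALSE, d[1], d[2])
  if (acq$dead_pixel_frac > 0) {
    ndead <- round(acq$dead_pixel_frac * d[1] * d[2])
    dead[sample.int(d[1] * d[2], ndead)] <- TRUE
    fr[rep(dead, d[3])] <- 0
  }
  if (acq$noise_sd > 0)
    fr <- fr + array(rnorm(length(fr), sd = acq$noise_sd), dim = d)
  out <- vf_movie(fr, dx_mm = vmovie$dx_mm, frame_ms = vmovie$frame_ms,
                  t0_ms = vmovie$t0_ms)
  attr(out, "dead_mask") <- dead
  attr(out, "acq") <- acq
  out
}

#' Compute the pseudo-ECG from a voltage movie
#'
#' Infinite-volume-conductor forward model: at each frame the signal is
#' `sum over pixels of grad(V) . grad(1/r) * dA`, with `r` the distance
#' from the pixel to the electrode. Units are arbitrary; the trace is
#' baseline-zeroed (median subtracted).
#'
#' @param vmovie voltage `vf_movie`
#' @param electrode_mm numeric length-3: electrode position
#'   (row mm, col mm, height mm above the tissue plane). Default: above the
#'   center of the mapped field at 8 mm standoff — a bath electrode close
#'   to the epicardium over the region of interest, which keeps every
#'   border-zone ectopic in the electrode's near field so its deflection
#'   is seen without the far-field growth delay of a distant electrode.
#' @return object of class `vf_ecg`: list with `time_ms`, `amp`, `dt_ms`,
#'   `pacing` (empty; attach with [attach_pacing()])
#' @export
compute_pseudo_ecg <- function(vmovie, electrode_mm = NULL) {
  stopifnot(inherits(vmovie, "vf_movie"))
  d <- dim(vmovie$frames)
  dx <- vmovie$dx_mm
  if (is.null(electrode_mm))
    electrode_mm <- c(0.5 * (d[1] - 1) * dx, 0.5 * (d[2] - 1) * dx, 8)
  stopifnot(length(electrode_mm) == 3)
  rowmm <- (seq_len(d[1]) - 1) * dx
  colmm <- (seq_len(d[2]) - 1) * dx
  R <- matrix(rowmm, d[1], d[2])
  C <- matrix(colmm, d[1], d[2], byrow = TRUE)
  dr <- R - electrode_mm[1]; dc <- C - electrode_mm[2]; dz <- -electrode_mm[3]
  r <- sqrt(dr^2 + dc^2 + dz^2)
  if (any(r < dx / 2))
    stop("electrode coincides with a tissue pixel (r = 0)")
  lead_gr <- -dr / r^3
  lead_gc <- -dc / r^3
  amp <- pseudo_ecg_cpp(vmovie$frames, d[1], d[2], lead_gr, lead_gc, dx)
  amp <- amp - median(amp)
  structure(list(time_ms = movie_times(vmovie), amp = amp,
                 dt_ms = vmovie$frame_ms,
                 pacing = data.frame(time_ms = numeric(0),
                                     kind = character(0),
                                     cycle_ms = numeric(0))),
            class = "vf_ecg")
}

#' Attach a pacing-event log to an ECG record
#' @param ecg `vf_ecg`
#' @param pacing_log data.frame with `time_ms`, `kind`
#'   ("paced"/"intrinsic"/"extra"), `cycle_ms`
#' @return the ECG with the log attached (sorted by time)
#' @export
attach_pacing <- function(ecg, pacing_log) {
  stopifnot(inherits(ecg, "vf_ecg"),
            all(c("time_ms", "kind") %in% names(pacing_log)))
  ecg$pacing <- pacing_log[order(pacing_log$time_ms), , drop = FALSE]
  ecg
}

#' @export
print.vf_ecg <- function(x, ...) {
  cat(sprintf("<vf_ecg> %d samples @ %g ms (%.1f s), %d pacing events\n",
              length(x$amp), x$dt_ms, diff(range(x$time_ms)) / 1000,
              nrow(x$pacing)))
  invisible(x)
}
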