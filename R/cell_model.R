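#' Ionic parameters of the two-variable excitable-medium model
#'
#' The tissue model is a two-current (inward/outward) excitable medium with a
#' single recovery gate. The inward current is gated by `h` and regenerative
#' in `v`; the outward current is a linear leak. The gate reopens with time
#' constant `tau_open` below `v_gate` and closes with `tau_close` above it.
#' Local action potential duration is controlled almost linearly by
#' `tau_close`, which is what the lesion model scales per pixel.
#'
#' The default `tau_close` is calibrated so that a single cell paced at a
#' 500-ms cycle has an APD80 of ~240 ms, a typical epicardial value for the
#' porcine right ventricle at slow rates.
#'
#' @param tau_in inward (depolarizing) time constant, ms
#' @param tau_out outward (repolarizing) time constant, ms
#' @param tau_open gate reopening time constant, ms
#' @param tau_close gate closing time constant, ms (sets APD)
#' @param v_gate gate threshold on the normalized membrane variable
#' @return a list of class `vf_ionic`
#' @export
ionic_params <- function(tau_in = 0.3, tau_out = 6, tau_open = 120,
                         tau_close = 135.04, v_gate = 0.13) {
  stopifnot(tau_in > 0, tau_out > 0, tau_open > 0, tau_close > 0,
            v_gate > 0, v_gate < 1)
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, v_gate = v_gate),
            class = "vf_ionic")
}

#' Single-cell (0-D) run of the ionic model
#'
#' Forward-Euler integration of the space-clamped model under pacing.
#' Used to tabulate the APD-versus-`tau_close` calibration curve and as the
#' independent oracle for the lesion field inversion.
#'
#' @param ionic `vf_ionic` parameters
#' @param scale multiplier applied to `tau_close` (the lesion scaling)
#' @param cycle_ms pacing cycle length
#' @param n_beats number of paced beats
#' @param dt_ms integration step
#' @param stim_dur_ms,stim_amp stimulus duration and amplitude
#' @return list with `time_ms`, `v` (trace) and `dt_ms`
#' @export
cell_run <- function(ionic = ionic_params(), scale = 1, cycle_ms = 500,
                     n_beats = 3, dt_ms = 0.05, stim_dur_ms = 1,
                     stim_amp = 0.6) {
  stopifnot(scale > 0)
  tau_close <- ionic$tau_close * scale
  nsteps <- round((cycle_ms * n_beats + 100) / dt_ms)
  v <- numeric(nsteps + 1)
  h <- 1
  vv <- 0
  stim_start <- (seq_len(n_beats) - 1) * cycle_ms + 5
  for (k in seq_len(nsteps)) {
    t <- (k - 1) * dt_ms
    stim <- if (any(t >= stim_start & t < stim_start + stim_dur_ms)) stim_amp else 0
    dv <- h * vv^2 * (1 - vv) / ionic$tau_in - vv / ionic$tau_out + stim
    hn <- if (vv < ionic$v_gate) h + dt_ms * (1 - h) / ionic$tau_open
          else h - dt_ms * h / tau_close
    vv <- vv + dt_ms * dv
    h <- min(1, max(0, hn))
    v[k + 1] <- vv
  }
  list(time_ms = seq(0, by = dt_ms, length.out = nsteps + 1), v = v,
       dt_ms = dt_ms, stim_start_ms = stim_start)
}

#' APD80 of a 0-D voltage trace
#'
#' Activation = upward crossing of 50 % of the unit amplitude; APD80 = time
#' until the trace falls back below 20 %, linearly interpolated.
#'
#' @param run output of [cell_run()]
#' @param beat which beat to measure (default: last complete one)
#' @return APD80 in ms (NA if the beat never repolarized)
#' @export
cell_apd80 <- function(run, beat = NULL) {
  v <- run$v
  t <- run$time_ms
  up <- which(v[-length(v)] < 0.5 & v[-1] >= 0.5)
  dn <- which(v[-length(v)] >= 0.2 & v[-1] < 0.2)
  if (length(up) == 0) return(NA_real_)
  if (is.null(beat)) beat <- length(up)
  if (beat > length(up)) return(NA_real_)
  iu <- up[beat]
  t_at <- t[iu] + run$dt_ms * (0.5 - v[iu]) / (v[iu + 1] - v[iu])
  dn <- dn[dn > iu]
  if (length(dn) == 0) return(NA_real_)
  id <- dn[1]
  t_dn <- t[id] + run$dt_ms * (v[id] - 0.2) / (v[id] - v[id + 1])
  t_dn - t_at
}

#' Tabulate the APD80-versus-scaling calibration curve
#'
#' Runs the single-cell model over a grid of `tau_close` scalings and
#' returns a monotone lookup table used to invert target APD80 values into
#' per-pixel scalings. Cached per parameter set within a session.
#'
#' @param ionic `vf_ionic` parameters
#' @param scales scaling grid (dimensionless, in (0, 1.5])
#' @param cycle_ms pacing cycle length used for calibration
#' @return data.frame with columns `scale` and `apd80_ms`, increasing in both
#' @export
apd_calibration <- function(ionic = ionic_params(),
                            scales = seq(0.25, 1.3, by = 0.05),
                            cycle_ms = 500) {
  key <- paste(signif(unlist(ionic), 10), collapse = "_")
  key <- paste(key, paste(signif(scales, 8), collapse = ","), cycle_ms, sep = "|")
  hit <- .vf_cache$calib[[key]]
  if (!is.null(hit)) return(hit)
  apd <- vapply(scales, function(s)
    cell_apd80(cell_run(ionic, scale = s, cycle_ms = cycle_ms)), numeric(1))
  ok <- is.finite(apd)
  tab <- data.frame(scale = scales[ok], apd80_ms = apd[ok])
  tab <- tab[order(tab$scale), ]
  if (any(diff(tab$apd80_ms) <= 0))
    stop("calibration curve not monotone; refine the scaling grid")
  .vf_cache$calib[[key]] <- tab
  tab
}

#' Invert the calibration curve: target APD80 -> tau_close scaling
#'
#' @param apd80_ms vector of target APD80 values (ms)
#' @param calib calibration table from [apd_calibration()]
#' @return scaling values; errors if a target leaves the calibrated range
#' @export
scale_for_apd <- function(apd80_ms, calib) {
  rng <- range(calib$apd80_ms)
  bad <- apd80_ms < rng[1] - 1e-9 | apd80_ms > rng[2] + 1e-9
  if (any(bad))
    stop(sprintf("target APD80 outside calibrated range [%.1f, %.1f] ms",
                 rng[1], rng[2]))
  approx(calib$apd80_ms, calib$scale, xout = apd80_ms, rule = 1)$y
}

.vf_cache <- new.env(parent = emptyenv())
.vf_cache$calib <- list()
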