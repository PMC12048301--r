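#' Parameters of the map-extraction stage
#'
#' @param baseline_win_ms chunk length for the sliding-percentile baseline
#' @param baseline_q percentile used as the running baseline
#' @param snr_min validity gate: beat amplitude / diastolic noise sd must be
#'   at least this (mirrors the exclusion of "noisy" pixels on published
#'   APD maps, without claiming the original rule)
#' @param at_method activation-time convention: `"max_deriv"` (time of the
#'   maximum positive temporal derivative, the dominant optical-mapping
#'   convention; default) or `"half_amp"` (50 % upstroke crossing)
#' @param deriv_frac candidate upstrokes are local derivative maxima above
#'   this fraction of the window's maximum derivative
#' @param min_upstroke minimum normalized amplitude an upstroke must reach
#'   (within 100 ms) to count as an activation
#' @param min_window_amp_frac a beat window is valid only if its amplitude
#'   is at least this fraction of the trace's overall AP amplitude — a
#'   window that catches only the falling repolarization tail of the
#'   previous beat (no true upstroke) would otherwise be renormalized to
#'   noise
#' @param apd_level repolarization level for APD (0.8 = APD80)
#' @param smooth_temporal apply a light Savitzky-Golay polynomial filter
#'   before differentiation (on by default; oracle tests on noiseless data
#'   disable it)
#' @param sg_width_ms width of the temporal filter
#' @return list of class `vf_map_params`
#' @export
map_params <- function(baseline_win_ms = 500, baseline_q = 0.1,
                       snr_min = 5, at_method = c("max_deriv", "half_amp"),
                       deriv_frac = 0.3, min_upstroke = 0.4,
                       min_window_amp_frac = 0.5,
                       apd_level = 0.8, smooth_temporal = TRUE,
                       sg_width_ms = 7) {
  at_method <- match.arg(at_method)
  structure(list(baseline_win_ms = baseline_win_ms, baseline_q = baseline_q,
                 snr_min = snr_min, at_method = at_method,
                 deriv_frac = deriv_frac, min_upstroke = min_upstroke,
                 min_window_amp_frac = min_window_amp_frac,
                 apd_level = apd_level, smooth_temporal = smooth_temporal,
                 sg_width_ms = sg_width_ms),
            class = "vf_map_params")
}

#' Condition a single-pixel optical trace
#'
#' Removes slow baseline drift (sliding-percentile subtraction), corrects
#' polarity so depolarization is positive, and — when beat windows are
#' supplied — renormalizes each beat window to [0, 1] using its own
#' diastolic baseline and peak. An all-constant or low-SNR trace is flagged
#' invalid rather than raising an error.
#'
#' @param trace numeric vector of fluorescence samples
#' @param frame_ms frame interval, ms
#' @param windows optional data.frame with `start_ms`, `end_ms` per beat
#' @param params [map_params()]
#' @param t0_ms time of the first sample
#' @return object of class `vf_trace`: list with the conditioned samples
#'   `x`, `frame_ms`, `t0_ms`, `valid`, `amplitude`, `noise_sd`, `windows`
#'   (with per-window validity and scaling)
#' @export
condition_trace <- function(trace, frame_ms, windows = NULL,
                            params = map_params(), t0_ms = 0) {
  n <- length(trace)
  x <- as.numeric(trace)
  # polarity first: depolarization is much steeper than repolarization,
  # so the extreme positive and negative slopes are asymmetric in a way
  # that does not depend on the action potential's duty cycle (a median-
  # or percentile-based rule would flip short windows dominated by the
  # plateau)
  if (n > 3) {
    dxx <- x[-1] - x[-n]
    if (max(dxx) + min(dxx) < 0) x <- -x
  }
  # running-percentile baseline over half-overlapping chunks
  w <- max(3L, round(params$baseline_win_ms / frame_ms))
  starts <- unique(pmin(seq(1L, n, by = max(1L, w %/% 2L)), n - 1L))
  mids <- pmin(starts + w %/% 2L, n)
  bl <- vapply(starts, function(s)
    quantile7(x[s:min(n, s + w - 1L)], params$baseline_q), numeric(1))
  base <- approx(mids, bl, xout = seq_len(n), rule = 2)$y
  x <- x - base
  lo <- quantile7(x, 0.02); hi <- quantile7(x, 0.98)
  dx <- abs(x[-1] - x[-n])
  noise_sd <- 1.4826 * median(dx) / sqrt(2)
  amplitude <- hi - lo
  valid <- is.finite(amplitude) && amplitude > 0 &&
    (noise_sd == 0 || amplitude / noise_sd >= params$snr_min)

  wins <- NULL
  if (!is.null(windows) && nrow(windows) > 0) {
    nw <- nrow(windows)
    wvalid <- logical(nw); wbase <- rep(NA_real_, nw); wamp <- rep(NA_real_, nw)
    i0 <- pmax(1L, ceiling((windows$start_ms - t0_ms) / frame_ms) + 1L)
    i1 <- pmin(n, floor((windows$end_ms - t0_ms) / frame_ms) + 1L)
    for (k in seq_len(nw)) {
      if (i1[k] - i0[k] < 2L) next
      idx <- i0[k]:i1[k]
      nb <- max(3L, min(round(50 / frame_ms), length(idx) %/% 4L))
      b <- median(x[idx[seq_len(nb)]])
      a <- max(x[idx]) - b
      ok <- is.finite(a) && a > 0 &&
        (noise_sd == 0 || a / noise_sd >= params$snr_min) &&
        a >= params$min_window_amp_frac * amplitude
      if (ok) x[idx] <- (x[idx] - b) / a
      wvalid[k] <- ok; wbase[k] <- b; wamp[k] <- a
    }
    wins <- windows
    wins$valid <- wvalid; wins$base <- wbase; wins$amp <- wamp
  }
  structure(list(x = x, frame_ms = frame_ms, t0_ms = t0_ms, valid = valid,
                 amplitude = amplitude, noise_sd = noise_sd, windows = wins),
            class = "vf_trace")
}

#' Exact type-7 sample quantile via partial sorting
#' @keywords internal
quantile7 <- function(v, q) {
  n <- length(v)
  if (n == 0) return(NA_real_)
  h <- (n - 1) * q + 1
  fl <- floor(h)
  up <- min(fl + 1, n)
  s <- sort.int(v, partial = unique(c(fl, up)))
  s[fl] + (h - fl) * (s[up] - s[fl])
}

#' Savitzky-Golay smoothing with a cached symmetric FIR kernel
#' (interior samples only; edges keep the raw values)
#' @keywords internal
sg_smooth <- function(x, frame_ms, width_ms, p = 3) {
  wl <- max(5L, round(width_ms / frame_ms))
  if (wl %% 2L == 0L) wl <- wl + 1L
  if (length(x) <= wl) return(x)
  key <- paste0("sg_", p, "_", wl)
  coef <- .vf_cache$calib[[key]]
  if (is.null(coef)) {
    coef <- signal::sgolay(p = p, n = wl)[(wl + 1) %/% 2, ]
    .vf_cache$calib[[key]] <- coef
  }
  y <- stats::filter(x, coef, sides = 2)
  y <- as.numeric(y)
  bad <- is.na(y)
  y[bad] <- x[bad]
  y
}

#' @keywords internal
window_index <- function(ct, window) {
  tt <- ct$t0_ms + (seq_along(ct$x) - 1) * ct$frame_ms
  which(tt >= window[1] & tt <= window[2])
}

#' Detect the activation time within a beat window
#'
#' Default convention: among candidate upstrokes (local maxima of the
#' temporal derivative above `deriv_frac` of the window maximum, each
#' required to reach `min_upstroke` of the normalized amplitude within
#' 100 ms), the earliest qualifying one is taken and its derivative peak is
#' refined by parabolic interpolation between samples. Returns `NA` when no
#' upstroke qualifies (flat or sub-threshold window).
#'
#' @param ct `vf_trace` (normalized within the window)
#' @param window numeric length-2 (ms)
#' @param params [map_params()]
#' @return activation time in ms, or `NA`
#' @export
detect_activation <- function(ct, window, params = map_params()) {
  idx <- window_index(ct, window)
  if (length(idx) < 5 || !ct$valid) return(NA_real_)
  x <- ct$x[idx]
  dtms <- ct$frame_ms
  if (params$smooth_temporal) x <- sg_smooth(x, dtms, params$sg_width_ms)
  d <- diff(x) / dtms
  if (all(!is.finite(d)) || max(d) <= 0) return(NA_real_)
  thr <- params$deriv_frac * max(d)
  # local maxima of the derivative above threshold, in time order
  cand <- which(d >= thr &
                d >= c(-Inf, d[-length(d)]) &
                d >= c(d[-1], -Inf))
  if (length(cand) == 0) return(NA_real_)
  look <- max(2L, round(30 / dtms))
  for (c0 in cand) {
    # rise relative to the candidate's own level, over a short look-ahead:
    # a noise blip ahead of the true upstroke must not inherit its rise
    reach <- max(x[c0:min(length(x), c0 + look)])
    if (reach - x[c0] >= params$min_upstroke) {
      if (params$at_method == "half_amp") {
        base_lvl <- quantile(x, 0.05, names = FALSE)
        lvl <- base_lvl + 0.5 * (max(x) - base_lvl)
        up <- which(x[-length(x)] < lvl & x[-1] >= lvl)
        up <- up[up >= c0 - look]
        if (length(up) == 0) return(NA_real_)
        i <- up[1]
        frac <- (lvl - x[i]) / (x[i + 1] - x[i])
        tt0 <- ct$t0_ms + (idx[1] - 1) * dtms
        return(tt0 + (i - 1 + frac) * dtms)
      }
      off <- 0
      if (c0 > 1 && c0 < length(d)) {
        den <- d[c0 - 1] - 2 * d[c0] + d[c0 + 1]
        if (abs(den) > .Machine$double.eps)
          off <- 0.5 * (d[c0 - 1] - d[c0 + 1]) / den
        off <- max(-0.5, min(0.5, off))
      }
      tt0 <- ct$t0_ms + (idx[1] - 1) * dtms
      # derivative sample c0 sits between samples c0 and c0+1
      return(tt0 + (c0 - 0.5 + off) * dtms)
    }
  }
  NA_real_
}

#' Measure the action potential duration at a repolarization level
#'
#' APD = first time after the AP peak at which the signal falls to
#' `(1 - level)` of the beat amplitude above the diastolic baseline, minus
#' the activation time; linearly interpolated between samples. `NA` when
#' repolarization is not reached before the window end.
#'
#' @param ct `vf_trace` (normalized within the window)
#' @param at activation time from [detect_activation()] (ms)
#' @param window numeric length-2 (ms)
#' @param level repolarization level (default 0.8 for APD80)
#' @param params [map_params()]
#' @return APD in ms, or `NA`
#' @export
measure_apd <- function(ct, at, window, level = NULL,
                        params = map_params()) {
  if (is.na(at)) return(NA_real_)
  if (is.null(level)) level <- params$apd_level
  stopifnot(level > 0, level <= 1)
  idx <- window_index(ct, window)
  if (length(idx) < 5) return(NA_real_)
  x <- ct$x[idx]
  dtms <- ct$frame_ms
  tt <- ct$t0_ms + (idx - 1) * dtms
  nb <- max(3L, min(round(50 / dtms), length(idx) %/% 4L))
  base <- median(x[seq_len(nb)])
  after <- which(tt >= at)
  if (length(after) < 3) return(NA_real_)
  pk <- after[which.max(x[after])]
  amp <- x[pk] - base
  if (!is.finite(amp) || amp <= 0) return(NA_real_)
  target <- base + (1 - level) * amp
  seg <- if (pk < length(x)) seq(pk, length(x) - 1L) else integer(0)
  dn <- seg[x[seg] >= target & x[seg + 1L] < target]
  if (length(dn) == 0) {
    # level = 1 means full return to baseline; accept a touch of the target
    if (level >= 1) {
      eq <- seg[x[seg + 1L] <= target + 1e-12]
      if (length(eq) > 0) return(tt[eq[1] + 1L] - at)
    }
    return(NA_real_)
  }
  i <- dn[1]
  frac <- (x[i] - target) / (x[i] - x[i + 1L])
  tt[i] + frac * dtms - at
}

#' A per-pixel scalar map with validity mask
#'
#' @param values numeric matrix (ms or ms/mm)
#' @param valid logical matrix, same shape
#' @param kind one of "AT", "APD80", "RT", "gradient"
#' @param dx_mm pixel pitch
#' @param beat source beat index (optional)
#' @return object of class `vf_map`; invalid pixels carry `NA`
#' @export
vf_map <- function(values, valid, kind, dx_mm, beat = NA_integer_) {
  stopifnot(is.matrix(values), identical(dim(values), dim(valid)))
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, kind = kind,
                 dx_mm = dx_mm, beat = beat), class = "vf_map")
}

#' @export
print.vf_map <- function(x, ...) {
  cat(sprintf("<vf_map %s> %d x %d px, %.1f%% valid, range [%.1f, %.1f]\n",
              x$kind, nrow(x$values), ncol(x$values), 100 * mean(x$valid),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Build AT / APD80 / RT maps for each beat window
#'
#' Runs the full per-pixel chain (conditioning, activation detection, APD
#' measurement) and assembles, per beat window, an activation-time map, an
#' APD80 map and a repolarization-time map with a shared validity mask.
#' RT = AT + APD80 holds exactly, pixel-wise, by construction. Pixels whose
#' trace fails the SNR gate or where AT or APD cannot be measured are
#' masked (the "noisy" pixels of published maps).
#'
#' @param movie `vf_movie`
#' @param windows data.frame with `start_ms`, `end_ms` (and optionally
#'   `label`), non-overlapping and sorted
#' @param params [map_params()]
#' @param fast use the compiled per-pixel chain (identical results; the
#'   interpreted reference path is kept for the `"half_amp"` convention
#'   and is held equal to the compiled one by an equivalence test)
#' @return list (one element per beat window) of lists with `at`, `apd80`,
#'   `rt` (`vf_map`s) and the window
#' @export
build_maps <- function(movie, windows, params = map_params(), fast = TRUE) {
  stopifnot(inherits(movie, "vf_movie"), nrow(windows) >= 1)
  if (is.unsorted(windows$start_ms, strictly = FALSE) ||
      any(windows$end_ms[-nrow(windows)] > windows$start_ms[-1]))
    stop("beat windows must be sorted and non-overlapping")
  d <- dim(movie$frames)
  npx <- d[1] * d[2]
  # restrict to the frames the windows need (plus baseline context)
  tt <- movie_times(movie)
  keep <- which(tt >= min(windows$start_ms) - params$baseline_win_ms &
                tt <= max(windows$end_ms) + 50)
  t0k <- tt[keep[1]]
  M <- matrix(movie$frames, npx, d[3])[, keep, drop = FALSE]
  nw <- nrow(windows)
  if (fast && params$at_method == "max_deriv") {
    kern <- numeric(0)
    if (params$smooth_temporal) {
      wl <- max(5L, round(params$sg_width_ms / movie$frame_ms))
      if (wl %% 2L == 0L) wl <- wl + 1L
      if (ncol(M) > wl) kern <- signal::sgolay(p = 3, n = wl)[(wl + 1) %/% 2, ]
    }
    res <- map_chain_cpp(M, movie$frame_ms, t0k,
                         as.matrix(windows[, c("start_ms", "end_ms")]),
                         params$baseline_win_ms, params$baseline_q,
                         params$snr_min, params$min_window_amp_frac,
                         params$deriv_frac, params$min_upstroke,
                         params$apd_level, kern)
    at_v <- res$at
    apd_v <- res$apd
  } else {
  at_v <- matrix(NA_real_, npx, nw)
  apd_v <- matrix(NA_real_, npx, nw)
  for (i in seq_len(npx)) {
    ct <- condition_trace(M[i, ], movie$frame_ms, windows = windows,
                          params = params, t0_ms = t0k)
    if (!ct$valid) next
    for (k in seq_len(nw)) {
      if (!ct$windows$valid[k]) next
      win <- c(windows$start_ms[k], windows$end_ms[k])
      a <- detect_activation(ct, win, params)
      if (is.na(a)) next
      at_v[i, k] <- a
      apd_v[i, k] <- measure_apd(ct, a, win, params = params)
    }
  }
  }
  out <- vector("list", nw)
  for (k in seq_len(nw)) {
    atm <- matrix(at_v[, k], d[1], d[2])
    apdm <- matrix(apd_v[, k], d[1], d[2])
    ok <- !is.na(atm) & !is.na(apdm)
    if (!any(ok))
      stop(sprintf("no valid pixels for beat window %d [%g, %g] ms",
                   k, windows$start_ms[k], windows$end_ms[k]))
    out[[k]] <- list(
      at = vf_map(atm, ok, "AT", movie$dx_mm, k),
      apd80 = vf_map(apdm, ok, "APD80", movie$dx_mm, k),
      rt = vf_map(atm + apdm, ok, "RT", movie$dx_mm, k),
      window = c(windows$start_ms[k], windows$end_ms[k]),
      label = if ("label" %in% names(windows)) windows$label[k] else NA)
  }
  out
}

#' Beat windows from a stimulus/pacing log
#'
#' Builds non-overlapping analysis windows, one per logged beat, starting
#' shortly before each stimulus and ending just before the next one (or
#' after `max_len_ms`).
#'
#' @param times_ms beat/stimulus onset times
#' @param lead_ms window start before each onset
#' @param max_len_ms maximum window length
#' @param labels optional label per beat
#' @param record_end_ms optional end of the recording (caps the last window)
#' @return data.frame with `start_ms`, `end_ms`, `label`
#' @export
beat_windows <- function(times_ms, lead_ms = 40, max_len_ms = 600,
                         labels = NULL, record_end_ms = Inf) {
  times_ms <- sort(times_ms)
  n <- length(times_ms)
  start <- times_ms - lead_ms
  nxt <- c(times_ms[-1] - lead_ms - 1, Inf)
  end <- pmin(times_ms + max_len_ms, nxt, record_end_ms)
  data.frame(start_ms = start, end_ms = end,
             label = if (is.null(labels)) rep(NA_character_, n) else labels,
             stringsAsFactors = FALSE)
}

#' The last fully repolarized pre-trigger beat window
#'
#' Maps "during regular activity preceding the onset" are taken from the
#' last beat whose repolarization completes everywhere before the trigger
#' arrives, so the APD measurement is uncontaminated.
#'
#' @param sim `vf_sim` with an injected ectopic
#' @param apd_margin_ms safety margin added to the expected repolarization
#' @return numeric length-2 window (ms)
#' @export
pre_trigger_window <- function(sim, apd_margin_ms = 80) {
  stopifnot(inherits(sim, "vf_sim"))
  ei <- sim$truth$ectopic
  trig <- if (!is.null(ei)) min(ei$realized_ms, na.rm = TRUE) else Inf
  pl <- sim$pacing_log
  cand <- pl$time_ms[pl$time_ms < trig]
  if (length(cand) < 2) stop("no complete pre-trigger beat")
  cyc <- pl$cycle_ms[1]
  # latest beat whose window [t, t + cycle] ends before the trigger
  ok <- cand + cyc <= trig
  t0 <- if (any(ok)) max(cand[ok]) else cand[length(cand) - 1]
  c(t0 - 40, min(t0 + cyc - 41, trig - 1))
}
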