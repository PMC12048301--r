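#' Analytic-signal phase of a single trace
#'
#' Phase of the analytic signal (FFT construction: negative frequencies
#' zeroed) of the mean-subtracted trace, wrapped to (-pi, pi].
#'
#' @param x numeric vector
#' @return phase in radians, same length
#' @export
analytic_phase <- function(x) {
  n <- length(x)
  stopifnot(n >= 4)
  x <- x - mean(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  atan2(Im(z), Re(z))
}

#' Compute a phase movie from an optical movie
#'
#' Per-pixel instantaneous phase of the analytic signal of the
#' mean-subtracted conditioned trace over the analysis window. Pixels
#' failing the SNR gate are masked and propagate as NA.
#'
#' The phase origin is, by default, aligned to depolarization: the raw
#' analytic-signal phase at the upstroke depends on the action potential's
#' duty cycle, so a global rotation (the circular mean of the phase at
#' each pixel's maximal positive derivative) is subtracted, after which
#' phase crosses zero at activation. Winding numbers are unaffected by a
#' global rotation. `align = "none"` keeps the raw convention.
#'
#' @param movie `vf_movie`
#' @param window numeric length-2 analysis window (ms); must contain at
#'   least two cycles of activity (`min_window_ms`)
#' @param params [map_params()] (SNR gate)
#' @param min_window_ms minimum window length
#' @param align `"upstroke"` (default) or `"none"`
#' @return list of class `vf_phase`: `phase` (rows x cols x time array),
#'   `valid` (matrix), `time_ms`, `dx_mm`
#' @export
compute_phase <- function(movie, window = NULL, params = map_params(),
                          min_window_ms = 400,
                          align = c("upstroke", "none")) {
  align <- match.arg(align)
  stopifnot(inherits(movie, "vf_movie"))
  tt <- movie_times(movie)
  if (is.null(window)) window <- range(tt)
  if (diff(window) < min_window_ms)
    stop(sprintf("analysis window %.0f ms < minimum %.0f ms (need >= 2 cycles)",
                 diff(window), min_window_ms))
  keep <- which(tt >= window[1] & tt <= window[2])
  d <- dim(movie$frames)
  npx <- d[1] * d[2]
  M <- matrix(movie$frames, npx, d[3])[, keep, drop = FALSE]
  M <- M - rowMeans(M)
  # analytic signal for all pixels at once via column FFTs
  n <- ncol(M)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  X <- mvfft(t(M))
  Z <- mvfft(X * h, inverse = TRUE) / n
  ph <- atan2(Im(Z), Re(Z))           # time x pixel
  # SNR mask from the raw traces
  amp <- apply(M, 1, function(r) diff(range(r)))
  nz <- apply(M, 1, function(r) median(abs(diff(r)))) * 1.4826 / sqrt(2)
  ok <- is.finite(amp) & amp > 0 & (nz == 0 | amp / nz >= params$snr_min)
  if (align == "upstroke" && any(ok)) {
    pick <- which(ok)
    if (length(pick) > 400) pick <- pick[round(seq(1, length(pick),
                                                   length.out = 400))]
    ups <- vapply(pick, function(i) {
      d <- diff(M[i, ])
      j <- which.max(d)
      ph[j, i]
    }, numeric(1))
    phi0 <- atan2(mean(sin(ups)), mean(cos(ups)))
    ph <- wrap_pi(ph - phi0)
  }
  arr <- array(t(ph), dim = c(d[1], d[2], n))
  arr[array(!ok, dim = c(d[1], d[2], n))] <- NA_real_
  structure(list(phase = arr, valid = matrix(ok, d[1], d[2]),
                 time_ms = tt[keep], dx_mm = movie$dx_mm),
            class = "vf_phase")
}

#' @keywords internal
wrap_pi <- function(x) atan2(sin(x), cos(x))

#' Detect phase singularities in one frame
#'
#' For every 2x2 plaquette of valid pixels the winding number is the sum
#' of wrapped phase differences around the loop divided by 2 pi; a winding
#' of +1 or -1 marks a singularity at the plaquette center with that
#' topological charge. Nearby opposite charges are retained (figure-of-8
#' support).
#'
#' @param phase `vf_phase` or a phase matrix (radians)
#' @param frame frame index (when `phase` is a `vf_phase`)
#' @return data.frame with `row`, `col` (plaquette centers, +0.5 offsets),
#'   `charge`
#' @export
detect_singularities <- function(phase, frame = 1) {
  P <- if (inherits(phase, "vf_phase")) phase$phase[, , frame] else phase
  nr <- nrow(P); nc <- ncol(P)
  a <- P[-nr, -nc]; b <- P[-nr, -1]; cc <- P[-1, -1]; dd <- P[-1, -nc]
  w <- (wrap_pi(b - a) + wrap_pi(cc - b) + wrap_pi(dd - cc) + wrap_pi(a - dd)) /
    (2 * pi)
  w[!is.finite(w)] <- 0
  idx <- which(abs(w) > 0.5, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = numeric(0), col = numeric(0), charge = numeric(0)))
  data.frame(row = idx[, 1] + 0.5, col = idx[, 2] + 0.5,
             charge = round(w[idx]))
}

#' Track phase singularities across frames
#'
#' Nearest-neighbor linking of same-charge singularities with a distance
#' gate; returns per-track positions and lifetimes.
#'
#' @param phase `vf_phase`
#' @param frames frame indices to scan (default all)
#' @param gate_px maximum per-frame displacement for linking
#' @return data.frame with `track`, `frame`, `time_ms`, `row`, `col`,
#'   `charge`
#' @export
track_singularities <- function(phase, frames = NULL, gate_px = 3) {
  stopifnot(inherits(phase, "vf_phase"))
  if (is.null(frames)) frames <- seq_along(phase$time_ms)
  out <- list()
  active <- data.frame(track = numeric(0), row = numeric(0),
                       col = numeric(0), charge = numeric(0),
                       last_frame = numeric(0))
  next_id <- 1
  for (f in frames) {
    s <- detect_singularities(phase, f)
    s$track <- rep(NA_real_, nrow(s))
    if (nrow(s) > 0 && nrow(active) > 0) {
      for (i in seq_len(nrow(s))) {
        cand <- which(active$charge == s$charge[i] &
                      f - active$last_frame <= 3)
        if (length(cand) == 0) next
        dd <- sqrt((active$row[cand] - s$row[i])^2 +
                   (active$col[cand] - s$col[i])^2)
        j <- which.min(dd)
        if (dd[j] <= gate_px * (f - active$last_frame[cand[j]])) {
          s$track[i] <- active$track[cand[j]]
          active$row[cand[j]] <- s$row[i]
          active$col[cand[j]] <- s$col[i]
          active$last_frame[cand[j]] <- f
        }
      }
    }
    for (i in which(is.na(s$track))) {
      s$track[i] <- next_id
      active <- rbind(active, data.frame(
        track = next_id, row = s$row[i], col = s$col[i],
        charge = s$charge[i], last_frame = f))
      next_id <- next_id + 1
    }
    if (nrow(s) > 0)
      out[[length(out) + 1]] <- data.frame(
        track = s$track, frame = f, time_ms = phase$time_ms[f],
        row = s$row, col = s$col, charge = s$charge)
    active <- active[f - active$last_frame <= 3, , drop = FALSE]
  }
  if (length(out) == 0)
    return(data.frame(track = numeric(0), frame = numeric(0),
                      time_ms = numeric(0), row = numeric(0),
                      col = numeric(0), charge = numeric(0)))
  do.call(rbind, out)
}

#' Localize the tissue origin of a trigger beat
#'
#' Computes the per-pixel activation map of the trigger beat window and
#' takes the centroid of the earliest-activated fraction of valid pixels
#' (default 1 %) as the origin; the origin time is the minimum activation
#' time.
#'
#' @param movie `vf_movie` (fluorescence)
#' @param window numeric length-2: the trigger beat window (ms)
#' @param params [map_params()]
#' @param percentile earliest-activated fraction defining the origin
#' @param early_ms when non-`NULL`, the origin cluster is instead the
#'   pixels activating within this many ms of the earliest activation —
#'   the breakthrough disc of the first frames. A fixed time depth tracks
#'   the physical source size; a pixel percentile grows with the captured
#'   area and drags the centroid toward the direction of fastest
#'   expansion (the recovered side). Default 3 ms.
#' @return list with `origin` (row, col), `origin_time_ms`, `at_map`
#'   (`vf_map`), `n_origin_px`
#' @export
localize_trigger <- function(movie, window, params = map_params(),
                             percentile = 0.01, early_ms = NULL) {
  stopifnot(inherits(movie, "vf_movie"), length(window) == 2)
  # a short-coupled trigger fires while its neighborhood is still finishing
  # repolarization: the beat-window amplitude there is legitimately reduced,
  # so the usual half-amplitude window gate would mask exactly the pixels
  # that carry the origin
  if (params$min_window_amp_frac > 0.35) params$min_window_amp_frac <- 0.35
  d <- dim(movie$frames)
  npx <- d[1] * d[2]
  tt <- movie_times(movie)
  keep <- which(tt >= window[1] - params$baseline_win_ms &
                tt <= window[2] + 50)
  M <- matrix(movie$frames, npx, d[3])[, keep, drop = FALSE]
  t0k <- tt[keep[1]]
  win_df <- data.frame(start_ms = window[1], end_ms = window[2])
  if (params$at_method == "max_deriv") {
    kern <- numeric(0)
    if (params$smooth_temporal) {
      wl <- max(5L, round(params$sg_width_ms / movie$frame_ms))
      if (wl %% 2L == 0L) wl <- wl + 1L
      if (ncol(M) > wl) kern <- signal::sgolay(p = 3, n = wl)[(wl + 1) %/% 2, ]
    }
    at <- map_chain_cpp(M, movie$frame_ms, t0k,
                        as.matrix(win_df), params$baseline_win_ms,
                        params$baseline_q, params$snr_min,
                        params$min_window_amp_frac, params$deriv_frac,
                        params$min_upstroke, params$apd_level, kern)$at[, 1]
  } else {
    at <- rep(NA_real_, npx)
    for (i in seq_len(npx)) {
      ct <- condition_trace(M[i, ], movie$frame_ms, windows = win_df,
                            params = params, t0_ms = t0k)
      if (!ct$valid || !ct$windows$valid[1]) next
      at[i] <- detect_activation(ct, window, params)
    }
  }
  atm <- matrix(at, d[1], d[2])
  ok <- !is.na(atm)
  if (!any(ok))
    stop("origin not mappable: no valid activation in the trigger window")
  qs <- if (is.null(early_ms)) quantile(atm[ok], percentile, names = FALSE)
        else min(atm[ok]) + early_ms
  early <- ok & atm <= qs
  # isolated noise-early pixels must not drag the centroid: the origin is
  # the largest connected cluster of early pixels
  lab <- EBImage::bwlabel(early + 0)
  if (max(lab) >= 1) {
    tabs <- tabulate(lab[lab > 0])
    early <- lab == which.max(tabs)
  }
  sel <- which(early, arr.ind = TRUE)
  if (nrow(sel) == 0) sel <- which(atm == min(atm[ok]), arr.ind = TRUE)
  list(origin = c(row = mean(sel[, 1]), col = mean(sel[, 2])),
       origin_time_ms = min(atm[early], na.rm = TRUE),
       at_map = vf_map(atm, ok, "AT", movie$dx_mm),
       n_origin_px = nrow(sel))
}

#' Classify the first VF cycles as breakthroughs or rotors
#'
#' Splits the post-trigger window into activation cycles (successive
#' activations at the reference pixel nearest the origin) and, per cycle,
#' reports `"rotor"` when a singularity track persists for at least one
#' rotation (track lifetime >= the cycle length) near the mapped region,
#' otherwise `"breakthrough"` when a focal activation appears (earliest
#' pixels activate before the surrounding ring). Cycles with neither
#' pattern are `"indeterminate"`.
#'
#' @param movie `vf_movie`
#' @param phase `vf_phase` covering the post-trigger window
#' @param origin trigger origin (row, col) from [localize_trigger()]
#' @param start_ms start of the first post-trigger cycle
#' @param n_cycles number of cycles to classify (the early-VF analysis
#'   deliberately stops after 4-5 complexes)
#' @param params [map_params()]
#' @return data.frame per cycle: `cycle`, `start_ms`, `end_ms`, `pattern`,
#'   `near_origin` (breakthrough within 5 mm of the trigger origin)
#' @export
classify_first_cycles <- function(movie, phase, origin, start_ms,
                                  n_cycles = 5, params = map_params()) {
  stopifnot(inherits(movie, "vf_movie"))
  d <- dim(movie$frames)
  r0 <- round(origin[1]); c0 <- round(origin[2])
  tt <- movie_times(movie)
  # reference trace near the origin: cycle boundaries = activations
  tr <- movie$frames[r0, c0, ]
  ct <- condition_trace(tr, movie$frame_ms, params = params, t0_ms = tt[1])
  x <- ct$x
  up <- which(x[-length(x)] < 0.5 & x[-1] >= 0.5)
  up_t <- tt[up]
  up_t <- up_t[up_t >= start_ms - 10]
  if (length(up_t) < 2) {
    warning("insufficient post-trigger cycles at the origin")
    return(data.frame(cycle = integer(0), start_ms = numeric(0),
                      end_ms = numeric(0), pattern = character(0),
                      near_origin = logical(0)))
  }
  n_avail <- min(n_cycles, length(up_t) - 1)
  if (n_avail < n_cycles)
    warning(sprintf("only %d of %d requested cycles available", n_avail,
                    n_cycles))
  tracks <- track_singularities(phase)
  track_life <- if (nrow(tracks) > 0)
    stats::aggregate(time_ms ~ track, tracks,
                     function(z) diff(range(z))) else NULL
  out <- vector("list", n_avail)
  for (k in seq_len(n_avail)) {
    w <- c(up_t[k] - 20, up_t[k + 1] - 20)
    cl <- up_t[k + 1] - up_t[k]
    pattern <- "indeterminate"; near <- NA
    # rotor: a track alive >= one rotation overlapping this cycle
    if (!is.null(track_life) && nrow(tracks) > 0) {
      in_cyc <- tracks[tracks$time_ms >= w[1] & tracks$time_ms <= w[2], ]
      if (nrow(in_cyc) > 0) {
        lives <- track_life$time_ms[match(unique(in_cyc$track),
                                          track_life$track)]
        if (any(lives >= cl)) pattern <- "rotor"
      }
    }
    if (pattern != "rotor") {
      # breakthrough: earliest activated cluster is focal (activates
      # before its surrounding 5-px ring)
      loc <- try(localize_trigger(movie, w, params), silent = TRUE)
      if (!inherits(loc, "try-error")) {
        atm <- loc$at_map$values
        rr <- round(loc$origin[1]); cc <- round(loc$origin[2])
        ring <- ring_values(atm, rr, cc, 5)
        if (length(ring) > 3 &&
            loc$origin_time_ms < min(ring, na.rm = TRUE)) {
          pattern <- "breakthrough"
          near <- sqrt((loc$origin[1] - origin[1])^2 +
                       (loc$origin[2] - origin[2])^2) * movie$dx_mm <= 5
        }
      }
    }
    out[[k]] <- data.frame(cycle = k, start_ms = w[1], end_ms = w[2],
                           pattern = pattern, near_origin = near)
  }
  do.call(rbind, out)
}

#' @keywords internal
ring_values <- function(m, r0, c0, radius) {
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  rr <- round(r0 + radius * sin(ang)); cc <- round(c0 + radius * cos(ang))
  ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  v <- m[cbind(rr[ok], cc[ok])]
  v[is.finite(v)]
}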