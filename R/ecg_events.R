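#' Parameters of the ECG event stage
#'
#' @param band_hz QRS detection band-pass (Hz)
#' @param lockout_ms refractory lockout between detected deflections
#' @param onset_frac backtracked onset = first sample of the deflection
#'   exceeding this fraction of its envelope peak
#' @param pace_match_ms a beat within this window of a logged pacing event
#'   is labeled paced/intrinsic
#' @param prematurity a beat is premature when its interval is below this
#'   fraction of the prevailing cycle length
#' @param vf_cycle_ms deflection cycle length below which activity counts
#'   as fibrillatory
#' @param vf_min_cycles minimum consecutive fast cycles to call VF
#' @param vf_cv_min minimum coefficient of variation of those cycles
#'   (excludes regular fast pacing)
#' @param sustained_s sustained/nonsustained episode threshold (inclusive)
#' @param spont_max_hz maximum pacing rate compatible with a "spontaneous"
#'   classification (inclusive; above it the rhythm is rapid pacing)
#' @return list of class `vf_ecg_params`
#' @export
ecg_params <- function(band_hz = c(0, 40), lockout_ms = 120,
                       onset_frac = 0.02, pace_match_ms = 25,
                       prematurity = 0.9, vf_cycle_ms = 250,
                       vf_min_cycles = 4, vf_cv_min = 0.1,
                       sustained_s = 8, spont_max_hz = 2) {
  structure(list(band_hz = band_hz, lockout_ms = lockout_ms,
                 onset_frac = onset_frac, pace_match_ms = pace_match_ms,
                 prematurity = prematurity, vf_cycle_ms = vf_cycle_ms,
                 vf_min_cycles = vf_min_cycles, vf_cv_min = vf_cv_min,
                 sustained_s = sustained_s, spont_max_hz = spont_max_hz),
            class = "vf_ecg_params")
}

#' @keywords internal
ecg_bandpass <- function(ecg, band_hz) {
  fs <- 1000 / ecg$dt_ms
  if (band_hz[1] <= 0) {
    bf <- signal::butter(2, min(band_hz[2] / (fs / 2), 0.99), type = "low")
  } else {
    bf <- signal::butter(2, pmin(band_hz / (fs / 2), 0.99), type = "pass")
  }
  as.numeric(signal::filtfilt(bf, ecg$amp))
}

#' @keywords internal
ecg_detfun <- function(x, dt_ms, band_hz, smooth_ms = 40) {
  fs <- 1000 / dt_ms
  if (band_hz[1] <= 0) {
    bf <- signal::butter(2, min(band_hz[2] / (fs / 2), 0.99), type = "low")
  } else {
    bf <- signal::butter(2, pmin(band_hz / (fs / 2), 0.99), type = "pass")
  }
  bp <- as.numeric(signal::filtfilt(bf, x - median(x)))
  env <- (c(0, diff(bp)) / dt_ms)^2
  k <- max(3L, round(smooth_ms / dt_ms))
  if (k %% 2L == 0L) k <- k + 1L
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  env
}

#' @keywords internal
env_peaks <- function(env, thr, lock) {
  cand <- which(env > thr &
                env >= c(-Inf, env[-length(env)]) &
                env >= c(env[-1], -Inf))
  cand <- cand[order(env[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (i in cand) {
    if (length(taken) == 0 || all(abs(taken - i) > lock)) taken <- c(taken, i)
  }
  sort(taken)
}

#' @keywords internal
env_onsets <- function(env, taken, onset_frac, dt_ms, max_back_ms = 200) {
  vapply(taken, function(i) {
    lvl <- onset_frac * env[i]
    j <- i
    lim <- max(1L, i - round(max_back_ms / dt_ms))
    while (j > lim && env[j - 1] > lvl) j <- j - 1L
    j
  }, numeric(1))
}

#' Detect beats (QRS-like deflections) on a pseudo-ECG
#'
#' Detection operates on the squared, smoothed temporal derivative of the
#' low-pass-filtered record (a Pan-Tompkins-style detection function).
#' Peaks above an adaptive threshold are picked greedily with a refractory
#' lockout; each beat's onset is backtracked to where the detection
#' function first exceeded a small fraction of its peak, which makes
#' onsets consistent across deflection morphologies.
#'
#' When the record carries a pacing log with at least three paced (or
#' intrinsic) events, the stereotyped paced complex — including its
#' boundary-collision terminal deflection and its T wave — is removed by
#' template subtraction (median complex over the logged cycles) before
#' ectopic deflections are detected on the residual. This is what makes a
#' small premature deflection detectable even when it is no larger than
#' the T wave it rides on. Without a log, single-pass detection is used.
#'
#' Beats within `pace_match_ms` of a logged pacing/intrinsic event inherit
#' that label; all others are "other" until classified. Detection is
#' invariant to amplitude scale and offset.
#'
#' @param ecg `vf_ecg`
#' @param params [ecg_params()]
#' @return data.frame with `onset_ms`, `peak_ms`, `strength` (detection
#'   function at the peak), `type`; empty (with a warning) on a flat
#'   record
#' @export
detect_beats <- function(ecg, params = ecg_params()) {
  stopifnot(inherits(ecg, "vf_ecg"))
  empty <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      strength = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
  if (length(ecg$amp) < 10 || diff(range(ecg$amp)) == 0) {
    warning("flat ECG record: no beats")
    return(empty)
  }
  dt <- ecg$dt_ms
  tt <- ecg$time_ms
  env <- ecg_detfun(ecg$amp, dt, params$band_hz)
  lock <- round(params$lockout_ms / dt)

  anchors <- ecg$pacing$time_ms[ecg$pacing$kind %in% c("paced", "intrinsic")]
  use_template <- length(anchors) >= 3

  if (!use_template) {
    thr <- max(6 * median(env), 0.002 * max(env))
    if (max(env) <= thr) {
      warning("no deflections above threshold")
      return(empty)
    }
    taken <- env_peaks(env, thr, lock)
    onsets <- env_onsets(env, taken, params$onset_frac, dt)
    out <- data.frame(onset_ms = tt[onsets], peak_ms = tt[taken],
                      strength = env[taken],
                      type = rep("other", length(taken)),
                      stringsAsFactors = FALSE)
  } else {
    n <- length(ecg$amp)
    ai <- round((anchors - ecg$time_ms[1]) / dt) + 1L
    L <- round(median(diff(ai)))
    # median paced complex over full cycles (excluding the first beat,
    # which starts from rest and has a different morphology)
    src <- ai[-1][ai[-1] + L - 1L <= n]
    if (length(src) >= 2) {
      tpl <- apply(vapply(src, function(i) ecg$amp[i:(i + L - 1L)],
                          numeric(L)), 1, median)
    } else tpl <- ecg$amp[ai[1] + seq_len(L) - 1L]
    resid <- ecg$amp
    for (i in ai) {
      j <- min(n, i + L - 1L)
      resid[i:j] <- resid[i:j] - tpl[seq_len(j - i + 1L)]
    }
    env_res <- ecg_detfun(resid, dt, params$band_hz)
    # fine (lightly smoothed) detection functions resolve the sharp foot of
    # each complex — the wavefront-birth/stimulus transient — to a few ms
    fine <- ecg_detfun(ecg$amp, dt, c(0, min(100, 0.45 * 1000 / dt)),
                       smooth_ms = 6)
    fine_res <- ecg_detfun(resid, dt, c(0, min(100, 0.45 * 1000 / dt)),
                           smooth_ms = 6)
    foot <- function(fe, pk, w0, flr) {
      w0 <- max(1L, w0)
      if (pk <= w0) return(pk)
      seg <- fe[w0:pk]
      lvl <- max(12 * flr, 1e-3 * max(seg), 1e-12 * max(fine))
      up <- which(seg > lvl)
      if (length(up) == 0) return(pk)
      w0 + up[1] - 1L
    }
    # paced onsets near each logged anchor; the floor is the diastolic
    # level just ahead of the stimulus
    paced <- vapply(ai, function(i) {
      w0 <- max(1L, i - round(30 / dt)); w1 <- min(n, i + round(150 / dt))
      pk <- w0 + which.max(env[w0:w1]) - 1L
      f0 <- max(1L, i - round(180 / dt)); f1 <- max(1L, i - round(40 / dt))
      c(pk, foot(fine, pk, w0, quantile7(fine[f0:f1], 0.15)))
    }, numeric(2))
    # ectopic deflections on the residual, against a LOCAL noise floor
    # (template-mismatch energy elsewhere must not mask a small
    # deflection). The floor is a running low percentile — unlike a
    # running median it stays at the inter-deflection level during
    # sustained fast activity, whose high duty cycle would otherwise
    # raise the floor above its own deflections.
    wf <- round(600 / dt)
    fstarts <- unique(pmin(seq(1L, n, by = max(1L, wf %/% 2L)), n - 1L))
    fmids <- pmin(fstarts + wf %/% 2L, n)
    flr10 <- vapply(fstarts, function(s)
      quantile7(env_res[s:min(n, s + wf - 1L)], 0.1), numeric(1))
    floor_res <- approx(fmids, flr10, xout = seq_len(n), rule = 2)$y
    thr_abs <- 0.005 * max(env)
    cand_ok <- env_res > pmax(5 * floor_res, thr_abs)
    env_gated <- ifelse(cand_ok, env_res, 0)
    taken <- env_peaks(env_gated, thr_abs, lock)
    # drop residual detections overlapping a paced QRS or the burn-in beat
    qrs_guard <- round(120 / dt)
    keep <- vapply(taken, function(i)
      all(abs(i - paced[1, ]) > qrs_guard) && i > ai[2],
      logical(1))
    taken <- taken[keep]
    # foot-based onsets on the residual; late lobes of one multi-lobed
    # complex resolve to the same foot and are deduplicated below. The
    # floor is the 5th percentile of the search window (its quiet start).
    # During fast activity the window is cut at the detection-function
    # valley after the previous deflection, so feet do not chain backward.
    onsets <- vapply(seq_along(taken), function(k) {
      i <- taken[k]
      w0 <- max(1L, i - round(250 / dt))
      crowded <- k > 1 && taken[k - 1] > w0
      if (crowded) {
        # overlapping complexes (fibrillatory rates) leave no quiet gap
        # for a floor-level foot: use the start of this peak's own
        # contiguous super-threshold region of the detection function
        j <- i
        while (j > 1 && cand_ok[j - 1]) j <- j - 1L
        return(max(j, taken[k - 1] + 1L))
      }
      foot(fine_res, i, w0, quantile7(fine_res[w0:i], 0.05))
    }, numeric(1))
    out <- rbind(
      data.frame(onset_ms = tt[paced[2, ]], peak_ms = tt[paced[1, ]],
                 strength = env[paced[1, ]],
                 type = rep("other", ncol(paced)),
                 stringsAsFactors = FALSE),
      data.frame(onset_ms = tt[onsets], peak_ms = tt[taken],
                 strength = env_res[taken],
                 type = rep("other", length(taken)),
                 stringsAsFactors = FALSE))
    out <- out[order(out$onset_ms, out$peak_ms), , drop = FALSE]
    # enforce the lockout across the merged set (earliest onset wins)
    if (nrow(out) > 1) {
      drop <- logical(nrow(out))
      last <- out$onset_ms[1]
      for (b in 2:nrow(out)) {
        if (out$onset_ms[b] - last < params$lockout_ms) drop[b] <- TRUE
        else last <- out$onset_ms[b]
      }
      out <- out[!drop, , drop = FALSE]
    }
  }
  if (nrow(ecg$pacing) > 0) {
    for (b in seq_len(nrow(out))) {
      dmin <- abs(ecg$pacing$time_ms - out$onset_ms[b])
      j <- which.min(dmin)
      if (dmin[j] <= params$pace_match_ms)
        out$type[b] <- as.character(ecg$pacing$kind[j])
    }
  }
  rownames(out) <- NULL
  out
}

#' Classify premature ventricular complexes and measure coupling intervals
#'
#' A PVC is a beat that does not match a logged pacing/intrinsic event and
#' is premature: its interval to the previous beat is below
#' `prematurity` times the prevailing cycle length (median of the last 5
#' non-PVC intervals). Coupling interval = PVC onset minus previous beat
#' onset.
#'
#' @param beats data.frame from [detect_beats()]
#' @param params [ecg_params()]
#' @return the beats with `type` refined ("pvc") and `coupling_ms`
#' @export
classify_pvc <- function(beats, params = ecg_params()) {
  beats$coupling_ms <- NA_real_
  n <- nrow(beats)
  if (n < 3) return(beats)
  recent <- numeric(0)
  last_onset <- beats$onset_ms[1]
  prev_was_pvc <- FALSE
  for (b in 2:n) {
    iv <- beats$onset_ms[b] - last_onset
    matched <- beats$type[b] %in% c("paced", "intrinsic")
    prevailing <- if (length(recent) > 0) median(recent) else NA_real_
    if (!matched && !is.na(prevailing) && iv < params$prematurity * prevailing) {
      beats$type[b] <- "pvc"
      beats$coupling_ms[b] <- iv
      prev_was_pvc <- TRUE
    } else {
      # the prevailing cycle is the interval between two non-PVC beats;
      # a post-PVC (compensatory) interval must not contaminate it
      if (!prev_was_pvc) {
        recent <- c(recent, iv)
        if (length(recent) > 5) recent <- recent[-1]
      }
      prev_was_pvc <- FALSE
    }
    last_onset <- beats$onset_ms[b]
  }
  beats
}

#' Estimate the end of the T wave of a beat (tangent method)
#'
#' Low-pass filters the record, finds the T peak in the repolarization
#' window of the beat, and intersects the steepest-descent tangent of the
#' descending limb with the baseline.
#'
#' @param ecg `vf_ecg`
#' @param onset_ms beat onset
#' @param limit_ms search must end before this time (e.g. the next beat)
#' @param qrs_end_ms start of the T-wave search window, relative to onset
#' @return list with `t_end_ms` (NA if not estimable) and `reason`
#' @export
twave_end <- function(ecg, onset_ms, limit_ms = Inf, qrs_end_ms = 120) {
  fs <- 1000 / ecg$dt_ms
  bf <- signal::butter(2, min(10 / (fs / 2), 0.99), type = "low")
  lp <- as.numeric(signal::filtfilt(bf, ecg$amp))
  tt <- ecg$time_ms
  i0 <- which(tt >= onset_ms + qrs_end_ms)[1]
  i1 <- max(which(tt <= min(limit_ms, onset_ms + 600)))
  if (is.na(i0) || i1 - i0 < 10)
    return(list(t_end_ms = NA_real_, reason = "window too short"))
  seg <- lp[i0:i1]
  pk <- which.max(abs(seg))
  if (pk >= length(seg) - 5)
    return(list(t_end_ms = NA_real_, reason = "T wave truncated"))
  sgn <- sign(seg[pk])
  y <- seg * sgn
  d <- diff(y) / ecg$dt_ms
  dseg <- d[pk:(length(y) - 1)]
  j <- which.min(dseg)        # steepest descent after the T peak
  if (dseg[j] >= 0)
    return(list(t_end_ms = NA_real_, reason = "no descending limb"))
  jj <- pk + j - 1
  t_j <- tt[i0 + jj - 1]
  t_end <- t_j - y[jj] / dseg[j]
  if (!is.finite(t_end) || t_end <= t_j)
    return(list(t_end_ms = NA_real_, reason = "tangent did not reach baseline"))
  list(t_end_ms = t_end, reason = NA_character_)
}

#' R-on-T assessment of a PVC
#'
#' A PVC is R-on-T when its onset falls at or before the estimated end of
#' the preceding beat's T wave. When the PVC truncates the T wave, the
#' T-end is taken from the median T-end offset of earlier unperturbed beats
#' of the same record.
#'
#' @param ecg `vf_ecg`
#' @param pvc_onset_ms PVC onset
#' @param prev_onset_ms preceding beat onset
#' @param template_offsets_ms optional T-end offsets (T-end minus onset) of
#'   unperturbed beats, used as fallback
#' @return list with `r_on_t` (logical, NA if not estimable), `t_end_ms`,
#'   `reason`
#' @export
twave_overlap <- function(ecg, pvc_onset_ms, prev_onset_ms,
                          template_offsets_ms = NULL) {
  te <- twave_end(ecg, prev_onset_ms, limit_ms = pvc_onset_ms - 5)
  if (is.na(te$t_end_ms) && length(template_offsets_ms) > 0) {
    te <- list(t_end_ms = prev_onset_ms + median(template_offsets_ms),
               reason = "template fallback")
  }
  if (is.na(te$t_end_ms))
    return(list(r_on_t = NA, t_end_ms = NA_real_, reason = te$reason))
  list(r_on_t = pvc_onset_ms <= te$t_end_ms, t_end_ms = te$t_end_ms,
       reason = te$reason)
}

#' Detect ventricular fibrillation episodes
#'
#' VF onset is the first of at least `vf_min_cycles` consecutive
#' deflections whose cycle lengths are all below `vf_cycle_ms` and whose
#' coefficient of variation exceeds `vf_cv_min` (irregularity excludes
#' regular rapid pacing). The episode ends at the return to organized
#' rhythm (first cycle at or above `vf_cycle_ms`) or at the record end.
#' Episodes are sustained when duration >= 8 s (inclusive), and spontaneous
#' when the pacing log shows no extrastimulus within 2 s before onset and a
#' pacing rate of at most 2 Hz (inclusive) at onset.
#'
#' @param ecg `vf_ecg`
#' @param beats classified beats from [classify_pvc()]
#' @param params [ecg_params()]
#' @return data.frame of episodes: `start_ms`, `end_ms`, `duration_s`,
#'   `sustained`, `spontaneous`, `trigger_onset_ms`, `trigger_coupling_ms`
#' @export
detect_vf <- function(ecg, beats, params = ecg_params()) {
  out <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                    duration_s = numeric(0), sustained = logical(0),
                    spontaneous = logical(0),
                    trigger_onset_ms = numeric(0),
                    trigger_coupling_ms = numeric(0))
  n <- nrow(beats)
  if (n < params$vf_min_cycles + 1) return(out)
  t <- beats$onset_ms
  iv <- diff(t)
  m <- params$vf_min_cycles
  i <- 1
  while (i <= length(iv) - m + 1) {
    win <- iv[i:(i + m - 1)]
    if (all(win < params$vf_cycle_ms) &&
        sd(win) / mean(win) > params$vf_cv_min) {
      onset <- t[i]
      j <- i + m - 1
      while (j < length(iv) && iv[j + 1] < params$vf_cycle_ms) j <- j + 1
      end <- t[j + 1]
      dur <- (end - onset) / 1000
      pvc_before <- which(beats$type == "pvc" & beats$onset_ms <= onset)
      trig <- if (length(pvc_before) > 0) max(pvc_before) else NA_integer_
      # spontaneity from the pacing log
      spont <- TRUE
      pl <- ecg$pacing
      if (nrow(pl) > 0) {
        if (any(pl$kind == "extra" &
                pl$time_ms > onset - 2000 & pl$time_ms <= onset))
          spont <- FALSE
        recent <- pl$time_ms[pl$kind == "paced" &
                             pl$time_ms > onset - 3000 & pl$time_ms <= onset]
        if (length(recent) >= 2) {
          rate_hz <- 1000 / median(diff(recent))
          if (rate_hz > params$spont_max_hz + 1e-9) spont <- FALSE
        }
      }
      out <- rbind(out, data.frame(
        start_ms = onset, end_ms = end, duration_s = dur,
        sustained = dur >= params$sustained_s,
        spontaneous = spont,
        trigger_onset_ms = if (is.na(trig)) NA_real_ else beats$onset_ms[trig],
        trigger_coupling_ms = if (is.na(trig)) NA_real_ else
          beats$coupling_ms[trig]))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

#' Summarize episodes and trigger characteristics
#'
#' Per-preparation counts of spontaneous VF (sustained/nonsustained split)
#' and coupling-interval statistics by PVC class: triggers of sustained VF,
#' triggers of nonsustained VF, and nontriggering PVCs, with R-on-T
#' fractions where assessed.
#'
#' @param episodes data.frame from [detect_vf()] (may carry a `prep`
#'   column for multi-preparation studies)
#' @param beats classified beats (may carry `prep` and `r_on_t` columns)
#' @return list with `counts`, `per_prep` and `coupling` data.frames
#' @export
episode_summary <- function(episodes, beats) {
  if (!"prep" %in% names(episodes))
    episodes$prep <- rep(1L, nrow(episodes))
  if (!"prep" %in% names(beats)) beats$prep <- rep(1L, nrow(beats))
  spont <- episodes[episodes$spontaneous, , drop = FALSE]
  per_prep <- data.frame(prep = sort(unique(c(episodes$prep, beats$prep))))
  per_prep$n_spont_vf <- vapply(per_prep$prep, function(p)
    sum(spont$prep == p), numeric(1))
  per_prep$n_sustained <- vapply(per_prep$prep, function(p)
    sum(spont$prep == p & spont$sustained), numeric(1))
  counts <- data.frame(
    n_preparations = nrow(per_prep),
    n_spont_vf = nrow(spont),
    n_sustained = sum(spont$sustained),
    n_nonsustained = sum(!spont$sustained),
    mean_per_prep = if (nrow(per_prep) > 0)
      nrow(spont) / nrow(per_prep) else 0)
  counts$mean_per_prep_rounded <- round(counts$mean_per_prep)

  cls <- function(b) {
    key <- paste(b$prep, b$onset_ms)
    sus <- paste(spont$prep, spont$trigger_onset_ms)[spont$sustained]
    nsus <- paste(spont$prep, spont$trigger_onset_ms)[!spont$sustained]
    ifelse(key %in% sus, "vf_trigger",
           ifelse(key %in% nsus, "nsvf_trigger", "non_trigger"))
  }
  pvcs <- beats[beats$type == "pvc", , drop = FALSE]
  coupling <- NULL
  if (nrow(pvcs) > 0) {
    pvcs$class <- cls(pvcs)
    coupling <- do.call(rbind, lapply(
      c("vf_trigger", "nsvf_trigger", "non_trigger"), function(cl) {
        sub <- pvcs[pvcs$class == cl, , drop = FALSE]
        data.frame(class = cl, n = nrow(sub),
                   mean_ms = if (nrow(sub)) mean(sub$coupling_ms) else NA_real_,
                   sd_ms = if (nrow(sub) > 1) sd(sub$coupling_ms) else NA_real_,
                   r_on_t_frac = if ("r_on_t" %in% names(sub) && nrow(sub))
                     mean(sub$r_on_t, na.rm = TRUE) else NA_real_)
      }))
  } else {
    coupling <- data.frame(class = character(0), n = numeric(0),
                           mean_ms = numeric(0), sd_ms = numeric(0),
                           r_on_t_frac = numeric(0))
  }
  list(counts = counts, per_prep = per_prep, coupling = coupling)
}
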