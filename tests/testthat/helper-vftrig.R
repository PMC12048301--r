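# Shared fixtures, built in code. Simulations are cached per session so
# several test files can reuse the same small preparation.

.fixture_env <- new.env(parent = emptyenv())

# a small (half-size, half-scale lesion) preparation configuration; the
# lesion deficit is halved together with the ramp width so the border
# gradient (15.9 ms/mm) matches the default calibration
small_config <- function(noise = TRUE, core_sd = 12, delta = -44.5) {
  study_config(
    n_rows = 64, n_cols = 64,
    lesion = lesion_spec(radius_mm = 3.85, border_width_mm = 2.8,
                         delta_apd_ms = delta,
                         core_sd_ms = core_sd, core_corr_mm = 1.5),
    pacing = pacing_protocol(n_beats = 3, site_row = 13),
    ectopic = ectopic_spec(site_offset_mm = -0.5),
    acquisition = if (noise) acquisition_model() else
      acquisition_model(blur_sigma_px = 0, noise_sd = 0,
                        rundown_per_min = 0, dead_pixel_frac = 0))
}

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small noiseless paced-only simulation (no ectopic), reused widely
small_paced_sim <- function() cached("paced_sim", {
  cfg <- small_config(noise = FALSE, core_sd = 0)
  field <- build_lesion_field(cfg$grid, cfg$lesion, cfg$ionic,
                              baseline_apd_ms = cfg$baseline_apd_ms, seed = 1)
  simulate_tissue(cfg$grid, field, cfg$pacing, duration_ms = 1600, seed = 1)
})

# small noiseless episode with one injected trigger
small_trigger_ep <- function() cached("trigger_ep", {
  synth_preparation(small_config(noise = FALSE, core_sd = 0), seed = 3)
})

# synthetic single-pixel action potential train (square-ish, linear
# repolarization tail), base 0 / amplitude 1
synth_ap_trace <- function(n_ms = 1500, frame_ms = 1, at = c(105, 605, 1105),
                           apd = 200, upstroke_ms = 2, tail_ms = 40,
                           amp = 1) {
  tt <- seq(0, n_ms - frame_ms, by = frame_ms)
  x <- numeric(length(tt))
  for (a in at) {
    rise <- pmin(1, pmax(0, (tt - a) / upstroke_ms))
    # holds near 1, then falls linearly so that the 20%-level (APD80)
    # crossing sits exactly `apd` after the upstroke onset
    fall <- pmin(1, pmax(0, (tt - (a + apd - 0.8 * tail_ms)) / tail_ms))
    x <- x + amp * pmax(0, rise - fall)
  }
  list(t = tt, x = x)
}

# synthetic movie of AP trains with a linear activation delay along rows
synth_movie <- function(nr = 16, nc = 16, n_ms = 1500, frame_ms = 1,
                        at0 = c(105, 605, 1105), delay_per_row = 2,
                        apd = 200, dx_mm = 0.39) {
  arr <- array(0, dim = c(nr, nc, n_ms / frame_ms))
  for (r in seq_len(nr)) {
    tr <- synth_ap_trace(n_ms, frame_ms, at0 + (r - 1) * delay_per_row, apd)
    for (c in seq_len(nc)) arr[r, c, ] <- tr$x
  }
  vf_movie(arr, dx_mm = dx_mm, frame_ms = frame_ms)
}

# Archimedean spiral phase field, charge +1, centered
spiral_phase <- function(n = 41, pitch = 0.5) {
  ctr <- (n + 1) / 2
  r <- outer(seq_len(n) - ctr, rep(1, n))
  c <- outer(rep(1, n), seq_len(n) - ctr)
  atan2(r, c) - pitch * sqrt(r^2 + c^2)
}

# brute-force winding-number oracle: explicit loop over plaquettes
winding_oracle <- function(P) {
  wrap <- function(x) atan2(sin(x), cos(x))
  out <- NULL
  for (i in seq_len(nrow(P) - 1)) for (j in seq_len(ncol(P) - 1)) {
    a <- P[i, j]; b <- P[i, j + 1]; cc <- P[i + 1, j + 1]; dd <- P[i + 1, j]
    if (any(!is.finite(c(a, b, cc, dd)))) next
    w <- (wrap(b - a) + wrap(cc - b) + wrap(dd - cc) + wrap(a - dd)) / (2 * pi)
    if (abs(w) > 0.5)
      out <- rbind(out, c(row = i + 0.5, col = j + 0.5, charge = round(w)))
  }
  if (is.null(out))
    data.frame(row = numeric(0), col = numeric(0), charge = numeric(0))
  else as.data.frame(out)
}

# Fisher two-sided enumeration oracle over all tables with fixed margins
fisher_oracle <- function(tab) {
  m <- rowSums(tab); k <- colSums(tab)
  if (any(m == 0) || any(k == 0)) return(1)
  a_min <- max(0, k[1] - m[2]); a_max <- min(k[1], m[1])
  av <- a_min:a_max
  pr <- dhyper(av, m[1], m[2], k[1])
  p_obs <- dhyper(tab[1, 1], m[1], m[2], k[1])
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
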