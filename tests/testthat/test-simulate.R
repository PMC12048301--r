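test_that("unstimulated homogeneous tissue stays at rest", {
  g <- tissue_grid(32, 32)
  fld <- build_lesion_field(g, NULL)
  pac <- pacing_protocol(n_beats = 0)
  sim <- simulate_tissue(g, fld, pac, duration_ms = 300, seed = 1)
  expect_lt(max(abs(sim$movie$frames)), 1e-9)
})

test_that("a paced beat produces activation isochrones monotone in distance", {
  sim <- small_paced_sim()
  tb <- truth_beat_maps(sim$truth, c(465, 1000))
  # along the pacing column, AT increases with distance from the site
  col <- 32
  at <- tb$at[13:60, col]
  expect_true(all(is.finite(at)))
  expect_true(all(diff(at) > 0))
})

test_that("an explicitly unstable step is rejected with a diagnostic", {
  g <- tissue_grid(32, 32, D = 0.3)
  fld <- build_lesion_field(g, NULL)
  expect_error(simulate_tissue(g, fld, pacing_protocol(), dt_ms = 0.2),
               "unstable step")
})

test_that("a stimulus into refractory tissue records a capture failure", {
  cfg <- small_config(noise = FALSE, core_sd = 0)
  ect <- ectopic_spec(coupling_mean_ms = 150, coupling_sd_ms = 0,
                      coupling_clip_ms = c(140, 160), defer_cap_ms = 5,
                      site_angle_deg = 90)
  field <- build_lesion_field(cfg$grid, cfg$lesion, cfg$ionic,
                              baseline_apd_ms = cfg$baseline_apd_ms)
  sim <- simulate_tissue(cfg$grid, field, cfg$pacing, ect,
                         duration_ms = 1700, seed = 2)
  ei <- sim$truth$ectopic
  expect_true(sim$truth$stim$failed[nrow(sim$truth$stim)] ||
              !ei$captured[1])
})

test_that("halving the time step changes activation times by < 0.5 ms", {
  g <- tissue_grid(48, 48)
  fld <- build_lesion_field(g, NULL)
  pac <- pacing_protocol(n_beats = 3, cycle_ms = 400, site_row = 8,
                         site_col = 24)
  s1 <- simulate_tissue(g, fld, pac, duration_ms = 1250, seed = 1,
                        dt_ms = 0.05)
  s2 <- simulate_tissue(g, fld, pac, duration_ms = 1250, seed = 1,
                        dt_ms = 0.025)
  a1 <- truth_beat_maps(s1$truth, c(770, 1250))$at
  a2 <- truth_beat_maps(s2$truth, c(770, 1250))$at
  expect_lt(max(abs(a1 - a2), na.rm = TRUE), 0.5)
})

test_that("identical seeds give bit-identical episodes", {
  cfg <- small_config()
  e1 <- synth_preparation(cfg, seed = 11, duration_ms = 1400)
  e2 <- synth_preparation(cfg, seed = 11, duration_ms = 1400)
  expect_identical(e1$sim$movie$frames, e2$sim$movie$frames)
  expect_identical(e1$optical$frames, e2$optical$frames)
  expect_identical(e1$ecg$amp, e2$ecg$amp)
})

test_that("realized ectopic couplings respect the refractory floor", {
  ep <- small_trigger_ep()
  ei <- ep$sim$truth$ectopic
  expect_true(ei$captured[1])
  expect_gte(ei$coupling_realized_ms[1], ei$coupling_drawn_ms[1] - 1e-9)
})
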