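test_that("noise-free rendering equals min-max normalized voltage", {
  sim <- small_paced_sim()
  om <- render_fluorescence(sim$movie,
                            acquisition_model(blur_sigma_px = 0,
                                              noise_sd = 0,
                                              rundown_per_min = 0,
                                              dead_pixel_frac = 0),
                            seed = 1)
  v <- sim$movie$frames
  ref <- (v - min(v)) / diff(range(v))
  expect_equal(om$frames, ref, tolerance = 1e-12)
})

test_that("rundown halves the amplitude after one minute at 50%/min", {
  arr <- array(rep(sin(seq(0, 40 * pi, length.out = 30001))^2, each = 16),
               dim = c(4, 4, 30001))
  mv <- vf_movie(arr, dx_mm = 0.39, frame_ms = 2)  # 60 s record
  om <- render_fluorescence(mv, acquisition_model(frame_ms = 2,
                                                  blur_sigma_px = 0,
                                                  noise_sd = 0,
                                                  rundown_per_min = 0.5,
                                                  dead_pixel_frac = 0),
                            seed = 1)
  early <- max(om$frames[, , 1:500])
  late <- max(om$frames[, , 29500:30001])
  expect_lt(abs(late / early - 0.5), 0.02)
})

test_that("acquisition noise is recovered from diastolic segments", {
  mv <- synth_movie(nr = 8, nc = 8, n_ms = 1200)
  om <- render_fluorescence(mv, acquisition_model(blur_sigma_px = 0,
                                                  noise_sd = 0.05,
                                                  rundown_per_min = 0,
                                                  dead_pixel_frac = 0),
                            seed = 2)
  # diastole of the synthetic train: 350-580 ms
  dia <- om$frames[, , 350:580]
  expect_lt(abs(sd(dia) / 0.05 - 1), 0.2)
})

test_that("a spatially uniform movie gives a null pseudo-ECG", {
  arr <- array(rep(seq(0, 1, length.out = 50), each = 64 * 64),
               dim = c(64, 64, 50))
  ecg <- compute_pseudo_ecg(vf_movie(arr, 0.39, 1))
  expect_lt(max(abs(ecg$amp)), 1e-9)
})

test_that("mirroring the electrode across a planar wave reverses polarity", {
  nr <- 32; nc <- 32; nt <- 120
  arr <- array(0, dim = c(nr, nc, nt))
  cidx <- col(matrix(0, nr, nc))
  for (k in seq_len(nt))                     # wave moving along columns
    arr[, , k] <- pmin(1, pmax(0, k / 2 - cidx))
  mv <- vf_movie(arr, 0.39, 1)
  ext <- (nc - 1) * 0.39
  e1 <- compute_pseudo_ecg(mv, electrode_mm = c(ext / 2, ext * 0.2, 10))
  e2 <- compute_pseudo_ecg(mv, electrode_mm = c(ext / 2, ext * 0.8, 10))
  # the dominant deflection reverses polarity at the mirrored electrode
  expect_equal(sign(e1$amp[which.max(abs(e1$amp))]),
               -sign(e2$amp[which.max(abs(e2$amp))]))
})

test_that("an electrode on a pixel is rejected", {
  sim <- small_paced_sim()
  expect_error(compute_pseudo_ecg(sim$movie, electrode_mm = c(5, 5, 0)),
               "r = 0")
})
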