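test_that("zero shortening gives a unit scaling field and baseline target", {
  g <- tissue_grid(48, 48)
  les <- lesion_spec(radius_mm = 3, border_width_mm = 1.5, delta_apd_ms = 0,
                     bg_gradient_ms_mm = 0, core_sd_ms = 0)
  fld <- build_lesion_field(g, les)
  expect_true(all(abs(fld$scale - 1) < 0.02))
  expect_true(all(abs(fld$target_apd - 240) < 1e-9))
})

test_that("default lesion covers 5-10% of tissue with the expected ramp", {
  g <- tissue_grid()
  fld <- build_lesion_field(g, lesion_spec(core_sd_ms = 0,
                                           bg_gradient_ms_mm = 0))
  expect_gte(fld$lesion_fraction, 0.05)
  expect_lte(fld$lesion_fraction, 0.10)
  # ideal maximal ramp slope of the target field = |delta| / border width
  mid <- 64
  prof <- fld$target_apd[mid:128, mid]
  slope <- max(abs(diff(prof))) / g$dx_mm
  expect_lt(abs(slope - 89 / 5.6), 0.8)
  # core deficit
  expect_lt(abs(fld$target_apd[mid, mid] - (240 - 89)) , 1e-6)
})

test_that("background gradient is applied at the stated magnitude", {
  g <- tissue_grid(64, 64)
  fld <- build_lesion_field(g, lesion_spec(radius_mm = 3.85,
                                           border_width_mm = 2.8,
                                           core_sd_ms = 0))
  far <- fld$target_apd[5, ]        # row far from the lesion
  slope <- median(diff(far)) / g$dx_mm
  expect_lt(abs(slope - 1.5), 0.02)
})

test_that("core heterogeneity is confined, zero-mean, and seeded", {
  g <- tissue_grid(64, 64)
  les <- lesion_spec(radius_mm = 3.85, border_width_mm = 2.8,
                     core_sd_ms = 12, core_corr_mm = 1.5,
                     bg_gradient_ms_mm = 0)
  f1 <- build_lesion_field(g, les, seed = 5)
  f2 <- build_lesion_field(g, les, seed = 5)
  f3 <- build_lesion_field(g, les, seed = 6)
  expect_identical(f1$target_apd, f2$target_apd)
  expect_false(identical(f1$target_apd, f3$target_apd))
  f0 <- build_lesion_field(g, lesion_spec(radius_mm = 3.85,
                                          border_width_mm = 2.8,
                                          core_sd_ms = 0,
                                          bg_gradient_ms_mm = 0))
  dev <- f1$target_apd - f0$target_apd
  ctr <- (64 + 1) / 2
  d <- sqrt(outer((seq_len(64) - ctr)^2, rep(1, 64)) +
            outer(rep(1, 64), (seq_len(64) - ctr)^2)) * g$dx_mm
  # untouched outside the inner quarter of the ramp
  expect_true(all(abs(dev[d > 3.85 - 2.8 / 8]) < 1e-9))
  expect_lt(abs(mean(dev[dev != 0])), 3)
})

test_that("invalid lesions are rejected", {
  g <- tissue_grid(48, 48)
  expect_error(build_lesion_field(g, lesion_spec(radius_mm = 15)),
               "fit inside")
  expect_error(
    build_lesion_field(g, lesion_spec(radius_mm = 3, border_width_mm = 1.5,
                                      delta_apd_ms = -200, core_sd_ms = 0)),
    "calibrated range")
})
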