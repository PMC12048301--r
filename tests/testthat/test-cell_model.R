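test_that("calibration curve is monotone and hits the baseline at scale 1", {
  cal <- apd_calibration()
  expect_true(all(diff(cal$apd80_ms) > 0))
  expect_true(all(diff(cal$scale) > 0))
  apd1 <- cell_apd80(cell_run(scale = 1))
  expect_lt(abs(apd1 - 240), 2)
})

test_that("calibration inversion round-trips through the single-cell model", {
  # independent oracle: 0-D time stepping at the inverted scaling
  cal <- apd_calibration()
  targets <- 240 + seq(-120, -20, length.out = 10)
  sc <- scale_for_apd(targets, cal)
  got <- vapply(sc, function(s) cell_apd80(cell_run(scale = s)), numeric(1))
  expect_true(all(abs(got - targets) <= 3))
})

test_that("targets outside the calibrated range are rejected", {
  cal <- apd_calibration()
  expect_error(scale_for_apd(10, cal), "calibrated range")
  expect_error(scale_for_apd(1000, cal), "calibrated range")
})
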