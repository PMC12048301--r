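win1 <- data.frame(start_ms = 60, end_ms = 500)

test_that("conditioning is an affine rescale on clean AP trains", {
  tr <- synth_ap_trace()
  w <- data.frame(start_ms = c(60, 560, 1060), end_ms = c(500, 1000, 1440))
  ct <- condition_trace(tr$x, 1, windows = w)
  expect_true(ct$valid)
  idx <- which(tr$t >= 60 & tr$t <= 500)
  expect_gt(cor(ct$x[idx], tr$x[idx]), 0.99999)
  expect_lt(min(ct$x[idx]), 0.05)
  expect_gt(max(ct$x[idx]), 0.95)
})

test_that("slow linear drift is removed to within 2%", {
  tr <- synth_ap_trace()
  drift <- 2 * tr$t / 60000          # two amplitudes per minute
  w <- data.frame(start_ms = c(60, 560, 1060), end_ms = c(500, 1000, 1440))
  c0 <- condition_trace(tr$x, 1, windows = w)
  c1 <- condition_trace(tr$x + drift, 1, windows = w)
  idx <- which(tr$t >= 60 & tr$t <= 1440)
  expect_lt(max(abs(c1$x[idx] - c0$x[idx])), 0.02)
})

test_that("a pure-noise trace fails the SNR gate", {
  set.seed(1)
  ct <- condition_trace(rnorm(1500, sd = 0.05), 1, windows = win1)
  expect_false(ct$valid)
})

test_that("inverted-polarity traces are corrected", {
  tr <- synth_ap_trace()
  ct <- condition_trace(-tr$x, 1, windows = win1)
  a <- detect_activation(ct, c(60, 500))
  expect_lt(abs(a - 105), 3)
})

test_that("activation time lands on the upstroke within one frame", {
  tr <- synth_ap_trace(upstroke_ms = 2)
  ct <- condition_trace(tr$x, 1, windows = win1)
  # 50% crossing of the linear 2-ms upstroke starting at 105 is at 106
  a <- detect_activation(ct, c(60, 500),
                         map_params(smooth_temporal = FALSE))
  expect_lt(abs(a - 106), 1.01)
  a2 <- detect_activation(ct, c(60, 500),
                          map_params(at_method = "half_amp",
                                     smooth_temporal = FALSE))
  expect_lt(abs(a2 - 106), 1.01)
})

test_that("a flat window yields no activation", {
  ct <- condition_trace(c(numeric(700), synth_ap_trace(800, at = 400)$x), 1,
                        windows = data.frame(start_ms = 10, end_ms = 500))
  expect_true(is.na(detect_activation(ct, c(10, 500))))
})

test_that("with two qualifying upstrokes the earlier one wins", {
  tt <- seq(0, 799)
  x <- pmin(1, pmax(0, (tt - 100) / 10)) - pmin(1, pmax(0, (tt - 240) / 30)) +
       pmin(1, pmax(0, (tt - 300) / 4)) - pmin(1, pmax(0, (tt - 500) / 30))
  ct <- condition_trace(x, 1, windows = data.frame(start_ms = 10,
                                                   end_ms = 790))
  a <- detect_activation(ct, c(10, 790), map_params(smooth_temporal = FALSE))
  expect_lt(a, 150)   # the earlier, shallower upstroke, not the steeper one
})

test_that("APD80 of a square pulse equals its width", {
  tr <- synth_ap_trace(apd = 200, tail_ms = 40)
  ct <- condition_trace(tr$x, 1, windows = win1)
  a <- detect_activation(ct, c(60, 500))
  apd <- measure_apd(ct, a, c(60, 500))
  expect_lt(abs(apd - 200), 3)
})

test_that("APD is monotone in the repolarization level", {
  tr <- synth_ap_trace()
  ct <- condition_trace(tr$x, 1, windows = win1)
  a <- detect_activation(ct, c(60, 500))
  a80 <- measure_apd(ct, a, c(60, 500), level = 0.8)
  a95 <- measure_apd(ct, a, c(60, 500), level = 0.95)
  a100 <- measure_apd(ct, a, c(60, 500), level = 1)
  expect_true(a80 < a95 && a95 <= a100)
})

test_that("unreached repolarization yields NA", {
  tr <- synth_ap_trace(n_ms = 900, at = 105, apd = 600)
  ct <- condition_trace(tr$x, 1, windows = win1)
  a <- detect_activation(ct, c(60, 500))
  expect_true(is.na(measure_apd(ct, a, c(60, 500))))
})

test_that("RT = AT + APD80 holds exactly on all valid pixels", {
  mv <- synth_movie()
  w <- data.frame(start_ms = c(60, 560), end_ms = c(500, 1000))
  maps <- build_maps(mv, w)
  for (m in maps) {
    ok <- m$rt$valid
    expect_true(any(ok))
    expect_identical(m$rt$values[ok], m$at$values[ok] + m$apd80$values[ok])
  }
})

test_that("build_maps recovers the synthetic activation delays", {
  mv <- synth_movie(delay_per_row = 2)
  maps <- build_maps(mv, data.frame(start_ms = 560, end_ms = 1000))
  at <- maps[[1]]$at$values
  expect_gt(mean(maps[[1]]$at$valid), 0.99)
  d <- diff(rowMeans(at, na.rm = TRUE))
  expect_true(all(abs(d - 2) < 0.5))
})

test_that("overlapping beat windows are rejected", {
  mv <- synth_movie(nr = 4, nc = 4, n_ms = 900)
  w <- data.frame(start_ms = c(60, 300), end_ms = c(500, 700))
  expect_error(build_maps(mv, w), "non-overlapping")
})

test_that("the compiled map chain equals the reference implementation", {
  mv <- synth_movie(nr = 10, nc = 10, n_ms = 1500)
  set.seed(7)
  mv$frames <- mv$frames + array(rnorm(length(mv$frames), sd = 0.03),
                                 dim(mv$frames))
  w <- data.frame(start_ms = c(60, 560), end_ms = c(500, 1000))
  mf <- build_maps(mv, w, fast = TRUE)
  mr <- build_maps(mv, w, fast = FALSE)
  for (k in 1:2) {
    expect_identical(mf[[k]]$at$valid, mr[[k]]$at$valid)
    expect_equal(mf[[k]]$at$values, mr[[k]]$at$values, tolerance = 1e-10)
    expect_equal(mf[[k]]$apd80$values, mr[[k]]$apd80$values,
                 tolerance = 1e-10)
  }
})
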