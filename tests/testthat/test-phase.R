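test_that("the analytic phase of a sinusoid advances at 2*pi*f", {
  fs <- 1000; f <- 4
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  ph <- analytic_phase(sin(2 * pi * f * t))
  dph <- diff(ph)
  dph <- atan2(sin(dph), cos(dph))
  core <- dph[100:1800]
  expect_lt(max(abs(core - 2 * pi * f / fs)), 1e-3)
})

test_that("negating a trace shifts its phase by pi", {
  x <- sin(seq(0, 40, by = 0.01)) + 0.3 * sin(seq(0, 80, by = 0.02))
  p1 <- analytic_phase(x)
  p2 <- analytic_phase(-x)
  d <- atan2(sin(p1 - p2), cos(p1 - p2))
  expect_lt(max(abs(abs(d[50:3900]) - pi)), 1e-6)
})

test_that("an Archimedean spiral holds exactly one +1 singularity at center", {
  P <- spiral_phase(41)
  s <- detect_singularities(P)
  expect_equal(nrow(s), 1)
  expect_equal(s$charge, 1)
  expect_lt(max(abs(c(s$row, s$col) - 21)), 1.01)
  # mirrored spiral: charge -1
  s2 <- detect_singularities(P[, 41:1])
  expect_equal(s2$charge, -1)
})

test_that("a planar phase field has no singularities", {
  P <- outer(rep(1, 32), seq(0, 6 * pi, length.out = 32))
  P <- atan2(sin(P), cos(P))
  expect_equal(nrow(detect_singularities(P)), 0)
})

test_that("the winding detector matches the brute-force oracle on random fields", {
  set.seed(99)
  for (k in 1:1000) {
    z <- matrix(complex(real = rnorm(24 * 24), imaginary = rnorm(24 * 24)),
                24, 24)
    zs <- EBImage::gblur(Re(z), 1.5) + 1i * EBImage::gblur(Im(z), 1.5)
    P <- atan2(Im(zs), Re(zs))
    got <- detect_singularities(P)
    ora <- winding_oracle(P)
    expect_equal(nrow(got), nrow(ora))
    if (nrow(got) > 0) {
      o1 <- order(got$row, got$col); o2 <- order(ora$row, ora$col)
      expect_equal(got$row[o1], ora$row[o2])
      expect_equal(got$col[o1], ora$col[o2])
      expect_equal(got$charge[o1], ora$charge[o2])
    }
  }
})

test_that("topological charge changes only in +/-2 pair events away from edges", {
  # rotating spiral movie: analytic field exp(i(theta - r - t))
  n <- 41; ctr <- 21
  r <- sqrt(outer((seq_len(n) - ctr)^2, rep(1, n)) +
            outer(rep(1, n), (seq_len(n) - ctr)^2))
  th <- atan2(outer(seq_len(n) - ctr, rep(1, n)),
              outer(rep(1, n), seq_len(n) - ctr))
  totals <- vapply(seq(0, 2 * pi, length.out = 20), function(t0) {
    s <- detect_singularities(atan2(sin(th - 0.4 * r - t0),
                                    cos(th - 0.4 * r - t0)))
    sum(s$charge)
  }, numeric(1))
  expect_true(all(totals == totals[1]))
})

test_that("singularity tracking links a drifting vortex into one track", {
  n <- 41
  mk <- function(cy, cx) {
    atan2(outer(seq_len(n) - cy, rep(1, n)),
          outer(rep(1, n), seq_len(n) - cx))
  }
  arr <- array(0, dim = c(n, n, 10))
  for (k in 1:10) arr[, , k] <- mk(15 + k * 0.8, 20)
  ph <- structure(list(phase = arr, valid = matrix(TRUE, n, n),
                       time_ms = seq_len(10), dx_mm = 0.39),
                  class = "vf_phase")
  tr <- track_singularities(ph)
  expect_equal(length(unique(tr$track)), 1)
  expect_equal(nrow(tr), 10)
})

test_that("phase mapping rejects windows that are too short", {
  mv <- synth_movie(nr = 8, nc = 8, n_ms = 1200)
  expect_error(compute_phase(mv, window = c(0, 200)), "minimum")
})

test_that("trigger localization of a paced beat lands on the pacing site", {
  sim <- small_paced_sim()
  om <- render_fluorescence(sim$movie,
                            acquisition_model(blur_sigma_px = 0,
                                              noise_sd = 0,
                                              rundown_per_min = 0,
                                              dead_pixel_frac = 0), seed = 1)
  loc <- localize_trigger(om, c(465, 905))
  expect_lt(sqrt((loc$origin[1] - 13)^2 + (loc$origin[2] - 32)^2), 3.5)
})

test_that("noiseless trigger-origin localization is within 2 px of truth", {
  ep <- small_trigger_ep()
  ei <- ep$sim$truth$ectopic
  twin <- c(ei$realized_ms[1] - 40, ei$realized_ms[1] + 250)
  loc <- localize_trigger(ep$optical, twin)
  err <- sqrt((loc$origin[1] - ei$site_row)^2 +
              (loc$origin[2] - ei$site_col)^2)
  expect_lte(err, 2)
})

test_that("a constructed focal source classifies as repeated breakthroughs", {
  mv <- synth_movie(nr = 24, nc = 24, n_ms = 1500,
                    at0 = c(105, 405, 705, 1005), delay_per_row = 0,
                    apd = 150)
  # radial delays from a focal source at (12, 12)
  d <- sqrt(outer((1:24 - 12)^2, rep(1, 24)) +
            outer(rep(1, 24), (1:24 - 12)^2))
  for (r in 1:24) for (c in 1:24) {
    sh <- round(d[r, c] * 2)
    x <- mv$frames[r, c, ]
    mv$frames[r, c, ] <- c(numeric(sh), x)[seq_along(x)]
  }
  ph <- compute_phase(mv, c(100, 1450))
  cls <- classify_first_cycles(mv, ph, origin = c(12, 12), start_ms = 380,
                               n_cycles = 3)
  expect_true(all(cls$pattern == "breakthrough"))
  expect_true(all(cls$near_origin))
})
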