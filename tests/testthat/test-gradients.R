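ramp_map <- function(n = 48, slope = 10, angle_deg = 0, dx = 0.39) {
  th <- angle_deg * pi / 180
  R <- outer(seq_len(n), rep(1, n)) * dx
  C <- outer(rep(1, n), seq_len(n)) * dx
  v <- slope * (C * cos(th) + R * sin(th))
  vf_map(v, matrix(TRUE, n, n), "APD80", dx)
}

test_that("gradient magnitude is exact on ramps of any orientation", {
  for (ang in c(0, 30, 45, 60, 90, 137)) {
    g <- local_gradient(ramp_map(angle_deg = ang))
    got <- g$values[g$valid]
    expect_true(all(abs(got - 10) / 10 < 0.01),
                label = sprintf("ramp at %d deg", ang))
  }
})

test_that("a constant map has zero gradient and a fully masked map errors", {
  m <- ramp_map(slope = 0)
  g <- local_gradient(m)
  expect_true(all(abs(g$values[g$valid]) < 1e-9))
  m$valid[] <- FALSE
  expect_error(local_gradient(m), "fully masked")
})

test_that("pixels whose stencil touches invalid pixels are masked", {
  m <- ramp_map()
  m$valid[24, 24] <- FALSE
  m$values[24, 24] <- NA
  g <- local_gradient(m)
  expect_false(any(g$valid[23:25, 23:25]))
  expect_true(g$valid[24, 28])
})

test_that("manual threshold on a step map puts the contour at the step", {
  n <- 48
  v <- matrix(250, n, n)
  v[, 1:20] <- 150
  m <- vf_map(v, matrix(TRUE, n, n), "APD80", 0.39)
  geo <- delineate_border(m, manual_threshold_ms = 200)
  expect_true(all(abs(geo$contour$col - 20.5) < 0.51))
})

test_that("a uniform map cannot be delineated", {
  m <- ramp_map(slope = 0)
  expect_error(delineate_border(m), "manual_threshold_ms")
})

test_that("distance to border matches a brute-force oracle and the 3.5-mm rule", {
  n <- 48
  v <- matrix(250, n, n)
  ctr <- 24.5; rad_px <- 10
  d <- sqrt(outer((seq_len(n) - ctr)^2, rep(1, n)) +
            outer(rep(1, n), (seq_len(n) - ctr)^2))
  v[d < rad_px] <- 150
  m <- vf_map(v, matrix(TRUE, n, n), "APD80", 0.39)
  geo <- delineate_border(m, manual_threshold_ms = 200)
  set.seed(4)
  for (k in 1:100) {
    site <- runif(2, 1, n)
    got <- distance_to_border(site, geo)$distance_mm
    oracle <- Inf
    for (i in seq_len(nrow(geo$contour)))
      oracle <- min(oracle, sqrt((geo$contour$row[i] - site[1])^2 +
                                 (geo$contour$col[i] - site[2])^2) * 0.39)
    expect_lt(abs(got - oracle), 0.39 / 2)
  }
  on_contour <- unlist(geo$contour[1, ])
  db <- distance_to_border(on_contour, geo)
  expect_lt(db$distance_mm, 1e-9)
  expect_true(db$border_zone)
  # boundary-inclusive at a site 3.5 mm from its nearest contour point
  p <- unlist(geo$contour[which.min(geo$contour$row), ])
  site35 <- c(p[1] - 3.5 / 0.39, p[2])
  db35 <- distance_to_border(site35, geo)
  expect_lte(db35$distance_mm, 3.5 + 1e-6)
  expect_true(db35$border_zone)
  # and exclusive just beyond
  site36 <- c(p[1] - 3.65 / 0.39, p[2])
  expect_false(distance_to_border(site36, geo)$border_zone)
})

test_that("nontrigger sampling is seeded and respects clearance", {
  ep <- small_trigger_ep()
  win <- pre_trigger_window(ep$sim)
  maps <- build_maps(ep$optical,
                     data.frame(start_ms = win[1], end_ms = win[2]))[[1]]
  geo <- delineate_border(maps$apd80)
  ga <- local_gradient(maps$apd80)
  s1 <- sample_nontrigger_sites(geo, ga, n = 3, seed = 5, clearance_mm = 4,
                                edge_margin_mm = 2)
  s2 <- sample_nontrigger_sites(geo, ga, n = 3, seed = 5, clearance_mm = 4,
                                edge_margin_mm = 2)
  expect_identical(s1[, c("row", "col")], s2[, c("row", "col")])
  expect_true(all(s1$distance_mm > 4))
  expect_error(sample_nontrigger_sites(geo, ga, n = 3, seed = 1,
                                       clearance_mm = 100),
               "too small|no eligible")
})

test_that("a masked trigger site errors with the nearest valid pixel", {
  m <- ramp_map()
  g <- local_gradient(m)
  geo <- delineate_border(ramp_map() , manual_threshold_ms = 60)
  g$valid[20, 20] <- FALSE
  expect_error(measure_trigger_site(c(20, 20), geo, g), "nearest valid")
})
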