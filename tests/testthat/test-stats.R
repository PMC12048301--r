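test_that("fisher_exact equals the enumeration oracle on random tables", {
  set.seed(10)
  for (k in 1:50) {
    tab <- matrix(rpois(4, 6), 2, 2)
    expect_lt(abs(fisher_exact(tab) - fisher_oracle(tab)), 1e-9)
  }
})

test_that("the incidence table is overwhelmingly significant", {
  p <- fisher_exact(matrix(c(0, 13, 16, 3), 2, 2))
  expect_lt(p, 1e-4)
  expect_lt(abs(p - fisher_oracle(matrix(c(0, 13, 16, 3), 2, 2))), 1e-12)
})

test_that("symmetric and zero-margin tables give p = 1", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, 2)), 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 7, 3), 2, 2)), 1)
})

test_that("Holm-Sidak adjustment is monotone and at least the raw p", {
  set.seed(3)
  p <- runif(12)^2
  adj <- holm_sidak(p)
  expect_true(all(adj >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  # smallest p gets the full-family Sidak correction
  expect_equal(adj[which.min(p)], min(1 - (1 - min(p))^length(p), 1))
})

test_that("test selection follows normality of the samples", {
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50, 0.2)
  expect_match(choose_test(list(a, b))$test, "t test")
  h1 <- rcauchy(60); h2 <- rcauchy(60)
  expect_match(choose_test(list(h1, h2))$test, "rank")
  k3 <- choose_test(list(rnorm(20), rnorm(20), rnorm(20, 1)))
  expect_match(k3$test, "Kruskal")
  expect_equal(nrow(k3$pairwise), 3)
  expect_warning(choose_test(list(c(1, 2), c(2, 3))), "n < 3")
})

test_that("identical groups compare as equal", {
  set.seed(8)
  g <- data.frame(apd_gradient = rnorm(10, 15), rt_gradient = rnorm(10, 15))
  gc <- gradient_comparison(g, g)
  expect_gt(gc$p_apd, 0.9)
  expect_equal(gc$summary$apd_mean[1], gc$summary$apd_mean[2])
  expect_equal(gc$ratio_apd, 1)
  expect_error(gradient_comparison(g[1, ], g), "at least 2")
})

test_that("report rendering is deterministic and complete", {
  eps <- data.frame(start_ms = 1, end_ms = 2, duration_s = 9,
                    sustained = TRUE, spontaneous = TRUE,
                    trigger_onset_ms = 1, trigger_coupling_ms = 300, prep = 1)
  beats <- data.frame(onset_ms = 1, peak_ms = 2, type = "pvc",
                      coupling_ms = 300, prep = 1)
  es <- episode_summary(eps, beats)
  g <- data.frame(apd_gradient = c(14, 16), rt_gradient = c(14, 16))
  gc <- gradient_comparison(g, g + 0.001)
  f1 <- tempfile(); f2 <- tempfile()
  render_report(list(episode_summary = es, gradients = gc, seeds = 1:3), f1)
  render_report(list(episode_summary = es, gradients = gc, seeds = 1:3), f2)
  expect_identical(readLines(f1), readLines(f2))
  txt <- readLines(f1)
  expect_true(any(grepl("mean episodes per preparation", txt)))
  expect_true(any(grepl("trigger", txt)))
})

test_that("an empty study still renders a zero-count report", {
  eps <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                    duration_s = numeric(0), sustained = logical(0),
                    spontaneous = logical(0), trigger_onset_ms = numeric(0),
                    trigger_coupling_ms = numeric(0))
  beats <- data.frame(onset_ms = numeric(0), peak_ms = numeric(0),
                      type = character(0), coupling_ms = numeric(0))
  es <- episode_summary(eps, beats)
  f <- tempfile()
  render_report(list(episode_summary = es), f)
  expect_true(any(grepl("episodes: 0", readLines(f))))
})
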