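# synthetic pseudo-ECG: Gaussian QRS complexes (and optional slow T waves)
synth_ecg <- function(beat_ms, n_ms = max(beat_ms) + 800, qrs_w = 15,
                      t_amp = 0, t_delay = 250, t_w = 60, amp = 1) {
  tt <- seq(0, n_ms - 1)
  x <- numeric(length(tt))
  for (b in beat_ms) {
    x <- x + amp * exp(-((tt - b - 2 * qrs_w) / qrs_w)^2)
    if (t_amp != 0)
      x <- x + t_amp * exp(-((tt - b - t_delay) / t_w)^2)
  }
  structure(list(time_ms = tt, amp = x, dt_ms = 1,
                 pacing = data.frame(time_ms = numeric(0),
                                     kind = character(0),
                                     cycle_ms = numeric(0))),
            class = "vf_ecg")
}

test_that("beat detection is scale- and offset-invariant", {
  e1 <- synth_ecg(seq(100, 4100, by = 500))
  e2 <- e1; e2$amp <- e1$amp * 10 + 3
  b1 <- detect_beats(e1)
  b2 <- detect_beats(e2)
  expect_equal(b1$onset_ms, b2$onset_ms)
  expect_equal(nrow(b1), 9)
  expect_true(all(abs(diff(b1$onset_ms) - 500) <= 2))
})

test_that("a flat record gives an empty beat list with a warning", {
  e <- synth_ecg(numeric(0), n_ms = 6000)
  expect_warning(b <- detect_beats(e), "flat|threshold")
  expect_equal(nrow(b), 0)
})

test_that("a perfectly regular rhythm has no PVCs", {
  b <- detect_beats(synth_ecg(seq(100, 5100, by = 500)))
  b <- classify_pvc(b)
  expect_false(any(b$type == "pvc"))
})

test_that("a premature beat is classified as PVC with its coupling interval", {
  beats <- c(seq(100, 2600, by = 500), 2900, seq(3600, 4600, by = 500))
  b <- classify_pvc(detect_beats(synth_ecg(beats)))
  pvc <- b[b$type == "pvc", ]
  expect_equal(nrow(pvc), 1)
  expect_lt(abs(pvc$coupling_ms - 300), 3)
})

test_that("R-on-T follows the ordering of PVC onset and tangent T-end", {
  e <- synth_ecg(500, n_ms = 1600, t_amp = 0.4, t_delay = 250, t_w = 50)
  te <- twave_end(e, 500, limit_ms = 1500)
  expect_false(is.na(te$t_end_ms))
  expect_gt(te$t_end_ms - 500, 250)      # beyond the T peak
  expect_lt(te$t_end_ms - 500, 450)
  # the early PVC truncates the T wave; the unperturbed beat's T-end
  # offset serves as template, as in the analysis pipeline
  r1 <- twave_overlap(e, 500 + 200, 500,
                      template_offsets_ms = te$t_end_ms - 500)
  r2 <- twave_overlap(e, 500 + 460, 500)
  expect_true(r1$r_on_t)
  expect_false(r2$r_on_t)
})

test_that("a truncated T wave falls back to the template offset", {
  e <- synth_ecg(500, n_ms = 1600, t_amp = 0.4)
  r <- twave_overlap(e, 630, 500, template_offsets_ms = 320)
  expect_identical(r$reason, "template fallback")
  expect_true(r$r_on_t)
})

mk_beats <- function(onsets, types = NULL) {
  data.frame(onset_ms = onsets, peak_ms = onsets + 20,
             type = if (is.null(types)) rep("other", length(onsets)) else types,
             coupling_ms = rep(NA_real_, length(onsets)),
             stringsAsFactors = FALSE)
}

blank_ecg <- function(n_ms, pacing = NULL) {
  structure(list(time_ms = seq(0, n_ms), amp = numeric(n_ms + 1), dt_ms = 1,
                 pacing = pacing %||%
                   data.frame(time_ms = numeric(0), kind = character(0),
                              cycle_ms = numeric(0))),
            class = "vf_ecg")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sustained classification is inclusive at exactly 8 s", {
  # irregular fast run lasting exactly 8.000 s, then silence
  iv <- rep(c(170, 230), 20)           # 40 cycles, 8000 ms, CV 0.15
  on8 <- c(500, 1000, cumsum(c(1500, iv)))
  b <- mk_beats(on8)
  eps <- detect_vf(blank_ecg(12000), b)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$duration_s, 8)
  expect_true(eps$sustained)

  iv79 <- c(rep(c(170, 230), 19), 170, 130)  # 7900 ms
  b2 <- mk_beats(c(500, 1000, cumsum(c(1500, iv79))))
  eps2 <- detect_vf(blank_ecg(12000), b2)
  expect_equal(eps2$duration_s, 7.9)
  expect_false(eps2$sustained)
})

test_that("regular fast pacing is not called VF (irregularity criterion)", {
  b <- mk_beats(seq(500, 8500, by = 200))
  eps <- detect_vf(blank_ecg(9000), b)
  expect_equal(nrow(eps), 0)
})

test_that("spontaneity is exact at the 2-Hz boundary and vetoed by extras", {
  iv <- rep(c(170, 230), 12)
  onsets <- c(seq(500, 3000, by = 500), cumsum(c(3300, iv)))
  b <- mk_beats(onsets)
  vf_on <- 3300
  pace_2hz <- data.frame(time_ms = seq(500, 3000, by = 500), kind = "paced",
                         cycle_ms = 500)
  e <- blank_ecg(12000, pace_2hz)
  eps <- detect_vf(e, b)
  expect_true(eps$spontaneous[1])
  pace_fast <- data.frame(time_ms = seq(500, 3000, by = 497.5),
                          kind = "paced", cycle_ms = 497.5)
  e2 <- blank_ecg(12000, pace_fast)
  expect_false(detect_vf(e2, b)$spontaneous[1])
  pace_extra <- rbind(pace_2hz,
                      data.frame(time_ms = vf_on - 500, kind = "extra",
                                 cycle_ms = NA))
  e3 <- blank_ecg(12000, pace_extra)
  expect_false(detect_vf(e3, b)$spontaneous[1])
})

test_that("the VF trigger is the last PVC at or before onset", {
  iv <- rep(c(170, 230), 12)
  onsets <- c(seq(500, 2500, by = 500), cumsum(c(2800, iv)))
  types <- c(rep("paced", 5), "pvc", rep("other", length(iv)))
  b <- mk_beats(onsets, types)
  b$coupling_ms[6] <- 300
  eps <- detect_vf(blank_ecg(10000), b)
  expect_equal(eps$trigger_onset_ms[1], 2800)
  expect_equal(eps$trigger_coupling_ms[1], 300)
})

test_that("episode summaries equal a brute-force tally", {
  set.seed(2)
  eps <- data.frame(
    start_ms = runif(74, 0, 1e5), end_ms = NA, duration_s = runif(74, 1, 20),
    sustained = NA, spontaneous = TRUE,
    trigger_onset_ms = NA, trigger_coupling_ms = NA,
    prep = sample(1:16, 74, replace = TRUE))
  eps$sustained <- eps$duration_s >= 8
  beats <- mk_beats(numeric(0))
  beats$prep <- integer(0)
  s <- episode_summary(eps, beats)
  expect_equal(s$counts$n_spont_vf, 74)
  expect_equal(s$counts$n_preparations, 16)
  expect_equal(s$counts$mean_per_prep, 74 / 16)
  expect_equal(s$counts$mean_per_prep_rounded, 5)
  expect_equal(sum(s$per_prep$n_spont_vf), 74)
  for (p in 1:16)
    expect_equal(s$per_prep$n_spont_vf[s$per_prep$prep == p],
                 sum(eps$prep == p))
})

test_that("an empty study gives an all-zero summary", {
  eps <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                    duration_s = numeric(0), sustained = logical(0),
                    spontaneous = logical(0),
                    trigger_onset_ms = numeric(0),
                    trigger_coupling_ms = numeric(0))
  s <- episode_summary(eps, mk_beats(numeric(0)))
  expect_equal(s$counts$n_spont_vf, 0)
})
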