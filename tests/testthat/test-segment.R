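test_that("a constant valid series yields all-zero normalized segments", {
  n <- 2000
  s <- make_series(HbO2 = rep(60, n), HHb = rep(25, n))
  seg <- segment_events(s, make_events(c(20, 60, 120)))
  expect_equal(dim(seg$normalized)[2], floor(6 * 10.4))
  expect_true(all(seg$normalized == 0))
  sm <- apply_event_qc(seg)
  expect_true(all(sm$kept))
  expect_true(all(sm$mean_pct == 0))
})

test_that("one noise-free evoked response reads back as its window mean", {
  sch <- make_session_schedule("cTBS", "s01", 1L)
  sch$events <- make_events(50)
  hrf <- hrf_model()
  tis <- simulate_chromophores(sch, hrf, noise_model_silent(), tail = 30)
  s <- as_chromophore_series(tis)
  seg <- segment_events(s, sch$events)
  sm <- apply_event_qc(seg)
  got <- sm$mean_pct[sm$signal == "BV"]
  # oracle: numerically integrate the kernel over the window
  expected <- 14 * stats::integrate(function(t) hrf_kernel(hrf, t), 0, 6,
                                    rel.tol = 1e-10)$value / 6
  expect_equal(got, expected, tolerance = 0.01)
  # HbO2 and HHb split 80/20 of the tHb excursion, but in percent of their
  # own baselines (60 and 25 uM)
  expect_equal(sm$mean_pct[sm$signal == "HbO2"],
               expected * 0.8 * 85 / 60, tolerance = 0.01)
  expect_equal(sm$mean_pct[sm$signal == "HHb"],
               expected * 0.2 * 85 / 25, tolerance = 0.01)
})

test_that("normalization is invariant to a common scale factor", {
  sch <- make_session_schedule("cTBS", "s01", 1L)
  sch$events <- make_events(c(50, 60))
  tis1 <- simulate_chromophores(sch, hrf = hrf_model(),
                                noise = noise_model_silent(),
                                baseline = c(HbO2 = 60, HHb = 25), tail = 30)
  tis2 <- simulate_chromophores(sch, hrf = hrf_model(),
                                noise = noise_model_silent(),
                                baseline = c(HbO2 = 120, HHb = 50), tail = 30)
  s1 <- segment_events(as_chromophore_series(tis1), sch$events)
  s2 <- segment_events(as_chromophore_series(tis2), sch$events)
  expect_equal(s1$normalized, s2$normalized, tolerance = 1e-10)
})

test_that("events too close to the recording end are dropped with a reason", {
  n <- 1000  # 96 s
  s <- make_series(HbO2 = rep(60, n), HHb = rep(25, n))
  seg <- segment_events(s, make_events(c(10, 95)))
  expect_false(seg$events$dropped[1])
  expect_true(seg$events$dropped[2])
  expect_match(seg$events$reason[2], "beyond recording")
  sm <- apply_event_qc(seg)
  expect_false(any(sm$kept[sm$onset == 95]))
})

test_that("near-zero baselines trip the stability guard", {
  n <- 1000
  s <- make_series(HbO2 = rep(1e-4, n), HHb = rep(-1e-4, n))  # tHb ~ 0
  seg <- segment_events(s, make_events(10))
  expect_true(seg$events$dropped[1])
  expect_equal(seg$events$reason[1], "unstable baseline")
})

test_that("pre-window baseline mode averages the half second before onset", {
  n <- 1000
  x <- rep(60, n)
  fs <- 10.4
  i0 <- round(20 * fs) + 1
  x[(i0 - 5):(i0 - 1)] <- 61   # only pre-onset samples differ
  s <- make_series(HbO2 = x, HHb = rep(25, n))
  seg_on <- segment_events(s, make_events(20), baseline_mode = "onset-sample")
  seg_pre <- segment_events(s, make_events(20), baseline_mode = "pre-window")
  expect_equal(seg_on$events$baseline_HbO2[1], 60)
  expect_gt(seg_pre$events$baseline_HbO2[1], 60)
  # with onset-sample baseline the window is unchanged, hence all zeros
  expect_true(all(seg_on$normalized[1, , "HbO2"] == 0))
})

test_that("the more-than-one-third invalid rule and artifact overlap discard", {
  n <- 2000
  nwin <- floor(6 * 10.4)
  onsets <- seq(10, 150, by = 10)
  valid <- rep(TRUE, n)
  # event at 30 s: exactly half the window invalid -> discard
  i30 <- round(30 * 10.4) + 1
  valid[i30 + seq_len(floor(nwin / 2))] <- FALSE
  # event at 50 s: one quarter invalid -> kept (1/4 < 1/3)
  i50 <- round(50 * 10.4) + 1
  valid[i50 + seq_len(floor(nwin / 4))] <- FALSE
  s <- make_series(HbO2 = rep(60, n), HHb = rep(25, n), valid = valid)
  seg <- segment_events(s, make_events(onsets))
  aw <- matrix(c(100, 101), ncol = 2)  # overlaps the event at 100 s
  sm <- apply_event_qc(seg, artifact_windows = aw)
  bv <- sm[sm$signal == "BV", ]
  expect_false(bv$kept[bv$onset == 30])
  expect_match(bv$reason[bv$onset == 30], "1/3")
  expect_true(bv$kept[bv$onset == 50])
  expect_false(bv$kept[bv$onset == 100])
  expect_match(bv$reason[bv$onset == 100], "artifact")
  expect_true(all(bv$kept[!bv$onset %in% c(30, 100)]))
})

test_that("artifact-overlap counting discards exactly the constructed events", {
  n <- 11000  # > 1005 s
  s <- make_series(HbO2 = rep(60, n), HHb = rep(25, n))
  onsets <- seq(5, by = 10, length.out = 100)
  seg <- segment_events(s, make_events(onsets))
  # artifact windows overlapping exactly the first 40 events
  aw <- cbind(onsets[1:40] + 1, onsets[1:40] + 1.5)
  sm <- apply_event_qc(seg, artifact_windows = aw)
  bv <- sm[sm$signal == "BV", ]
  expect_equal(sum(bv$kept), 60)
  expect_equal(sum(!bv$kept), 40)
  expect_true(all(bv$onset[!bv$kept] %in% onsets[1:40]))
})

test_that("invalid baseline samples drop the segment", {
  n <- 1000
  valid <- rep(TRUE, n)
  i0 <- round(20 * 10.4) + 1
  valid[i0] <- FALSE
  s <- make_series(HbO2 = rep(60, n), HHb = rep(25, n), valid = valid)
  seg <- segment_events(s, make_events(c(20, 40)))
  expect_true(seg$events$dropped[1])
  expect_equal(seg$events$reason[1], "invalid baseline")
  expect_false(seg$events$dropped[2])
})

test_that("filtered null sessions keep all-zero summaries end to end", {
  sch <- make_session_schedule("cTBS", "s01", 2L,
                               n_pre_blocks = 1L, n_post_blocks = 1L,
                               n_real = 5L, n_sham = 5L)
  hrf0 <- hrf_model(amplitudes = data.frame(modality = "real", epoch = "post",
                                            paradigm = "cTBS", amplitude = 0))
  tis <- simulate_chromophores(sch, hrf0, noise_model_silent())
  s <- as_chromophore_series(tis)
  y <- apply_filter(s, design_bandpass())
  sm <- apply_event_qc(segment_events(y, sch$events))
  expect_true(any(sm$kept))
  expect_true(all(abs(sm$mean_pct[sm$kept]) < 1e-9))
})
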