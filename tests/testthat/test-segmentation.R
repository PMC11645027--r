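test_that("prominent trough detection matches a constructed trace", {
  # Two deep troughs plus one shallow dip on a flat baseline.
  t <- (0:499) / 50
  x <- -60 * exp(-((t - 3)^2) / 0.05) - 50 * exp(-((t - 6)^2) / 0.05) -
    5 * exp(-((t - 8)^2) / 0.05)
  found <- detect_transition_minima(x, 50, segmentation_config(min_prominence = 20))
  expect_length(found, 2)
  expect_equal((found - 1) / 50, c(3, 6), tolerance = 0.05)
})

test_that("flat or empty traces yield no detections, not errors", {
  expect_identical(detect_transition_minima(rep(1, 100), 50), integer())
  expect_identical(detect_transition_minima(numeric(0), 50), integer())
})

test_that("raising the prominence threshold never finds more minima", {
  pre <- small_segmented()$pre
  counts <- vapply(c(5, 10, 20, 40, 60, 90), function(pr) {
    length(detect_transition_minima(pre$gyr_pitch, 50,
                                    segmentation_config(min_prominence = pr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("close troughs are thinned to the more prominent one", {
  t <- (0:299) / 50
  x <- -60 * exp(-((t - 2)^2) / 0.02) - 40 * exp(-((t - 2.2)^2) / 0.02)
  found <- detect_transition_minima(x, 50,
    segmentation_config(min_prominence = 10, min_separation_s = 0.5))
  expect_length(found, 1)
  expect_equal((found - 1) / 50, 2, tolerance = 0.05)
})

test_that("detected events match generator ground truth within 0.2 s", {
  pre <- small_segmented()$pre
  minima <- detect_transition_minima(pre$gyr_pitch, sample_rate(pre))
  ev <- ground_truth_events(pre)
  expect_equal(length(minima), nrow(ev))
  expect_lt(max(abs((minima - 1) / sample_rate(pre) - ev$time_s)), 0.2)
})

test_that("ten minima build 5 SiSt + 5 StSi + 5 SSS + 1 FTSTS segments", {
  segs <- small_segmented()$segs
  expect_equal(as.vector(table(segs$kind)), c(5, 5, 5, 1))
  expect_true(all(segs$start_index < segs$end_index))
  expect_true(all(segs$start_index >= 1))
  expect_true(all(segs$end_index <= nrow(small_segmented()$pre)))
})

test_that("a single cycle builds one segment of each kind", {
  rec <- simulate_ftsts(kinematic_params("Young", tremor_noise_sd = 0),
                        n_cycles = 1, seed = 13)
  pre <- preprocess_recording(rec)
  segs <- segment_recording(pre)
  expect_equal(as.vector(table(segs$kind)), c(1, 1, 1, 1))
})

test_that("SSS spans its SiSt start to its StSi end; FTSTS spans the test", {
  segs <- small_segmented()$segs
  for (k in 1:5) {
    sist <- segs[segs$kind == "SiSt" & segs$repetition == k, ]
    stsi <- segs[segs$kind == "StSi" & segs$repetition == k, ]
    sss <- segs[segs$kind == "SSS" & segs$repetition == k, ]
    expect_equal(sss$start_index, sist$start_index)
    expect_equal(sss$end_index, stsi$end_index)
  }
  ftsts <- segs[segs$kind == "FTSTS", ]
  expect_equal(ftsts$start_index, min(segs$start_index[segs$kind == "SiSt"]))
  expect_equal(ftsts$end_index, max(segs$end_index[segs$kind == "StSi"]))
})

test_that("same-kind segments do not overlap and sit inside the test window", {
  segs <- small_segmented()$segs
  for (kind in c("SiSt", "StSi", "SSS")) {
    s <- segs[segs$kind == kind, ]
    s <- s[order(s$start_index), ]
    if (kind != "SSS") {
      expect_true(all(s$start_index[-1] > s$end_index[-nrow(s)]))
    }
  }
  ftsts <- segs[segs$kind == "FTSTS", ]
  inner <- segs[segs$kind != "FTSTS", ]
  expect_true(all(inner$start_index >= ftsts$start_index))
  expect_true(all(inner$end_index <= ftsts$end_index))
})

test_that("odd trailing events are dropped with a warning; none is an error", {
  pre <- small_segmented()$pre
  minima <- detect_transition_minima(pre$gyr_pitch, 50)
  expect_warning(segs <- build_segments(pre, minima[1:9]), "trailing")
  expect_equal(sum(segs$kind == "SiSt"), 4)
  expect_error(build_segments(pre, integer()), "cannot segment")
})

test_that("noise-free event recovery is exact (recall and precision 1)", {
  rec <- simulate_ftsts(kinematic_params("Stage1", tremor_noise_sd = 0),
                        n_cycles = 5, seed = 17)
  pre <- preprocess_recording(rec)
  minima <- detect_transition_minima(pre$gyr_pitch, 50)
  ev <- ground_truth_events(pre)
  expect_equal(length(minima), nrow(ev)) # no spurious, none missed
  expect_lt(max(abs((minima - 1) / 50 - ev$time_s)), 0.1)
})
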