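test_that("resultant is the elementwise Euclidean norm", {
  expect_equal(resultant(0.6, 0.8, 0), 1)
  expect_equal(resultant(0, 0, 0), 0)
  expect_equal(resultant(1, 2, 2), 3)
  expect_error(resultant(1:3, 1:2, 1:3), "equal lengths")
})

test_that("duration divides sample count by rate", {
  expect_equal(duration(numeric(150), 50), 3)
  expect_equal(duration(numeric(50), 50), 1)
  expect_error(duration(numeric(0), 50), "empty")
})

test_that("range matches a brute-force scan on random input", {
  set.seed(3)
  x <- rnorm(100)
  brute <- -Inf
  brute_min <- Inf
  for (v in x) {
    if (v > brute) brute <- v
    if (v < brute_min) brute_min <- v
  }
  expect_equal(range_acc(x), brute - brute_min)
  expect_equal(range_acc(c(-0.5, 1.0, 0.25)), 1.5)
  expect_equal(range_acc(rep(2, 10)), 0)
})

test_that("rms matches closed forms", {
  expect_equal(rms(rep(2, 17)), 2)
  expect_equal(rms(c(1, -1, 1, -1)), 1)
  # sine of amplitude A over integer periods -> A / sqrt(2)
  a <- 2.5
  x <- a * sin(2 * pi * 3 * (0:599) / 100) # 3 Hz, 6 s, whole periods
  expect_equal(rms(x), a / sqrt(2), tolerance = 1e-6)
})

test_that("amax equals the maximum of the composed resultant", {
  set.seed(4)
  ml <- rnorm(64)
  ap <- rnorm(64)
  si <- rnorm(64)
  expect_equal(amax(resultant(ml, ap, si)), max(sqrt(ml^2 + ap^2 + si^2)))
  expect_equal(amax(c(0, 3, 1)), 3)
  expect_equal(amax(numeric(5)), 0)
})

test_that("jerk matches closed forms and vanishes for constants", {
  expect_equal(jerk(rep(1.3, 40), T_s = 2), 0)
  # linear ramp with step d: (N-1) d^2 / T
  d <- 0.25
  N <- 30
  expect_equal(jerk(d * (0:(N - 1)), T_s = 1.5), (N - 1) * d^2 / 1.5)
  # alternating +-a: (N-1) (2a)^2 / T
  a <- 0.8
  x <- a * rep(c(1, -1), length.out = 20)
  expect_equal(jerk(x, T_s = 0.4), 19 * (2 * a)^2 / 0.4)
  expect_error(jerk(1, T_s = 1), "at least 2")
})

test_that("total power agrees with a direct O(N^2) DFT oracle", {
  set.seed(5)
  x <- rnorm(64)
  spec_dft <- Mod(direct_dft(x))^2
  oracle <- sum(spec_dft[2:33]) # one-sided, DC excluded, Nyquist included
  expect_equal(total_power(x, 50), oracle, tolerance = 1e-8)
  expect_equal(total_power(numeric(32), 50), 0)
})

test_that("a pure tone concentrates its power in the right bin", {
  # 4 Hz tone, rate 64 Hz, 256 samples: exactly on the DFT grid.
  x <- sin(2 * pi * 4 * (0:255) / 64)
  sp <- power_spectrum(x, 64)
  peak <- which.max(sp$power)
  expect_equal(sp$freq[peak], 4)
  window <- sp$power[max(1, peak - 1):min(nrow(sp), peak + 1)]
  expect_gt(sum(window) / sum(sp$power), 0.99)
})

test_that("spectral edge frequencies match a cumulative-spectrum oracle", {
  tt <- (0:255) / 64
  tone <- sin(2 * pi * 2 * tt)
  expect_equal(sef(tone, 64, 0.5), 2)
  expect_equal(sef(tone, 64, 0.95), 2)
  two <- sin(2 * pi * 1 * tt) + sin(2 * pi * 4 * tt) # equal-power tones
  expect_equal(sef(two, 64, 0.5), 1)
  expect_equal(sef(two, 64, 0.95), 4)
  # independent oracle: brute-force cumulative sum over the DFT
  spec_dft <- Mod(direct_dft(two))^2
  one_sided <- spec_dft[2:129]
  freqs <- (1:128) * 64 / 256
  cum <- cumsum(one_sided) / sum(one_sided)
  expect_equal(sef(two, 64, 0.5), freqs[which(cum >= 0.5 - 1e-9)[1]])
  expect_error(sef(numeric(32), 50, 0.5), "zero-power")
  expect_lte(sef(two, 64, 0.5), sef(two, 64, 0.95))
})

test_that("aggregation returns mean and sample CV with undefined flags", {
  expect_equal(aggregate_segments(c(2, 2, 2)), list(mean = 2, cv = 0))
  agg <- aggregate_segments(c(1, 3))
  expect_equal(agg$mean, 2)
  expect_equal(agg$cv, sqrt(2) / 2, tolerance = 1e-12)
  single <- aggregate_segments(5)
  expect_equal(single$mean, 5)
  expect_true(is.na(single$cv))
  zero <- aggregate_segments(c(-1, 1))
  expect_true(is.na(zero$cv)) # zero mean: CV undefined, not NaN
})

test_that("a five-cycle recording yields exactly 144 primary metrics", {
  fx <- small_segmented()
  fv <- extract_features(fx$pre, fx$segs)
  primary <- names(fv)[!startsWith(names(fv), "cv_")]
  expect_length(primary, 144)
  expect_true(all(is.finite(unlist(fv[primary]))))
  # 4 contexts x 4 channels x 9 metrics, all named
  expect_equal(sum(startsWith(primary, "FTSTS_")), 36)
  expect_equal(sum(grepl("_RES_", primary)), 36)
  expect_equal(sum(endsWith(primary, "_sef95")), 16)
  # SEF bounded by Nyquist, durations positive
  expect_true(all(unlist(fv[primary[grepl("_sef", primary)]]) <= 25))
  expect_true(all(unlist(fv[primary[endsWith(primary, "_duration")]]) > 0))
})

test_that("single-cycle features still count 144 with undefined CVs", {
  rec <- simulate_ftsts(kinematic_params("Young"), n_cycles = 1, seed = 19)
  pre <- preprocess_recording(rec)
  fv <- extract_features(pre, segment_recording(pre))
  expect_length(names(fv)[!startsWith(names(fv), "cv_")], 144)
  expect_true(all(is.na(unlist(fv[startsWith(names(fv), "cv_")]))))
})

test_that("whole-test maxima are compositional", {
  fx <- small_segmented()
  fv <- extract_features(fx$pre, fx$segs)
  ftsts <- fx$segs[fx$segs$kind == "FTSTS", ]
  idx <- ftsts$start_index:ftsts$end_index
  res <- resultant(fx$pre$acc_ml[idx], fx$pre$acc_ap[idx], fx$pre$acc_si[idx])
  expect_equal(fv$FTSTS_RES_max, max(res))
  expect_equal(fv$FTSTS_RES_amax, amax(res))
  expect_equal(fv$FTSTS_ML_duration, length(idx) / 50)
})

test_that("the feature map is scale-equivariant", {
  fx <- small_segmented()
  pre <- fx$pre
  c_scale <- 2.5
  scaled_df <- as.data.frame(pre)
  for (ch in c("acc_ml", "acc_ap", "acc_si")) {
    scaled_df[[ch]] <- c_scale * scaled_df[[ch]]
  }
  scaled <- imu_recording(scaled_df, 50, events = ground_truth_events(pre))
  f1 <- extract_features(pre, fx$segs)
  f2 <- extract_features(scaled, fx$segs)
  linear <- grepl("_(max|range|rms|amax)$", names(f1)) &
    !startsWith(names(f1), "cv_")
  quad <- grepl("_(jerk|total_power)$", names(f1)) &
    !startsWith(names(f1), "cv_")
  invariant <- grepl("_(duration|sef50|sef95)$", names(f1)) &
    !startsWith(names(f1), "cv_")
  expect_equal(unlist(f2[linear]), c_scale * unlist(f1[linear]))
  expect_equal(unlist(f2[quad]), c_scale^2 * unlist(f1[quad]))
  expect_equal(unlist(f2[invariant]), unlist(f1[invariant]))
})

test_that("compact layout drops replicated duration and amax copies", {
  fx <- small_segmented()
  fv <- extract_features(fx$pre, fx$segs, layout = "compact")
  primary <- names(fv)[!startsWith(names(fv), "cv_")]
  expect_length(primary, 120) # 4 x (2 + 7 x 4)
})

test_that("Parseval-style identity holds on real segment data", {
  fx <- small_segmented()
  segs <- fx$segs[fx$segs$kind == "SiSt", ]
  for (i in seq_len(nrow(segs))) {
    x <- fx$pre$acc_ap[segs$start_index[i]:segs$end_index[i]]
    np <- 2^ceiling(log2(length(x)))
    padded <- c(x, numeric(np - length(x)))
    spec_dft <- Mod(direct_dft(padded))^2
    oracle <- sum(spec_dft[2:(np / 2 + 1)])
    expect_equal(total_power(x, 50), oracle, tolerance = 1e-8)
  }
})

test_that("mean transition duration rises with stage on generator defaults", {
  feats <- purrr::map_dfr(c("Young", "NonLS", "Stage1", "Stage2"), function(g) {
    rec <- simulate_ftsts(kinematic_params(g), seed = 31)
    pre <- preprocess_recording(rec)
    fv <- extract_features(pre, segment_recording(pre))
    tibble::tibble(group = g, sist_dur = fv$SiSt_ML_duration)
  })
  expect_true(all(diff(feats$sist_dur) > 0))
})
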