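# Shared fixtures, built in code at test time.

# A flat tibble wrapping six channels into a recording.
make_recording <- function(n = 200, rate = 100, fill = 0) {
  t <- (seq_len(n) - 1) / rate
  imu_recording(
    tibble::tibble(
      t = t,
      acc_ml = rep(fill, n), acc_ap = rep(fill, n), acc_si = rep(fill, n),
      gyr_roll = rep(fill, n), gyr_pitch = rep(fill, n), gyr_yaw = rep(fill, n)
    ),
    sample_rate_hz = rate
  )
}

# Recording whose channels are supplied vectors (recycled to max length).
make_recording_from <- function(rate = 100, ...) {
  chans <- list(...)
  n <- max(lengths(chans))
  full <- list(
    acc_ml = numeric(n), acc_ap = numeric(n), acc_si = numeric(n),
    gyr_roll = numeric(n), gyr_pitch = numeric(n), gyr_yaw = numeric(n)
  )
  for (nm in names(chans)) full[[nm]] <- rep_len(chans[[nm]], n)
  imu_recording(
    tibble::as_tibble(c(list(t = (seq_len(n) - 1) / rate), full)),
    sample_rate_hz = rate
  )
}

# A well-separated Gaussian-blob feature table: class k's centre sits at
# sep * k along every (sign-alternating) axis, so the separation survives
# standardization in all dimensions.
make_blobs <- function(n_per_class = 20, n_classes = 2, p = 4, sep = 6,
                       seed = 1) {
  set.seed(seed)
  signs <- rep(c(1, -1), length.out = p)
  purrr::map_dfr(seq_len(n_classes), function(k) {
    m <- matrix(rnorm(n_per_class * p), n_per_class, p)
    m <- sweep(m, 2, signs * sep * k, "+")
    out <- tibble::as_tibble(as.data.frame(m))
    names(out) <- paste0("f", seq_len(p))
    out$group <- factor(paste0("c", k),
                        levels = paste0("c", seq_len(n_classes)))
    out
  })
}

# A small preprocessed recording plus its segments, shared across tests.
small_segmented <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- simulate_ftsts(kinematic_params("NonLS"), seed = 7)
      pre <- preprocess_recording(rec)
      cache <<- list(pre = pre, segs = segment_recording(pre))
    }
    cache
  }
})

# Direct O(N^2) DFT, the independent oracle for the FFT-based spectra.
direct_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))
  }, complex(1))
}
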