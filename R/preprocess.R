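#' Preprocessing configuration
#'
#' Settings for [preprocess_recording()]: resample to `target_rate_hz`
#' (default 50 Hz) and low-pass filter with a Butterworth filter of
#' `filter_order` (default 3) at `cutoff_hz` (default 5 Hz). Zero-phase
#' (forward-backward) filtering is the default so that event timing is
#' preserved; `zero_phase = FALSE` gives the causal single-pass filter.
#'
#' @param target_rate_hz Output sampling rate, Hz.
#' @param filter_order Butterworth filter order.
#' @param cutoff_hz Low-pass cut-off frequency, Hz; must be below the
#'   output Nyquist frequency.
#' @param zero_phase Use forward-backward filtering (no group delay)?
#'
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate_hz = 50, filter_order = 3,
                              cutoff_hz = 5, zero_phase = TRUE) {
  assert_scalar_number(target_rate_hz, "target_rate_hz", 0, strict_lower = TRUE)
  assert_scalar_number(filter_order, "filter_order", 1)
  assert_scalar_number(cutoff_hz, "cutoff_hz", 0, strict_lower = TRUE)
  if (cutoff_hz >= target_rate_hz / 2) {
    abort("`cutoff_hz` must be below the output Nyquist frequency (target_rate_hz / 2).")
  }
  structure(
    list(
      target_rate_hz = target_rate_hz, filter_order = as.integer(filter_order),
      cutoff_hz = cutoff_hz, zero_phase = isTRUE(zero_phase)
    ),
    class = "preprocess_config"
  )
}

#' Remove the constant offset of a signal
#'
#' Subtracts the mean of the whole signal, eliminating constant offsets
#' (e.g. a gravity projection on an acceleration axis) so analysis
#' focuses on the dynamic component. Idempotent.
#'
#' @param signal Numeric vector, length >= 1.
#' @return The signal minus its mean.
#' @examples
#' zero_center(c(1, 2, 3))
#' @export
zero_center <- function(signal) {
  if (length(signal) < 1 || !is.numeric(signal)) {
    abort("`signal` must be a nonempty numeric vector.")
  }
  signal - mean(signal)
}

# Zero-phase filtering with odd reflection padding at both ends, which
# suppresses the startup transients of plain forward-backward filtering.
filtfilt_padded <- function(bf, y) {
  pad <- min(length(y) - 1, 3 * (length(bf$b) + length(bf$a)))
  head_pad <- 2 * y[1] - y[seq(pad + 1, 2)]
  tail_pad <- 2 * y[length(y)] - y[seq(length(y) - 1, length(y) - pad)]
  z <- signal::filtfilt(bf, c(head_pad, y, tail_pad))
  z[seq(pad + 1, pad + length(y))]
}

#' Resample a recording to a new rate
#'
#' Resamples all six channels onto the new time grid. Downsampling is
#' preceded by a zero-phase 8th-order Butterworth anti-alias filter at
#' 90% of the new Nyquist frequency; samples are then interpolated with
#' a cubic spline at the new timestamps, so there is no group delay.
#' Ground-truth event times are carried over unchanged, since they live
#' on the time axis, not on sample indices.
#'
#' @param recording An [imu_recording()].
#' @param target_rate_hz New sampling rate, Hz.
#' @return An [imu_recording()] at the new rate, same duration to within
#'   one output sample.
#' @export
resample_recording <- function(recording, target_rate_hz) {
  stopifnot(inherits(recording, "imu_recording"))
  assert_scalar_number(target_rate_hz, "target_rate_hz", 0, strict_lower = TRUE)
  src <- sample_rate(recording)
  if (isTRUE(all.equal(src, target_rate_hz))) {
    return(recording)
  }
  chans <- c("acc_ml", "acc_ap", "acc_si", "gyr_roll", "gyr_pitch", "gyr_yaw")
  t_old <- recording$t
  n_out <- round(nrow(recording) * target_rate_hz / src)
  t_new <- (seq_len(n_out) - 1) / target_rate_hz

  anti_alias <- NULL
  if (target_rate_hz < src) {
    anti_alias <- signal::butter(8, 0.9 * target_rate_hz / src, type = "low")
  }
  out <- purrr::map(chans, function(ch) {
    y <- recording[[ch]]
    if (!is.null(anti_alias)) y <- filtfilt_padded(anti_alias, y)
    stats::spline(t_old, y, xout = t_new, method = "natural")$y
  })
  names(out) <- chans
  df <- tibble::as_tibble(out)
  df$t <- t_new
  rebuild_recording(recording, df, sample_rate_hz = target_rate_hz)
}

#' Butterworth low-pass filter a signal
#'
#' Applies the configured Butterworth low-pass filter. With
#' `zero_phase = TRUE` the filter runs forward and backward
#' (`signal::filtfilt`), doubling the effective attenuation and removing
#' group delay.
#'
#' @param signal Numeric vector; must be longer than 3 x filter order.
#' @param rate_hz Sampling rate of `signal`, Hz.
#' @param config A [preprocess_config()] (its `target_rate_hz` is ignored
#'   here; `rate_hz` governs the normalized cut-off).
#' @return Filtered signal, same length.
#' @export
lowpass <- function(signal, rate_hz, config = preprocess_config()) {
  min_len <- 3 * config$filter_order + 1
  if (length(signal) < min_len) {
    abort(sprintf("`signal` must have at least %d samples for a %d-order filter.",
                  min_len, config$filter_order))
  }
  if (config$cutoff_hz >= rate_hz / 2) {
    abort("Filter cut-off must be below the Nyquist frequency of `signal`.")
  }
  bf <- signal::butter(config$filter_order, config$cutoff_hz / (rate_hz / 2),
                       type = "low")
  if (config$zero_phase) {
    filtfilt_padded(bf, signal)
  } else {
    as.numeric(signal::filter(bf, signal))
  }
}

#' Condition a raw recording for segmentation and feature extraction
#'
#' Runs the standard conditioning chain in order: per-channel
#' zero-centering over the whole recording, resampling to the target rate,
#' then Butterworth low-pass filtering of all six channels.
#'
#' @param recording An [imu_recording()].
#' @param config A [preprocess_config()].
#' @return A conditioned [imu_recording()] at `config$target_rate_hz`.
#' @examples
#' rec <- simulate_ftsts(seed = 1)
#' pre <- preprocess_recording(rec)
#' sample_rate(pre)
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "imu_recording"))
  chans <- c("acc_ml", "acc_ap", "acc_si", "gyr_roll", "gyr_pitch", "gyr_yaw")

  centred <- as.data.frame(recording)
  for (ch in chans) centred[[ch]] <- zero_center(centred[[ch]])
  rec <- rebuild_recording(recording, centred)

  rec <- resample_recording(rec, config$target_rate_hz)

  filtered <- as.data.frame(rec)
  for (ch in chans) {
    filtered[[ch]] <- lowpass(filtered[[ch]], config$target_rate_hz, config)
  }
  rebuild_recording(rec, filtered)
}
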