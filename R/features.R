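#' Resultant acceleration magnitude
#'
#' Elementwise Euclidean norm of the three acceleration axes:
#' `sqrt(ml^2 + ap^2 + si^2)`. A composite measure of total body
#' acceleration during a transition.
#'
#' @param ml,ap,si Numeric vectors of equal length (m/s^2).
#' @return Nonnegative numeric vector of the same length.
#' @examples
#' resultant(0.6, 0.8, 0)
#' @export
resultant <- function(ml, ap, si) {
  if (length(ml) != length(ap) || length(ap) != length(si)) {
    abort("`ml`, `ap` and `si` must have equal lengths.")
  }
  sqrt(ml^2 + ap^2 + si^2)
}

#' Time-domain segment metrics
#'
#' `duration()` is the segment length divided by the sampling rate;
#' `range_acc()` the max-minus-min excursion; `rms()` the root mean
#' square; `amax()` the maximum of the resultant magnitude; `jerk()` the
#' smoothness metric: the sum of squared consecutive sample differences
#' divided by the segment duration `T` (reported in m^2/s^5 for
#' accelerations in m/s^2).
#'
#' @param x Numeric vector of segment samples.
#' @param rate_hz Sampling rate, Hz.
#' @param res Resultant magnitude samples of the segment.
#' @param T_s Segment duration in seconds.
#' @name segment_metrics
#' @examples
#' duration(rep(0, 150), 50)
#' jerk(c(0, 1, 2, 3), T_s = 1)
NULL

#' @rdname segment_metrics
#' @export
duration <- function(x, rate_hz) {
  if (length(x) == 0) abort("Cannot take the duration of an empty segment.")
  assert_scalar_number(rate_hz, "rate_hz", 0, strict_lower = TRUE)
  length(x) / rate_hz
}

#' @rdname segment_metrics
#' @export
range_acc <- function(x) {
  if (length(x) == 0) abort("Cannot take the range of an empty segment.")
  max(x) - min(x)
}

#' @rdname segment_metrics
#' @export
rms <- function(x) {
  if (length(x) == 0) abort("Cannot take the RMS of an empty segment.")
  sqrt(mean(x^2))
}

#' @rdname segment_metrics
#' @export
amax <- function(res) {
  if (length(res) == 0) abort("Cannot take the maximum of an empty segment.")
  max(res)
}

#' @rdname segment_metrics
#' @export
jerk <- function(x, T_s) {
  if (length(x) < 2) abort("Jerk needs at least 2 samples.")
  assert_scalar_number(T_s, "T_s", 0, strict_lower = TRUE)
  sum(diff(x)^2) / T_s
}

#' One-sided power spectrum of a segment
#'
#' Computes the discrete Fourier transform of the segment zero-padded to
#' the next power of two, without windowing, and returns the one-sided
#' spectrum with the DC bin excluded (segments are zero-centred at the
#' recording level, so the residual DC offset carries no movement
#' information).
#'
#' @param x Numeric vector of segment samples.
#' @param rate_hz Sampling rate, Hz.
#' @return A tibble with columns `freq` (Hz) and `power` (squared DFT
#'   magnitude).
#' @export
power_spectrum <- function(x, rate_hz) {
  if (length(x) == 0) abort("Cannot compute the spectrum of an empty segment.")
  assert_scalar_number(rate_hz, "rate_hz", 0, strict_lower = TRUE)
  np <- next_pow2(length(x))
  X <- fft(c(x, numeric(np - length(x))))
  k <- seq_len(np %/% 2) # DC excluded, Nyquist included
  tibble::tibble(freq = k * rate_hz / np, power = Mod(X[k + 1])^2)
}

#' Total spectral power of a segment
#'
#' Sum of squared DFT magnitudes over the one-sided spectrum (DC
#' excluded): the overall dynamic energy of the segment.
#'
#' @inheritParams power_spectrum
#' @return Nonnegative scalar.
#' @export
total_power <- function(x, rate_hz = 50) {
  sum(power_spectrum(x, rate_hz)$power)
}

#' Spectral edge frequency
#'
#' The smallest frequency below which at least `fraction` of the
#' segment's one-sided spectral power lies. `fraction = 0.5` gives SEF50
#' (the dominant-frequency edge), `fraction = 0.95` SEF95 (the primary
#' movement band edge).
#'
#' @inheritParams power_spectrum
#' @param fraction Power fraction in (0, 1).
#' @return Frequency in Hz, at most the Nyquist frequency.
#' @examples
#' x <- sin(2 * pi * 2 * (0:255) / 50)
#' sef(x, 50, 0.5)
#' @export
sef <- function(x, rate_hz, fraction) {
  assert_scalar_number(fraction, "fraction", 0, upper = 1, strict_lower = TRUE)
  if (fraction >= 1) abort("`fraction` must be strictly below 1.")
  spec <- power_spectrum(x, rate_hz)
  tot <- sum(spec$power)
  if (tot <= 0) abort("Spectral edge frequency is undefined for a zero-power signal.")
  # small tolerance so an exact power split lands on the lower edge
  spec$freq[which(cumsum(spec$power) >= (fraction - 1e-9) * tot)[1]]
}

#' Aggregate a per-repetition metric into mean and CV
#'
#' @param values Numeric vector of one metric across repetitions.
#' @return A list with `mean` and `cv` (sample standard deviation over
#'   the absolute mean). The CV is `NA` (undefined) for a single value or
#'   a zero mean rather than propagating NaN.
#' @examples
#' aggregate_segments(c(1, 3))
#' @export
aggregate_segments <- function(values) {
  if (length(values) < 1) abort("Need at least one value to aggregate.")
  m <- mean(values)
  cv <- if (length(values) < 2 || m == 0) NA_real_ else sd(values) / abs(m)
  list(mean = m, cv = cv)
}

# The nine metric families, in canonical order.
metric_names <- function() {
  c("duration", "max", "range", "rms", "amax", "jerk",
    "total_power", "sef50", "sef95")
}

feature_channels <- function() c("ML", "AP", "SI", "RES")
feature_contexts <- function() c("FTSTS", "SiSt", "StSi", "SSS")

# All nine metrics for one channel of one segment window.
channel_metrics <- function(x, res, rate_hz) {
  T_s <- duration(x, rate_hz)
  c(
    duration = T_s,
    max = max(x),
    range = range_acc(x),
    rms = rms(x),
    amax = amax(res),
    jerk = jerk(x, T_s),
    total_power = total_power(x, rate_hz),
    sef50 = sef(x, rate_hz, 0.5),
    sef95 = sef(x, rate_hz, 0.95)
  )
}

# 4 channels x 9 metrics for one window of a recording, as a named vector
# keyed {channel}_{metric}.
window_metrics <- function(recording, lo, hi, rate_hz) {
  ml <- recording$acc_ml[lo:hi]
  ap <- recording$acc_ap[lo:hi]
  si <- recording$acc_si[lo:hi]
  res <- resultant(ml, ap, si)
  chans <- list(ML = ml, AP = ap, SI = si, RES = res)
  out <- purrr::imap(chans, function(x, nm) {
    v <- channel_metrics(x, res, rate_hz)
    names(v) <- paste(nm, names(v), sep = "_")
    v
  })
  unlist(unname(out))
}

#' Extract the 144-metric feature vector of one test
#'
#' Computes nine metric families (duration, signed maximum, range, RMS,
#' resultant maximum, jerk, total spectral power, SEF50, SEF95) on four
#' channels (ML, AP, SI, resultant) in four contexts: the whole test
#' (`FTSTS`, first sit-to-stand start to last stand-to-sit end) and the
#' per-repetition `SiSt`, `StSi` and `SSS` windows averaged across
#' repetitions. That yields exactly 4 x 4 x 9 = 144 primary metrics,
#' named `{context}_{channel}_{metric}`. Duration and the resultant
#' maximum do not genuinely vary by channel; in the default
#' `"primary144"` layout they are replicated across channels to honour
#' the canonical count, while `layout = "compact"` keeps one copy per
#' context (120 metrics). Coefficients of variation across repetitions
#' are attached as `cv_`-prefixed supplements for the three repeated
#' contexts.
#'
#' @param recording A preprocessed [imu_recording()].
#' @param segments Segment tibble from [segment_recording()].
#' @param layout `"primary144"` (default) or `"compact"`.
#' @return A one-row tibble: 144 (or 120) primary metric columns followed
#'   by `cv_`-prefixed supplements.
#' @examples
#' rec <- preprocess_recording(simulate_ftsts(seed = 1))
#' fv <- extract_features(rec, segment_recording(rec))
#' sum(!startsWith(names(fv), "cv_"))
#' @export
extract_features <- function(recording, segments,
                             layout = c("primary144", "compact")) {
  layout <- match.arg(layout)
  stopifnot(inherits(recording, "imu_recording"))
  if (nrow(segments) == 0 || !any(segments$kind == "SSS")) {
    abort("`segments` must contain at least one full sit-stand-sit cycle.")
  }
  rate <- sample_rate(recording)

  per_context <- purrr::map(feature_contexts(), function(ctx) {
    rows <- segments[segments$kind == ctx, ]
    per_rep <- purrr::map(seq_len(nrow(rows)), function(i) {
      window_metrics(recording, rows$start_index[i], rows$end_index[i], rate)
    })
    mat <- do.call(rbind, per_rep)
    agg <- apply(mat, 2, function(v) unlist(aggregate_segments(v)["mean"]))
    cv <- apply(mat, 2, function(v) unlist(aggregate_segments(v)["cv"],
                                           use.names = FALSE))
    names(agg) <- paste(ctx, colnames(mat), sep = "_")
    names(cv) <- paste0("cv_", ctx, "_", colnames(mat))
    list(mean = agg, cv = cv)
  })

  primary <- unlist(purrr::map(per_context, "mean"))
  bad <- !is.finite(primary)
  if (any(bad)) {
    abort(paste0("Non-finite feature value(s): ",
                 paste(names(primary)[bad], collapse = ", ")))
  }
  # CV supplements only for the repeated contexts.
  cvs <- unlist(purrr::map(per_context[-1], "cv"))

  if (layout == "compact") {
    # one duration (ML slot) and one amax (RES slot) per context
    keep <- !grepl("_(duration|amax)$", names(primary)) |
      grepl("_ML_duration$", names(primary)) |
      grepl("_RES_amax$", names(primary))
    primary <- primary[keep]
  }
  tibble::as_tibble(as.list(c(primary, cvs)))
}

#' Feature table for a whole cohort
#'
#' Preprocesses, segments and feature-extracts every recording of a
#' generated (or loaded) cohort and binds the results into one analysis
#' table.
#'
#' @param cohort A list with `profiles` and `recordings`, as returned by
#'   [generate_cohort()].
#' @param preprocess A [preprocess_config()].
#' @param segmentation A [segmentation_config()].
#' @param layout Feature layout, see [extract_features()].
#' @return A tibble: `participant_id`, `group`, `glfs_score`, then the
#'   feature columns.
#' @export
extract_cohort_features <- function(cohort,
                                    preprocess = preprocess_config(),
                                    segmentation = segmentation_config(),
                                    layout = "primary144") {
  feats <- purrr::imap_dfr(cohort$recordings, function(rec, id) {
    pre <- preprocess_recording(rec, preprocess)
    segs <- segment_recording(pre, segmentation)
    fv <- extract_features(pre, segs, layout = layout)
    dplyr::bind_cols(tibble::tibble(participant_id = id), fv)
  })
  dplyr::left_join(
    cohort$profiles[, c("participant_id", "group", "glfs_score")],
    feats,
    by = "participant_id"
  )
}
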