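#' Segmentation configuration
#'
#' Thresholds for transition detection. `min_prominence` is the minimum
#' topographic prominence (deg/s) a pitch angular-velocity trough must
#' have to count as a postural transition; `min_separation_s` the minimum
#' time between two transitions; `boundary_fraction` sets segment edges
#' where the absolute pitch velocity falls below this fraction of the
#' trough magnitude. Defaults (20 deg/s, 0.5 s, 0.1) are conservative for
#' a self-paced five-time sit-to-stand.
#'
#' @param min_prominence Minimum trough prominence, deg/s.
#' @param min_separation_s Minimum separation between transitions, s.
#' @param boundary_fraction Fraction of the trough magnitude at which a
#'   transition window ends, in (0, 1].
#' @param differentiate If `TRUE`, treat the pitch channel as an angle
#'   and detect minima of its first derivative instead of the channel
#'   itself (alternative reading of the detection cue).
#'
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(min_prominence = 20, min_separation_s = 0.5,
                                boundary_fraction = 0.1,
                                differentiate = FALSE) {
  assert_scalar_number(min_prominence, "min_prominence", 0, strict_lower = TRUE)
  assert_scalar_number(min_separation_s, "min_separation_s", 0, strict_lower = TRUE)
  assert_scalar_number(boundary_fraction, "boundary_fraction", 0, upper = 1,
                       strict_lower = TRUE)
  structure(
    list(
      min_prominence = min_prominence,
      min_separation_s = min_separation_s,
      boundary_fraction = boundary_fraction,
      differentiate = isTRUE(differentiate)
    ),
    class = "segmentation_config"
  )
}

# Topographic prominence of strict local minima.
# For each strict local minimum, walk outward on each side until a sample
# lower than the minimum (or the signal edge) is met; the prominence is
# the smaller of the two maximal excursions above the minimum.
local_minima_prominence <- function(x) {
  n <- length(x)
  if (n < 3) {
    return(tibble::tibble(index = integer(), prominence = numeric()))
  }
  core <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
  prom <- vapply(core, function(i) {
    left_max <- -Inf
    j <- i - 1L
    while (j >= 1L && x[j] >= x[i]) {
      if (x[j] > left_max) left_max <- x[j]
      j <- j - 1L
    }
    right_max <- -Inf
    j <- i + 1L
    while (j <= n && x[j] >= x[i]) {
      if (x[j] > right_max) right_max <- x[j]
      j <- j + 1L
    }
    min(left_max, right_max) - x[i]
  }, numeric(1))
  tibble::tibble(index = core, prominence = prom)
}

#' Detect postural transitions as pitch angular-velocity minima
#'
#' Forward trunk flexion at each sit-to-stand and stand-to-sit produces a
#' trough (local minimum) in the gyroscope pitch angular velocity; these
#' troughs mark the transitions. Candidate strict local minima are ranked
#' by topographic prominence; troughs below `min_prominence` are
#' discarded, and of any pair closer than `min_separation_s` only the more
#' prominent survives.
#'
#' @param pitch_velocity Numeric vector: preprocessed pitch angular
#'   velocity, deg/s.
#' @param rate_hz Sampling rate of the trace, Hz.
#' @param config A [segmentation_config()].
#'
#' @return Sorted integer vector of sample indices (1-based). A flat or
#'   featureless trace yields an empty vector, not an error.
#' @examples
#' rec <- preprocess_recording(simulate_ftsts(seed = 1))
#' detect_transition_minima(rec$gyr_pitch, sample_rate(rec))
#' @export
detect_transition_minima <- function(pitch_velocity, rate_hz,
                                     config = segmentation_config()) {
  assert_scalar_number(rate_hz, "rate_hz", 0, strict_lower = TRUE)
  cand <- local_minima_prominence(pitch_velocity)
  cand <- cand[cand$prominence >= config$min_prominence, ]
  if (nrow(cand) == 0) {
    return(integer())
  }
  # Enforce minimum separation, keeping the more prominent trough.
  cand <- cand[order(-cand$prominence, cand$index), ]
  min_gap <- config$min_separation_s * rate_hz
  kept <- integer()
  for (i in seq_len(nrow(cand))) {
    idx <- cand$index[i]
    if (all(abs(kept - idx) >= min_gap)) kept <- c(kept, idx)
  }
  sort(kept)
}

# One transition window: expand outward from the trough until |v| drops
# below boundary_fraction * |trough|, capped at the midpoint to the
# neighbouring event (or the recording edge).
transition_window <- function(v, m, frac, left_cap, right_cap) {
  thr <- frac * abs(v[m])
  lo <- m
  while (lo > left_cap && abs(v[lo - 1]) > thr) lo <- lo - 1L
  hi <- m
  while (hi < right_cap && abs(v[hi + 1]) > thr) hi <- hi + 1L
  c(lo, hi)
}

#' Build labelled transition segments from detected minima
#'
#' Pairs the detected minima into cycles by alternation (the first trough
#' of each cycle is the sit-to-stand), builds one `SiSt` and one `StSi`
#' window per cycle, the enclosing `SSS` window (SiSt start to StSi end),
#' and the whole-test `FTSTS` window (first SiSt start to last StSi end).
#' Windows are 1-based inclusive index ranges into the recording.
#'
#' @param recording A preprocessed [imu_recording()].
#' @param minima Integer indices from [detect_transition_minima()].
#' @param config A [segmentation_config()].
#'
#' @return A tibble with columns `kind` (`SiSt`, `StSi`, `SSS`, `FTSTS`),
#'   `repetition`, `start_index`, `end_index`, `start_s`, `end_s`.
#' @export
build_segments <- function(recording, minima,
                           config = segmentation_config()) {
  stopifnot(inherits(recording, "imu_recording"))
  if (length(minima) == 0) {
    abort(sprintf(
      "No transitions detected in recording%s; cannot segment.",
      if (!is.null(attr(recording, "participant_id"))) {
        paste0(" '", attr(recording, "participant_id"), "'")
      } else ""
    ))
  }
  if (length(minima) %% 2 == 1) {
    warn("Odd number of detected transitions; dropping the trailing event.")
    minima <- minima[-length(minima)]
    if (length(minima) == 0) {
      abort("No complete sit-stand-sit cycle detected; cannot segment.")
    }
  }
  rate <- sample_rate(recording)
  v <- recording$gyr_pitch
  n <- nrow(recording)
  n_cyc <- length(minima) %/% 2

  # Midpoints between neighbouring events cap each window.
  caps_left <- c(1L, floor((head(minima, -1) + tail(minima, -1)) / 2))
  caps_right <- c(ceiling((head(minima, -1) + tail(minima, -1)) / 2), n)

  wins <- purrr::map(seq_along(minima), function(j) {
    transition_window(v, minima[j], config$boundary_fraction,
                      caps_left[j], caps_right[j])
  })

  sist <- wins[seq(1, by = 2, length.out = n_cyc)]
  stsi <- wins[seq(2, by = 2, length.out = n_cyc)]

  seg_row <- function(kind, rep, lo, hi) {
    tibble::tibble(
      kind = kind, repetition = rep,
      start_index = lo, end_index = hi,
      start_s = (lo - 1) / rate, end_s = (hi - 1) / rate
    )
  }
  segs <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_cyc), function(k) {
      seg_row("SiSt", k, sist[[k]][1], sist[[k]][2])
    }),
    purrr::map_dfr(seq_len(n_cyc), function(k) {
      seg_row("StSi", k, stsi[[k]][1], stsi[[k]][2])
    }),
    purrr::map_dfr(seq_len(n_cyc), function(k) {
      seg_row("SSS", k, sist[[k]][1], stsi[[k]][2])
    }),
    seg_row("FTSTS", 1L, sist[[1]][1], stsi[[n_cyc]][2])
  )
  segs$kind <- factor(segs$kind, levels = c("SiSt", "StSi", "SSS", "FTSTS"))
  segs
}

#' Segment a preprocessed recording in one call
#'
#' Runs [detect_transition_minima()] on the pitch angular-velocity
#' channel (or its first derivative when the configuration asks for it)
#' and then [build_segments()].
#'
#' @inheritParams build_segments
#' @return The segment tibble from [build_segments()].
#' @examples
#' rec <- preprocess_recording(simulate_ftsts(seed = 1))
#' segment_recording(rec)
#' @export
segment_recording <- function(recording, config = segmentation_config()) {
  trace <- recording$gyr_pitch
  rate <- sample_rate(recording)
  if (config$differentiate) {
    trace <- c(0, diff(trace)) * rate
  }
  minima <- detect_transition_minima(trace, rate, config)
  build_segments(recording, minima, config)
}
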