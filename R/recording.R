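#' IMU recording objects
#'
#' An IMU recording is a tibble with one row per sample and columns
#' `t` (seconds), `acc_ml`, `acc_ap`, `acc_si` (trunk accelerations, m/s^2)
#' and `gyr_roll`, `gyr_pitch`, `gyr_yaw` (angular velocities, deg/s),
#' carrying the sampling rate and optional ground-truth transition events
#' as attributes. `imu_recording()` validates and constructs one from a
#' plain data frame; `sample_rate()` and `ground_truth_events()` read the
#' attributes back.
#'
#' @param data A data frame with columns `t`, `acc_ml`, `acc_ap`, `acc_si`,
#'   `gyr_roll`, `gyr_pitch`, `gyr_yaw`.
#' @param sample_rate_hz Sampling rate in Hz (positive).
#' @param events Optional tibble of ground-truth transition events with
#'   columns `event` (`"seat_off"` or `"seat_on"`) and `time_s`; times must
#'   be strictly increasing and alternate seat-off / seat-on.
#' @param participant_id Optional participant identifier string.
#'
#' @return A tibble of class `imu_recording`.
#' @export
imu_recording <- function(data, sample_rate_hz, events = NULL,
                          participant_id = NULL) {
  cols <- c("t", "acc_ml", "acc_ap", "acc_si", "gyr_roll", "gyr_pitch", "gyr_yaw")
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Recording is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 2) {
    abort("A recording needs at least 2 samples.")
  }
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 0, strict_lower = TRUE)
  if (!is.null(events)) {
    if (!all(c("event", "time_s") %in% names(events))) {
      abort("`events` needs columns `event` and `time_s`.")
    }
    if (nrow(events) > 0) {
      if (any(diff(events$time_s) <= 0)) {
        abort("Ground-truth event times must be strictly increasing.")
      }
      expected <- rep(c("seat_off", "seat_on"), length.out = nrow(events))
      if (!all(events$event == expected)) {
        abort("Ground-truth events must alternate seat_off / seat_on, starting with seat_off.")
      }
    }
    events <- tibble::as_tibble(events)
  }
  out <- tibble::as_tibble(data[cols])
  structure(out,
    class = c("imu_recording", class(out)),
    sample_rate_hz = as.numeric(sample_rate_hz),
    events = events,
    participant_id = participant_id
  )
}

#' @rdname imu_recording
#' @param recording An `imu_recording`.
#' @export
sample_rate <- function(recording) {
  rate <- attr(recording, "sample_rate_hz")
  if (is.null(rate)) abort("Object carries no `sample_rate_hz` attribute.")
  rate
}

#' @rdname imu_recording
#' @export
ground_truth_events <- function(recording) {
  attr(recording, "events")
}

#' @method print imu_recording
#' @export
print.imu_recording <- function(x, ...) {
  ev <- ground_truth_events(x)
  cat(sprintf(
    "<imu_recording: %d samples @ %g Hz (%.2f s)%s>\n",
    nrow(x), sample_rate(x), nrow(x) / sample_rate(x),
    if (!is.null(ev)) sprintf(", %d ground-truth events", nrow(ev)) else ""
  ))
  NextMethod()
}

# Rebuild an imu_recording from modified sample data, keeping metadata.
rebuild_recording <- function(template, data, sample_rate_hz = NULL) {
  imu_recording(
    data,
    sample_rate_hz = sample_rate_hz %||% sample_rate(template),
    events = ground_truth_events(template),
    participant_id = attr(template, "participant_id")
  )
}
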