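#' Read and write recordings and cohort tables as CSV
#'
#' Recordings are stored one file per participant with header
#' `t,acc_ml,acc_ap,acc_si,gyr_roll,gyr_pitch,gyr_yaw` (SI units, deg/s
#' for the gyroscope); the sampling rate is recovered from the time
#' column on read. The cohort manifest holds one row per participant
#' (`participant_id,group,sex,age,glfs`).
#'
#' @param recording An [imu_recording()].
#' @param path File path.
#' @param sample_rate_hz Sampling rate to assume on read; inferred from
#'   the median time step when `NULL`.
#' @name recording_io
NULL

#' @rdname recording_io
#' @export
write_recording <- function(recording, path) {
  readr::write_csv(tibble::as_tibble(recording), path)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_recording <- function(path, sample_rate_hz = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  rate <- sample_rate_hz %||% (1 / median(diff(df$t)))
  imu_recording(df, sample_rate_hz = rate)
}

#' @rdname recording_io
#' @param profiles Profile tibble from [generate_cohort()].
#' @export
write_cohort_manifest <- function(profiles, path) {
  out <- tibble::tibble(
    participant_id = profiles$participant_id,
    group = as.character(profiles$group),
    sex = profiles$sex,
    age = profiles$age_years,
    glfs = profiles$glfs_score
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_cohort_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(
    participant_id = df$participant_id,
    group = factor(df$group, levels = ls_group_levels()),
    sex = df$sex,
    age_years = df$age,
    glfs_score = df$glfs
  )
}

#' @rdname recording_io
#' @param features Feature table from [extract_cohort_features()].
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("group" %in% names(df)) {
    df$group <- factor(df$group, levels = ls_group_levels())
  }
  df
}
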