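#' Kinematic parameters for the sit-to-stand simulator
#'
#' Bundles the per-participant kinematic settings used by
#' [simulate_ftsts()]. Group presets order the classes so that a higher
#' locomotive-syndrome stage means slower cycles, weaker acceleration
#' bursts, a shallower pitch angular-velocity trough and more tremor.
#' The presets are simulator configuration values chosen to produce
#' separable classes; they are not measurements of any study population.
#'
#' @param group Optional group preset, one of `"Young"`, `"NonLS"`,
#'   `"Stage1"`, `"Stage2"`. When given, unset arguments take the preset
#'   values.
#' @param cycle_duration_s Mean duration of one sit-stand-sit cycle (s).
#' @param duration_cv Within-participant coefficient of variation of cycle
#'   durations (log-normal draw).
#' @param peak_pitch_velocity Magnitude of the pitch angular-velocity
#'   trough at each postural transition (deg/s).
#' @param peak_ap_accel,peak_si_accel Peak anterior-posterior and
#'   superior-inferior acceleration burst magnitudes (m/s^2).
#' @param tremor_noise_sd Standard deviation of additive Gaussian
#'   acceleration noise (m/s^2); 0 gives a noise-free recording.
#' @param inter_cycle_pause_s Seated pause between consecutive cycles (s).
#'
#' @return A one-row tibble of kinematic parameters.
#' @examples
#' kinematic_params("Stage2")
#' @export
kinematic_params <- function(group = NULL,
                             cycle_duration_s = NULL,
                             duration_cv = NULL,
                             peak_pitch_velocity = NULL,
                             peak_ap_accel = NULL,
                             peak_si_accel = NULL,
                             tremor_noise_sd = NULL,
                             inter_cycle_pause_s = NULL) {
  presets <- tibble::tribble(
    ~group,   ~cycle_duration_s, ~duration_cv, ~peak_pitch_velocity,
    ~peak_ap_accel, ~peak_si_accel, ~tremor_noise_sd, ~inter_cycle_pause_s,
    "Young",  1.5, 0.06, 90, 2.4, 2.0, 0.03, 0.30,
    "NonLS",  1.8, 0.08, 75, 2.0, 1.6, 0.05, 0.40,
    "Stage1", 2.4, 0.10, 60, 1.5, 1.2, 0.08, 0.55,
    "Stage2", 3.0, 0.12, 45, 1.1, 0.9, 0.10, 0.70
  )
  base <- if (is.null(group)) {
    presets[presets$group == "NonLS", -1]
  } else {
    group <- match.arg(group, ls_group_levels())
    presets[presets$group == group, -1]
  }
  take <- function(user, name) user %||% base[[name]]
  out <- tibble::tibble(
    cycle_duration_s = take(cycle_duration_s, "cycle_duration_s"),
    duration_cv = take(duration_cv, "duration_cv"),
    peak_pitch_velocity = take(peak_pitch_velocity, "peak_pitch_velocity"),
    peak_ap_accel = take(peak_ap_accel, "peak_ap_accel"),
    peak_si_accel = take(peak_si_accel, "peak_si_accel"),
    tremor_noise_sd = take(tremor_noise_sd, "tremor_noise_sd"),
    inter_cycle_pause_s = take(inter_cycle_pause_s, "inter_cycle_pause_s")
  )
  assert_scalar_number(out$cycle_duration_s, "cycle_duration_s", 0, strict_lower = TRUE)
  assert_scalar_number(out$duration_cv, "duration_cv", 0)
  assert_scalar_number(out$peak_pitch_velocity, "peak_pitch_velocity", 0, strict_lower = TRUE)
  assert_scalar_number(out$peak_ap_accel, "peak_ap_accel", 0, strict_lower = TRUE)
  assert_scalar_number(out$peak_si_accel, "peak_si_accel", 0, strict_lower = TRUE)
  assert_scalar_number(out$tremor_noise_sd, "tremor_noise_sd", 0)
  assert_scalar_number(out$inter_cycle_pause_s, "inter_cycle_pause_s", 0)
  out
}

# Logistic density bump, peak 1 at u = 0. The pitch angle is a sum of
# logistic ramps; this is its (rescaled) analytic derivative.
logistic_bump <- function(u) {
  e <- exp(-abs(u))
  4 * e / (1 + e)^2
}

# Odd biphasic burst, peaks +-1 at u = -+1: derivative-of-bump shape used
# for the AP acceleration around each transition.
biphasic_burst <- function(u) {
  -u * exp((1 - u^2) / 2)
}

# Even "braking" bump used for the SI acceleration (Ricker shape, peak 1).
ricker_bump <- function(u) {
  (1 - u^2) * exp(-u^2 / 2)
}

#' Simulate one five-time sit-to-stand recording
#'
#' Generates a trunk IMU recording of `n_cycles` consecutive
#' sit-stand-sit cycles at a self-selected pace. The pitch angle follows a
#' sum of logistic ramps (forward flexion then extension at each postural
#' transition), so the pitch angular velocity is an analytic sum of
#' negative logistic-density troughs: exactly one dominant local minimum
#' per transition, two per cycle. Anterior-posterior and
#' superior-inferior accelerations carry time-locked bursts scaled by the
#' kinematic parameters; the mediolateral channel is low-amplitude sway
#' plus noise. Accelerations are generated gravity-free (dynamic
#' component only) unless `gravity_offset` is set, since preprocessing
#' removes constant offsets anyway. Ground-truth seat-off / seat-on times
#' are attached to the recording.
#'
#' @inheritParams imu_recording
#' @param params Kinematic parameters from [kinematic_params()].
#' @param n_cycles Number of sit-stand-sit cycles (default 5, the
#'   standard protocol).
#' @param sample_rate_hz Sampling rate in Hz (default 100).
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param gravity_offset If `TRUE`, add a constant 9.81 m/s^2 offset to
#'   the SI channel to exercise zero-centering.
#' @param lead_in_s Seated rest before the first and after the last cycle (s).
#'
#' @return An [imu_recording()] with `2 * n_cycles` ground-truth events.
#' @examples
#' rec <- simulate_ftsts(kinematic_params("Young"), seed = 1)
#' ground_truth_events(rec)
#' @export
simulate_ftsts <- function(params = kinematic_params(), n_cycles = 5,
                           sample_rate_hz = 100, seed = 1,
                           gravity_offset = FALSE, lead_in_s = 1.5,
                           participant_id = NULL) {
  stopifnot(nrow(params) == 1)
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", 0, strict_lower = TRUE)

  with_seed(seed, {
    p <- as.list(params)
    # Per-cycle durations: log-normal with the requested mean and CV.
    sdlog <- sqrt(log(1 + p$duration_cv^2))
    meanlog <- log(p$cycle_duration_s) - sdlog^2 / 2
    durations <- rlnorm(n_cycles, meanlog, sdlog)

    starts <- lead_in_s + cumsum(c(0, head(durations, -1) + p$inter_cycle_pause_s))
    sist_times <- starts + 0.25 * durations
    stsi_times <- starts + 0.75 * durations
    total_s <- starts[n_cycles] + durations[n_cycles] + lead_in_s

    n <- round(total_s * sample_rate_hz)
    t <- (seq_len(n) - 1) / sample_rate_hz

    # Transition half-widths scale with the cycle duration.
    widths <- durations / 14
    centers <- as.vector(rbind(sist_times, stsi_times))
    w_all <- rep(widths, each = 2)
    is_sist <- rep(c(TRUE, FALSE), times = n_cycles)

    gyr_pitch <- numeric(n)
    acc_ap <- numeric(n)
    acc_si <- numeric(n)
    for (j in seq_along(centers)) {
      u <- (t - centers[j]) / w_all[j]
      gyr_pitch <- gyr_pitch - p$peak_pitch_velocity * logistic_bump(u)
      sgn <- if (is_sist[j]) 1 else -1
      acc_ap <- acc_ap + sgn * p$peak_ap_accel * biphasic_burst(u / 1.6)
      acc_si <- acc_si + p$peak_si_accel * ricker_bump(u / 1.6)
    }
    # Low-frequency postural sway on the ML axis; the sway frequency is
    # participant-specific, as in real standing balance.
    sway_hz <- runif(1, 0.3, 0.5)
    acc_ml <- 0.06 * p$peak_ap_accel * sin(2 * pi * sway_hz * t)

    if (p$tremor_noise_sd > 0) {
      acc_ml <- acc_ml + rnorm(n, 0, p$tremor_noise_sd)
      acc_ap <- acc_ap + rnorm(n, 0, p$tremor_noise_sd)
      acc_si <- acc_si + rnorm(n, 0, p$tremor_noise_sd)
      gyr_noise <- 10 * p$tremor_noise_sd
      gyr_roll <- rnorm(n, 0, gyr_noise)
      gyr_pitch <- gyr_pitch + rnorm(n, 0, gyr_noise)
      gyr_yaw <- rnorm(n, 0, gyr_noise)
    } else {
      gyr_roll <- numeric(n)
      gyr_yaw <- numeric(n)
    }
    if (gravity_offset) acc_si <- acc_si + 9.81

    events <- tibble::tibble(
      event = as.vector(rbind(rep("seat_off", n_cycles), rep("seat_on", n_cycles))),
      time_s = centers
    )
    imu_recording(
      tibble::tibble(
        t = t, acc_ml = acc_ml, acc_ap = acc_ap, acc_si = acc_si,
        gyr_roll = gyr_roll, gyr_pitch = gyr_pitch, gyr_yaw = gyr_yaw
      ),
      sample_rate_hz = sample_rate_hz,
      events = events,
      participant_id = participant_id
    )
  })
}

#' Cohort configuration for the synthetic generator
#'
#' @param group_counts Named integer vector of participants per group.
#'   The default reproduces the study composition: 47 non-LS, 29 LS stage
#'   1, 49 LS stage 2 and 49 young adults (174 in total).
#' @param between_subject_cv Multiplicative log-normal coefficient of
#'   variation applied to each participant's kinematic magnitudes around
#'   the group preset.
#' @param n_cycles,sample_rate_hz Protocol settings passed to
#'   [simulate_ftsts()].
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_counts = c(NonLS = 47, Stage1 = 29,
                                           Stage2 = 49, Young = 49),
                          between_subject_cv = 0.06,
                          n_cycles = 5, sample_rate_hz = 100) {
  if (is.null(names(group_counts)) ||
      !all(names(group_counts) %in% ls_group_levels())) {
    abort("`group_counts` must be named with groups Young/NonLS/Stage1/Stage2.")
  }
  if (any(group_counts < 1)) abort("Every group count must be >= 1.")
  assert_scalar_number(between_subject_cv, "between_subject_cv", 0)
  structure(
    list(
      group_counts = group_counts,
      between_subject_cv = between_subject_cv,
      n_cycles = n_cycles,
      sample_rate_hz = sample_rate_hz
    ),
    class = "cohort_config"
  )
}

# Demographic presets: sex split and age mean/sd per group, matching the
# published cohort's demographic table.
demographics_presets <- function() {
  tibble::tribble(
    ~group,   ~p_male,  ~age_mean, ~age_sd, ~age_min, ~age_max,
    "NonLS",  21 / 47,  71.4,      6.1,     60,       95,
    "Stage1", 8 / 29,   72.3,      8.6,     60,       95,
    "Stage2", 19 / 49,  76.1,      11.3,    60,       95,
    "Young",  30 / 49,  27.04,     7.1,     18,       45
  )
}

# Draw a GLFS-25 score consistent with a group's staging interval.
draw_glfs <- function(group, n) {
  switch(group,
    NonLS = sample(0:6, n, replace = TRUE),
    Stage1 = sample(7:15, n, replace = TRUE),
    Stage2 = sample(16:40, n, replace = TRUE),
    Young = rep(NA_integer_, n)
  )
}

#' Generate a synthetic five-time sit-to-stand cohort
#'
#' Builds participant profiles (group, sex, age, GLFS-25 score) and one
#' simulated IMU recording per participant. GLFS scores are drawn
#' uniformly within each group's staging interval, so
#' `assign_stage(glfs_score)` always agrees with the group for older
#' participants; young participants carry no score. Each participant's
#' kinematics are the group preset jittered by a multiplicative
#' log-normal factor, making the classes separable but overlapping.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return A list with `profiles` (a tibble: `participant_id`, `group`,
#'   `sex`, `age_years`, `glfs_score`) and `recordings` (a named list of
#'   [imu_recording()] objects, one per profile).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(group_counts =
#'   c(NonLS = 2, Stage1 = 2, Stage2 = 2, Young = 2)), seed = 1)
#' cohort$profiles
#' }
#' @export
generate_cohort <- function(config = cohort_config(), seed = 42) {
  stopifnot(inherits(config, "cohort_config"))
  demo <- demographics_presets()

  profiles <- with_seed(derive_seed(seed, "profiles"), {
    purrr::map_dfr(names(config$group_counts), function(g) {
      n <- config$group_counts[[g]]
      d <- demo[demo$group == g, ]
      age <- pmin(pmax(rnorm(n, d$age_mean, d$age_sd), d$age_min), d$age_max)
      tibble::tibble(
        participant_id = sprintf("%s_%03d", g, seq_len(n)),
        group = g,
        sex = ifelse(runif(n) < d$p_male, "M", "F"),
        age_years = round(age, 1),
        glfs_score = draw_glfs(g, n)
      )
    })
  })
  profiles$group <- factor(profiles$group, levels = ls_group_levels())

  recordings <- purrr::map(seq_len(nrow(profiles)), function(i) {
    g <- as.character(profiles$group[i])
    base <- kinematic_params(g)
    jitter_seed <- derive_seed(seed, paste0("kin_", profiles$participant_id[i]))
    jittered <- with_seed(jitter_seed, {
      cv <- config$between_subject_cv
      sdlog <- sqrt(log(1 + cv^2))
      jit <- function(x) x * rlnorm(1, -sdlog^2 / 2, sdlog)
      base$cycle_duration_s <- jit(base$cycle_duration_s)
      base$peak_pitch_velocity <- jit(base$peak_pitch_velocity)
      base$peak_ap_accel <- jit(base$peak_ap_accel)
      base$peak_si_accel <- jit(base$peak_si_accel)
      base
    })
    simulate_ftsts(
      jittered,
      n_cycles = config$n_cycles,
      sample_rate_hz = config$sample_rate_hz,
      seed = derive_seed(seed, paste0("rec_", profiles$participant_id[i])),
      participant_id = profiles$participant_id[i]
    )
  })
  names(recordings) <- profiles$participant_id
  list(profiles = profiles, recordings = recordings)
}
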