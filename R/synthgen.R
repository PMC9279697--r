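# Synthetic Kinect-format recordings of the five-action stimulus task with
# severity-dependent kinematic effects (psychomotor retardation): reduced
# movement amplitude and velocity, longer and more variable reaction times,
# a head-down postural offset, and larger lateral body sway. Trajectories
# use minimum-jerk interpolation between rest and keyframe poses; all pose
# changes are rigid rotations/translations of the rest skeleton, so bone
# lengths are conserved exactly on the noise-free trajectories, with
# isotropic Gaussian sensor jitter added on top.

# Rest pose for a subject of the given height (meters), standing 3 m from
# the sensor; +x is the subject's left, +y up, +z away from the sensor.
rest_pose <- function(height = 1.75) {
  s <- height / 1.75
  pose <- rbind(
    SpineBase     = c(0.00, 0.95, 3.00),
    SpineMid      = c(0.00, 1.18, 3.00),
    Neck          = c(0.00, 1.47, 3.00),
    Head          = c(0.00, 1.62, 3.00),
    ShoulderLeft  = c(0.20, 1.40, 3.00),
    ElbowLeft     = c(0.24, 1.12, 3.00),
    WristLeft     = c(0.26, 0.88, 3.00),
    HandLeft      = c(0.27, 0.80, 3.00),
    ShoulderRight = c(-0.20, 1.40, 3.00),
    ElbowRight    = c(-0.24, 1.12, 3.00),
    WristRight    = c(-0.26, 0.88, 3.00),
    HandRight     = c(-0.27, 0.80, 3.00),
    HipLeft       = c(0.10, 0.92, 3.00),
    KneeLeft      = c(0.11, 0.50, 3.00),
    AnkleLeft     = c(0.12, 0.08, 3.00),
    FootLeft      = c(0.12, 0.03, 2.88),
    HipRight      = c(-0.10, 0.92, 3.00),
    KneeRight     = c(-0.11, 0.50, 3.00),
    AnkleRight    = c(-0.12, 0.08, 3.00),
    FootRight     = c(-0.12, 0.03, 2.88),
    SpineShoulder = c(0.00, 1.40, 3.00),
    HandTipLeft   = c(0.275, 0.72, 3.00),
    ThumbLeft     = c(0.22, 0.78, 2.97),
    HandTipRight  = c(-0.275, 0.72, 3.00),
    ThumbRight    = c(-0.22, 0.78, 2.97)
  )
  pose[, 1:2] <- pose[, 1:2] * s
  pose[, 3] <- 3 + (pose[, 3] - 3) * s
  pose[kinect_joints(), , drop = FALSE]
}

#' Severity-to-kinematics effect profile
#'
#' Maps a severity band to the kinematic effect parameters the simulator
#' applies, linearly in the band index (documented defaults below). With
#' `effect_multiplier = m`, each parameter becomes
#' `baseline + m * (band_value - baseline)` where the baseline is the NONE
#' row, so `m = 0` makes all bands kinematically identical (negative
#' control) and `m > 1` exaggerates the separation.
#'
#' Defaults by band NONE / PROBABLE / MEDIUM / SEVERE:
#' amplitude scale 1.0 / 0.9 / 0.75 / 0.6; velocity scale the same;
#' reaction delay mean 0.3 / 0.5 / 0.8 / 1.2 s (sd 0.05 / 0.12 / 0.20 /
#' 0.30); head-down pitch 0 / 0.08 / 0.20 / 0.35 rad; lateral sway
#' amplitude 5 / 12 / 20 / 30 mm. Sensor jitter sd is 5 mm for every band.
#'
#' @param band A band name from [severity_bands()].
#' @param effect_multiplier Non-negative scale on all band effects.
#' @return Named list of effect parameters.
#' @export
severity_profile <- function(band, effect_multiplier = 1) {
  band <- match.arg(as.character(band), severity_bands())
  tab <- list(
    amplitude_scale     = c(1.0, 0.9, 0.75, 0.6),
    velocity_scale      = c(1.0, 0.9, 0.75, 0.6),
    reaction_delay_mean = c(0.3, 0.5, 0.8, 1.2),
    reaction_delay_sd   = c(0.05, 0.12, 0.20, 0.30),
    head_pitch_offset   = c(0.0, 0.08, 0.20, 0.35),
    sway_amplitude      = c(0.005, 0.012, 0.020, 0.030),
    jitter_sd           = c(0.005, 0.005, 0.005, 0.005)
  )
  i <- match(band, severity_bands())
  prof <- lapply(tab, function(v) v[1] + effect_multiplier * (v[i] - v[1]))
  prof$amplitude_scale <- max(prof$amplitude_scale, 0.05)
  prof$velocity_scale <- max(prof$velocity_scale, 0.05)
  prof$band <- band
  prof
}

# Minimum-jerk position profile on u in [0, 1].
min_jerk <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  10 * u^3 - 15 * u^4 + 6 * u^5
}

# Activation curve of one cued action inside [t0, t1]: zero, a smooth
# minimum-jerk rise after the reaction delay, a hold, and a smooth return.
action_activation <- function(times, t0, t1, profile) {
  seg <- t1 - t0
  delay <- max(0, rnorm(1, profile$reaction_delay_mean,
                        profile$reaction_delay_sd))
  onset <- t0 + min(delay, 0.5 * seg)
  rise <- min(1.2 / profile$velocity_scale, 0.3 * seg)
  ret_start <- t1 - rise - 0.05 * seg
  up <- min_jerk((times - onset) / rise)
  down <- min_jerk((times - ret_start) / rise)
  a <- up * (1 - down)
  a[times < t0 | times >= t1] <- 0
  a
}

# Core trajectory synthesis: given per-frame action activations, build the
# 25-joint position and orientation streams.
synth_motion <- function(times, act, profile, height, absent_rate) {
  t_n <- length(times)
  joints <- kinect_joints()
  base <- rest_pose(height)
  amp <- profile$amplitude_scale
  theta_max <- 2.4 # rad, full lateral arm raise
  phi_max <- 1.0   # rad, full trunk turn
  theta_l <- theta_max * amp * (act$LIFT_TWO_HANDS + act$LIFT_LEFT)
  theta_r <- theta_max * amp * (act$LIFT_TWO_HANDS + act$LIFT_RIGHT)
  phi <- phi_max * amp * (act$TURN_LEFT - act$TURN_RIGHT)
  alpha <- profile$head_pitch_offset # constant head-down pitch
  sway <- profile$sway_amplitude * sin(2 * pi * 0.25 * times)

  pos <- array(0, c(t_n, 25, 3))
  for (j in seq_len(25)) pos[, j, ] <- matrix(base[j, ], t_n, 3, byrow = TRUE)

  arm_left <- match(c("ElbowLeft", "WristLeft", "HandLeft", "HandTipLeft",
                      "ThumbLeft"), joints)
  arm_right <- match(c("ElbowRight", "WristRight", "HandRight",
                       "HandTipRight", "ThumbRight"), joints)
  sh_l <- base["ShoulderLeft", ]
  sh_r <- base["ShoulderRight", ]
  rot_z <- function(idx, shoulder, psi) {
    cp <- cos(psi); sp <- sin(psi)
    for (j in idx) {
      off <- base[j, ] - shoulder
      pos[, j, 1] <<- shoulder[1] + cp * off[1] - sp * off[2]
      pos[, j, 2] <<- shoulder[2] + sp * off[1] + cp * off[2]
    }
  }
  rot_z(arm_left, sh_l, theta_l)    # left arm raises toward +x
  rot_z(arm_right, sh_r, -theta_r)  # right arm raises toward -x

  # head-down pitch about the x-axis through the neck
  head_i <- match("Head", joints)
  off_h <- base["Head", ] - base["Neck", ]
  pos[, head_i, 2] <- base["Neck", 2] + cos(alpha) * off_h[2] -
    sin(alpha) * off_h[3] + 0 * times
  pos[, head_i, 3] <- base["Neck", 3] + sin(alpha) * off_h[2] +
    cos(alpha) * off_h[3] + 0 * times

  # whole-body turn about the vertical axis through SpineBase
  pivot <- base["SpineBase", ]
  cphi <- cos(phi); sphi <- sin(phi)
  rx <- pos[, , 1] - pivot[1]
  rz <- pos[, , 3] - pivot[3]
  pos[, , 1] <- pivot[1] + cphi * rx + sphi * rz
  pos[, , 3] <- pivot[3] - sphi * rx + cphi * rz

  pos[, , 1] <- pos[, , 1] + sway # lateral sway translation

  if (profile$jitter_sd > 0) {
    pos <- pos + array(rnorm(length(pos), 0, profile$jitter_sd), dim(pos))
  }

  # orientations: local joint rotation composed with the trunk turn
  q_turn <- cbind(x = 0, y = sin(phi / 2), z = 0 * phi, w = cos(phi / 2))
  quat <- array(0, c(t_n, 25, 4))
  identity_q <- cbind(0 * phi, 0 * phi, 0 * phi, 1 + 0 * phi)
  q_head <- quat_multiply(q_turn,
    cbind(sin(alpha / 2) + 0 * phi, 0 * phi, 0 * phi,
          cos(alpha / 2) + 0 * phi))
  q_arm <- function(psi) {
    quat_multiply(q_turn, cbind(0 * psi, 0 * psi, sin(psi / 2), cos(psi / 2)))
  }
  q_l <- q_arm(theta_l)
  q_r <- q_arm(-theta_r)
  for (j in seq_len(25)) {
    q <- quat_multiply(q_turn, identity_q)
    if (j %in% arm_left) q <- q_l
    if (j %in% arm_right) q <- q_r
    if (j == head_i) q <- q_head
    quat[, j, ] <- q
  }

  # leaf joints occasionally lack an orientation in Kinect streams
  leaf <- match(c("Head", "FootLeft", "FootRight", "HandTipLeft",
                  "ThumbLeft", "HandTipRight", "ThumbRight"), joints)
  if (absent_rate > 0) {
    absent <- matrix(FALSE, t_n, 25)
    absent[, leaf] <- runif(t_n * length(leaf)) < absent_rate
    for (ch in 1:4) {
      qc <- quat[, , ch]
      qc[absent] <- NA_real_
      quat[, , ch] <- qc
    }
  }
  list(pos = pos, quat = quat)
}

motion_to_sequence <- function(motion, times, subject_id, action,
                               sample_rate) {
  t_n <- length(times)
  frames <- tibble::tibble(
    frame = rep(0:(t_n - 1), each = 25),
    timestamp = rep(times, each = 25),
    joint = rep(kinect_joints(), t_n),
    x = as.vector(t(motion$pos[, , 1])),
    y = as.vector(t(motion$pos[, , 2])),
    z = as.vector(t(motion$pos[, , 3])),
    rx = as.vector(t(motion$quat[, , 1])),
    ry = as.vector(t(motion$quat[, , 2])),
    rz = as.vector(t(motion$quat[, , 3])),
    rw = as.vector(t(motion$quat[, , 4])),
    tracked = TRUE
  )
  skeleton_sequence(frames, subject_id = subject_id, action = action,
                    sample_rate = sample_rate, validate = FALSE)
}

#' Generate a single cued action
#'
#' One action performed once from rest, with the kinematic effects of the
#' given profile. Deterministic under `seed`.
#'
#' @param action One of [stimulus_actions()].
#' @param profile A [severity_profile()].
#' @param height Subject height in meters.
#' @param seed Integer seed.
#' @param duration Segment length in seconds (default 10).
#' @param sample_rate Hz (default 30).
#' @param absent_rate Per-frame probability that a leaf joint (head, feet,
#'   hand tips, thumbs) reports no orientation (default 0.15).
#' @return A [skeleton_sequence()].
#' @export
generate_action <- function(action, profile, height = 1.75, seed = 1,
                            duration = 10, sample_rate = 30,
                            absent_rate = 0.15) {
  action <- match.arg(action, stimulus_actions())
  withr::with_seed(seed, {
    t_n <- round(duration * sample_rate)
    times <- (seq_len(t_n) - 1) / sample_rate
    act <- stats::setNames(
      rep(list(numeric(t_n)), length(stimulus_actions())),
      stimulus_actions())
    if (action != "RESET") {
      act[[action]] <- action_activation(times, 0, duration, profile)
    }
    motion <- synth_motion(times, act, profile, height, absent_rate)
    motion_to_sequence(motion, times, sprintf("action_%s", action), action,
                       sample_rate)
  })
}

#' Generate a full stimulus-task recording
#'
#' A continuous recording (default 60 s at 30 Hz, 1800 frames) of the five
#' audio-cued actions plus reset, spaced evenly: segment k of 6 holds action
#' k. Returns the recording together with its cue schedule (segment onsets),
#' whose interior cue times feed [segment_by_cues()].
#'
#' @param severity A band from [severity_bands()].
#' @param subject_id Subject identifier.
#' @param seed Integer seed.
#' @param duration Recording length in seconds (default 60).
#' @param sample_rate Hz (default 30).
#' @param effect_multiplier Scale on all severity effects (see
#'   [severity_profile()]).
#' @param height Subject height in meters (default: drawn from U(1.55, 1.90)).
#' @param absent_rate See [generate_action()].
#' @param jitter_sd Override the profile's sensor jitter sd (meters).
#' @return List with `sequence` (a [skeleton_sequence()]), `schedule`
#'   (tibble `cue_time_s`, `action` of segment onsets), and `profile`.
#' @export
generate_recording <- function(severity, subject_id = "sim", seed = 1,
                               duration = 60, sample_rate = 30,
                               effect_multiplier = 1, height = NULL,
                               absent_rate = 0.15, jitter_sd = NULL) {
  profile <- severity_profile(severity, effect_multiplier)
  if (!is.null(jitter_sd)) profile$jitter_sd <- jitter_sd
  withr::with_seed(seed, {
    if (is.null(height)) height <- runif(1, 1.55, 1.90)
    t_n <- round(duration * sample_rate)
    times <- (seq_len(t_n) - 1) / sample_rate
    bounds <- duration * (0:6) / 6
    actions <- stimulus_actions()
    act <- stats::setNames(
      rep(list(numeric(t_n)), length(actions)), actions)
    for (k in 1:5) {
      act[[actions[k]]] <- action_activation(times, bounds[k], bounds[k + 1],
                                             profile)
    }
    motion <- synth_motion(times, act, profile, height, absent_rate)
    seq <- motion_to_sequence(motion, times, subject_id, "FULL_RECORDING",
                              sample_rate)
    schedule <- tibble::tibble(cue_time_s = bounds[1:6], action = actions)
    list(sequence = seq, schedule = schedule, profile = profile)
  })
}

# Truncated-normal integer HAM-D scores within a band's interval.
sample_hamd <- function(n, mean, sd, lo, hi) {
  p <- runif(n, stats::pnorm(lo - 0.5, mean, sd),
             stats::pnorm(hi + 0.5, mean, sd))
  pmin(pmax(round(stats::qnorm(p, mean, sd)), lo), hi)
}

#' Generate a synthetic cohort with recordings
#'
#' Draws HDRS-24 totals inside each requested band (score distributions
#' emulating the clinical tables: NONE ~ 1.2 +/- 2, PROBABLE ~ 14 +/- 2,
#' MEDIUM ~ 25.7 +/- 3.5, SEVERE ~ 39.6 +/- 2.7, truncated to the band),
#' assigns groups, and simulates one stimulus-task recording per subject
#' with that band's effect profile.
#'
#' With `clinical_crossover = TRUE` (requires the default 130/14/50/16 band
#' sizes or larger), the group structure of the clinical cohort is
#' reproduced: 4 patients scoring below 8 and 2 patients scoring exactly 8
#' sit inside the NONE band, and 1 normal control scores inside PROBABLE --
#' the unique composition consistent with an 85/125 group split, 81/124
#' surviving the binary screen, and band sizes 16/50/14/130. Otherwise the
#' group is NORMAL for NONE-band subjects and PATIENT above.
#'
#' @param n_per_band Named counts for NONE/PROBABLE/MEDIUM/SEVERE.
#' @param seed Integer seed (drives scores, ages, heights, recordings).
#' @param clinical_crossover Reproduce the clinical group/band overlap.
#' @param duration,sample_rate,effect_multiplier,absent_rate,jitter_sd
#'   Passed to [generate_recording()].
#' @param recordings Simulate motion recordings (default `TRUE`); with
#'   `FALSE` only the metadata table is generated.
#' @return List with `records` (tibble: `subject_id`, `group`, `age`,
#'   `hamd_score`, `band`), `recordings` (named list of sequences), and
#'   `schedules` (named list of cue schedules).
#' @export
generate_cohort <- function(n_per_band = c(NONE = 130, PROBABLE = 14,
                                           MEDIUM = 50, SEVERE = 16),
                            seed = 1, clinical_crossover = FALSE,
                            duration = 60, sample_rate = 30,
                            effect_multiplier = 1, absent_rate = 0.15,
                            jitter_sd = NULL, recordings = TRUE) {
  n_per_band <- n_per_band[severity_bands()]
  names(n_per_band) <- severity_bands()
  n_per_band[is.na(n_per_band)] <- 0
  if (clinical_crossover && (n_per_band["NONE"] < 7 ||
                             n_per_band["PROBABLE"] < 1)) {
    abort("clinical_crossover needs at least 7 NONE and 1 PROBABLE subjects")
  }
  score_par <- list(
    NONE = c(1.2, 2.0, 0, 8), PROBABLE = c(14.0, 2.0, 9, 20),
    MEDIUM = c(25.7, 3.5, 21, 35), SEVERE = c(39.6, 2.7, 36, 52)
  )
  total <- sum(n_per_band)
  records <- withr::with_seed(seed, {
    rows <- list()
    sid <- 0
    for (band in severity_bands()) {
      nb <- n_per_band[[band]]
      if (nb == 0) next
      pr <- score_par[[band]]
      scores <- sample_hamd(nb, pr[1], pr[2], pr[3], pr[4])
      group <- if (band == "NONE") rep("NORMAL", nb) else rep("PATIENT", nb)
      if (clinical_crossover && band == "NONE") {
        # 4 recovered patients (<8) and 2 patients at the boundary (=8)
        group[1:6] <- "PATIENT"
        scores[1:4] <- sample_hamd(4, 5, 1.5, 0, 7)
        scores[5:6] <- 8
      }
      if (clinical_crossover && band == "PROBABLE") {
        group[1] <- "NORMAL" # one control scoring above the cutpoint
      }
      age <- pmin(pmax(round(rnorm(nb, 39, 14)), 18), 65)
      for (i in seq_len(nb)) {
        sid <- sid + 1
        rows[[sid]] <- tibble::tibble(
          subject_id = sprintf("S%03d", sid), group = group[i],
          age = age[i], hamd_score = scores[i])
      }
    }
    dplyr::bind_rows(rows)
  })
  records$band <- band_score(records$hamd_score)
  if (!recordings) {
    return(list(records = records, recordings = list(), schedules = list()))
  }
  rec_seeds <- withr::with_seed(seed + 1, sample.int(.Machine$integer.max - 1,
                                                     total))
  recordings <- vector("list", total)
  schedules <- vector("list", total)
  for (i in seq_len(total)) {
    sim <- generate_recording(
      as.character(records$band[i]), subject_id = records$subject_id[i],
      seed = rec_seeds[i], duration = duration, sample_rate = sample_rate,
      effect_multiplier = effect_multiplier, absent_rate = absent_rate,
      jitter_sd = jitter_sd)
    recordings[[i]] <- sim$sequence
    schedules[[i]] <- sim$schedule
  }
  names(recordings) <- records$subject_id
  names(schedules) <- records$subject_id
  list(records = records, recordings = recordings, schedules = schedules)
}

#' Write a simulated cohort to disk
#'
#' Writes one recording file per subject (CSV dialect), the subject
#' metadata CSV and a combined cue-schedule CSV under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [generate_cohort()].
#' @return Invisibly, a list of written paths.
#' @export
simulate_cohort <- function(out_dir, ...) {
  cohort <- generate_cohort(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec_dir <- file.path(out_dir, "recordings")
  dir.create(rec_dir, showWarnings = FALSE)
  paths <- character(0)
  for (sid in names(cohort$recordings)) {
    p <- file.path(rec_dir, paste0(sid, ".csv"))
    write_recording(cohort$recordings[[sid]], p, "csv")
    paths <- c(paths, p)
  }
  meta <- file.path(out_dir, "metadata.csv")
  write_subjects(cohort$records, meta)
  sched <- dplyr::bind_rows(
    lapply(names(cohort$schedules), function(sid) {
      dplyr::mutate(cohort$schedules[[sid]], subject_id = sid,
                    .before = 1)
    })
  )
  sched_path <- file.path(out_dir, "cue_schedules.csv")
  readr::write_csv(sched, sched_path, progress = FALSE)
  invisible(list(metadata = meta, schedules = sched_path,
                 recordings = paths))
}
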