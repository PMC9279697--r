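# Synthetic stimulus-task motion: determinism, schema validity, kinematic
# effects, bone-length conservation, cohort structure.

test_that("generation is deterministic under a fixed seed", {
  a <- generate_recording("MEDIUM", seed = 7, duration = 1)
  b <- generate_recording("MEDIUM", seed = 7, duration = 1)
  expect_identical(tibble::as_tibble(a$sequence), tibble::as_tibble(b$sequence))
  expect_identical(a$schedule, b$schedule)
  c1 <- generate_cohort(n_per_band = c(NONE = 3, PROBABLE = 2, MEDIUM = 2,
                                       SEVERE = 2),
                        seed = 5, recordings = FALSE)
  c2 <- generate_cohort(n_per_band = c(NONE = 3, PROBABLE = 2, MEDIUM = 2,
                                       SEVERE = 2),
                        seed = 5, recordings = FALSE)
  expect_identical(c1$records, c2$records)
})

test_that("generated sequences are schema-valid", {
  for (band in severity_bands()) {
    rec <- generate_action("LIFT_LEFT", severity_profile(band), seed = 3,
                           duration = 1)
    expect_identical(nrow(validate_schema(rec)), 0L)
  }
  full <- generate_recording("SEVERE", seed = 4, duration = 2)$sequence
  expect_identical(nrow(validate_schema(full)), 0L)
})

test_that("a recording is 1800 frames at 60 s / 30 Hz and segments on its cue schedule", {
  rec <- generate_recording("PROBABLE", seed = 6, duration = 60,
                            sample_rate = 30)
  expect_equal(length(unique(rec$sequence$frame)), 1800)
  segs <- segment_by_cues(rec$sequence, rec$schedule$cue_time_s[-1])
  expect_length(segs, 6)
  expect_identical(vapply(segs, function(s) attr(s, "action"), character(1)),
                   rec$schedule$action)
  # evenly spaced cues -> equal segment sizes
  expect_equal(unique(vapply(segs, function(s) length(unique(s$frame)),
                             integer(1))), 300)
})

test_that("amplitude scaling halves the peak angular excursion of the wrist", {
  prof1 <- severity_profile("NONE")
  prof1$jitter_sd <- 0
  prof05 <- prof1
  prof05$amplitude_scale <- 0.5
  peak_angle <- function(prof) {
    rec <- generate_action("LIFT_LEFT", prof, height = 1.75, seed = 8,
                           duration = 10, absent_rate = 0)
    wrist <- rec[rec$joint == "WristLeft", c("x", "y", "z")]
    shoulder <- rec[rec$joint == "ShoulderLeft", c("x", "y", "z")]
    off <- as.matrix(wrist) - as.matrix(shoulder)
    rest <- off[1, ]
    cosang <- (off %*% rest) / (sqrt(rowSums(off^2)) * sqrt(sum(rest^2)))
    max(acos(pmin(pmax(cosang, -1), 1)))
  }
  a1 <- peak_angle(prof1)
  a05 <- peak_angle(prof05)
  expect_equal(a05 / a1, 0.5, tolerance = 0.02)
})

test_that("severe recordings move strictly slower than healthy ones", {
  speed <- function(band) {
    rec <- generate_recording(band, seed = 10, duration = 12,
                              effect_multiplier = 1, jitter_sd = 0)$sequence
    hand <- as.matrix(rec[rec$joint == "HandLeft", c("x", "y", "z")])
    mean(sqrt(rowSums(diff(hand)^2))) * attr(rec, "sample_rate")
  }
  expect_lt(speed("SEVERE"), speed("NONE"))
})

test_that("kinematic effects are monotone across severity bands", {
  # profile table is monotone by construction
  profs <- lapply(severity_bands(), severity_profile)
  amp <- vapply(profs, `[[`, numeric(1), "amplitude_scale")
  vel <- vapply(profs, `[[`, numeric(1), "velocity_scale")
  delay_sd <- vapply(profs, `[[`, numeric(1), "reaction_delay_sd")
  pitch <- vapply(profs, `[[`, numeric(1), "head_pitch_offset")
  expect_true(all(diff(amp) < 0))
  expect_true(all(diff(vel) < 0))
  expect_true(all(diff(delay_sd) > 0))
  expect_true(all(diff(pitch) > 0))
  # and empirically: per-band mean hand speed decreases over 30 subjects/band
  band_speed <- function(band, n = 30) {
    speeds <- vapply(seq_len(n), function(i) {
      rec <- generate_recording(band, seed = 1000 + i, duration = 6,
                                jitter_sd = 0, absent_rate = 0)$sequence
      hand <- as.matrix(rec[rec$joint == "HandRight", c("x", "y", "z")])
      mean(sqrt(rowSums(diff(hand)^2)))
    }, numeric(1))
    mean(speeds)
  }
  ms <- vapply(severity_bands(), band_speed, numeric(1))
  expect_true(all(diff(ms) < 0))
})

test_that("bone lengths are conserved across frames on noise-free trajectories", {
  rec <- generate_recording("SEVERE", seed = 12, duration = 4,
                            jitter_sd = 0, absent_rate = 0)$sequence
  bones <- kinect_bones()
  df <- tibble::as_tibble(rec)
  for (b in seq_len(nrow(bones))) {
    from <- as.matrix(df[df$joint == bones$from[b], c("x", "y", "z")])
    to <- as.matrix(df[df$joint == bones$to[b], c("x", "y", "z")])
    len <- sqrt(rowSums((from - to)^2))
    expect_lt(max(abs(len - len[1])) / len[1], 1e-6)
  }
})

test_that("zeroed effect multiplier makes all severity profiles identical", {
  base <- severity_profile("NONE", effect_multiplier = 0)
  for (band in severity_bands()) {
    p <- severity_profile(band, effect_multiplier = 0)
    expect_equal(p[names(p) != "band"], base[names(base) != "band"])
  }
})

test_that("cohort scores respect their band intervals and requested counts", {
  cohort <- generate_cohort(
    n_per_band = c(NONE = 16, PROBABLE = 50, MEDIUM = 14, SEVERE = 130),
    seed = 9, recordings = FALSE)$records
  counts <- table(factor(cohort$band, levels = severity_bands()))
  expect_equal(as.integer(counts), c(16, 50, 14, 130))
  expect_true(all(cohort$hamd_score[cohort$band == "NONE"] <= 8))
  expect_true(all(cohort$hamd_score[cohort$band == "PROBABLE"] > 8 &
                    cohort$hamd_score[cohort$band == "PROBABLE"] <= 20))
  expect_true(all(cohort$hamd_score[cohort$band == "SEVERE"] > 35))
  expect_true(all(cohort$age >= 18 & cohort$age <= 65))
})

test_that("simulate_cohort writes recordings, metadata and schedules", {
  dir <- withr::local_tempdir()
  paths <- simulate_cohort(dir, n_per_band = c(NONE = 2, PROBABLE = 0,
                                               MEDIUM = 1, SEVERE = 0),
                           seed = 2, duration = 1)
  expect_true(file.exists(paths$metadata))
  expect_length(paths$recordings, 3)
  meta <- read_subjects(paths$metadata)
  expect_equal(nrow(meta), 3)
  rec <- read_recording(paths$recordings[1], "csv")
  expect_identical(nrow(validate_schema(rec)), 0L)
})
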