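# Reading, writing and validating skeleton recordings and subject metadata.
#
# On-disk dialects:
#  * CSV: long format, one row per (frame, joint), mandatory header
#    frame,timestamp,joint,x,y,z,rx,ry,rz,rw,tracked. Empty quaternion cells
#    mean the orientation is absent (never zero-filled on read).
#  * JSONL: one frame object per line:
#    {"frame":0,"timestamp":0.0,"joints":[{"joint":"SpineBase","x":..., ...,
#     "rx":... or null, "tracked":true}, ...]}

#' Construct a skeleton sequence
#'
#' A skeleton sequence is a long-format tibble with one row per
#' (frame, joint): columns `frame`, `timestamp`, `joint`, `x`, `y`, `z`,
#' `rx`, `ry`, `rz`, `rw`, `tracked`. Positions are meters in sensor space;
#' orientations are unit quaternions with all four components `NA` when the
#' sensor reports none for that joint. Frames hold exactly the 25 canonical
#' Kinect V2 joints in canonical order. Recording-level fields
#' (`subject_id`, `action`, `sample_rate`) are carried as attributes.
#'
#' @param frames Tibble/data frame in the long format above.
#' @param subject_id Subject identifier string.
#' @param action One of [stimulus_actions()] or `"FULL_RECORDING"`.
#' @param sample_rate Nominal sampling rate in Hz (default 30).
#' @param validate Check schema and abort on violations (default `TRUE`).
#' @return A `skeleton_sequence` tibble.
#' @export
skeleton_sequence <- function(frames, subject_id = "unknown",
                              action = "FULL_RECORDING", sample_rate = 30,
                              validate = TRUE) {
  frames <- tibble::as_tibble(frames)
  needed <- c("frame", "timestamp", "joint", "x", "y", "z",
              "rx", "ry", "rz", "rw", "tracked")
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols) > 0) {
    abort(paste0("skeleton_sequence is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  frames <- frames[needed]
  out <- structure(
    frames,
    subject_id = subject_id,
    action = action,
    sample_rate = sample_rate,
    class = c("skeleton_sequence", class(tibble::tibble()))
  )
  if (validate) {
    report <- validate_schema(out)
    if (nrow(report) > 0) {
      abort(paste0(
        "invalid skeleton sequence (", nrow(report), " violation(s)); first: ",
        report$rule[1], " [frame ", report$frame[1], ", joint ",
        report$joint[1], "]"
      ))
    }
  }
  out
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  n_frames <- length(unique(x$frame))
  cat(sprintf(
    "<skeleton_sequence> subject %s, action %s, %d frames @ %g Hz\n",
    attr(x, "subject_id"), attr(x, "action"), n_frames,
    attr(x, "sample_rate")
  ))
  NextMethod()
}

n_frames <- function(seq) length(unique(seq$frame))

#' Validate a skeleton sequence against the schema
#'
#' Checks every container invariant and returns violations as data (one row
#' per violation) rather than raising conditions: exactly the 25 canonical
#' joints per frame in canonical order, strictly increasing timestamps,
#' finite positions, all-or-none quaternion components with unit norm
#' (tolerance 1e-6), and a positive sample rate.
#'
#' @param seq A `skeleton_sequence` (or long-format data frame).
#' @return Tibble with columns `frame`, `joint`, `rule`, `detail`; zero rows
#'   iff the sequence is schema-valid.
#' @export
validate_schema <- function(seq) {
  violations <- list()
  add <- function(frame, joint, rule, detail = "") {
    violations[[length(violations) + 1]] <<-
      tibble::tibble(frame = as.integer(frame), joint = joint,
                     rule = rule, detail = detail)
  }

  if (nrow(seq) == 0) {
    add(NA, NA_character_, "non_empty", "sequence has no frames")
    return(dplyr::bind_rows(violations))
  }
  sr <- attr(seq, "sample_rate")
  if (!is.null(sr) && (!is.finite(sr) || sr <= 0)) {
    add(NA, NA_character_, "sample_rate_positive", paste0("sample_rate=", sr))
  }

  canonical <- kinect_joints()
  by_frame <- split(seq_len(nrow(seq)), seq$frame)
  frame_ids <- as.integer(names(by_frame))
  ord <- order(frame_ids)
  by_frame <- by_frame[ord]
  frame_ids <- frame_ids[ord]

  ts <- vapply(by_frame, function(idx) seq$timestamp[idx][1], numeric(1))
  if (length(ts) > 1) {
    bad <- which(diff(ts) <= 0)
    for (b in bad) {
      add(frame_ids[b + 1], NA_character_, "timestamps_strictly_increasing",
          sprintf("timestamp %g after %g", ts[b + 1], ts[b]))
    }
  }

  for (k in seq_along(by_frame)) {
    idx <- by_frame[[k]]
    fid <- frame_ids[k]
    joints <- seq$joint[idx]
    if (length(joints) != 25 || !identical(as.character(joints), canonical)) {
      if (length(joints) != 25) {
        add(fid, NA_character_, "joint_count_25",
            sprintf("frame has %d joints", length(joints)))
      } else {
        add(fid, NA_character_, "canonical_joint_order",
            "joints present but not in canonical Kinect V2 order")
      }
      next
    }
    pos <- as.matrix(seq[idx, c("x", "y", "z")])
    badpos <- which(!apply(is.finite(pos), 1, all))
    for (b in badpos) add(fid, joints[b], "position_finite")
    quat <- as.matrix(seq[idx, c("rx", "ry", "rz", "rw")])
    n_na <- rowSums(is.na(quat))
    partial <- which(n_na > 0 & n_na < 4)
    for (b in partial) add(fid, joints[b], "quaternion_all_or_none")
    present <- which(n_na == 0)
    if (length(present) > 0) {
      norms <- sqrt(rowSums(quat[present, , drop = FALSE]^2))
      off <- which(abs(norms - 1) > 1e-6)
      for (b in off) {
        add(fid, joints[present[b]], "quaternion_unit_norm",
            sprintf("norm %.8f", norms[b]))
      }
    }
  }
  if (length(violations) == 0) {
    return(tibble::tibble(frame = integer(), joint = character(),
                          rule = character(), detail = character()))
  }
  dplyr::bind_rows(violations)
}

#' Read a skeleton recording
#'
#' @param path File path.
#' @param dialect `"csv"` (long format, one row per frame-joint) or `"jsonl"`
#'   (one frame object per line).
#' @param subject_id,action,sample_rate Recording-level metadata; defaults:
#'   file name stem, `"FULL_RECORDING"`, 30 Hz.
#' @return A [skeleton_sequence()].
#' @export
read_recording <- function(path, dialect = c("csv", "jsonl"),
                           subject_id = NULL, action = "FULL_RECORDING",
                           sample_rate = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  frames <- switch(dialect,
    csv = read_recording_csv(path),
    jsonl = read_recording_jsonl(path)
  )
  skeleton_sequence(frames, subject_id = subject_id, action = action,
                    sample_rate = sample_rate, validate = TRUE)
}

read_recording_csv <- function(path) {
  cols <- readr::cols(
    frame = readr::col_integer(),
    timestamp = readr::col_double(),
    joint = readr::col_character(),
    x = readr::col_double(), y = readr::col_double(),
    z = readr::col_double(),
    rx = readr::col_double(), ry = readr::col_double(),
    rz = readr::col_double(), rw = readr::col_double(),
    tracked = readr::col_logical()
  )
  df <- suppressWarnings(
    readr::read_csv(path, col_types = cols, progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error in %s at line %d: expected %s, got '%s'",
                  path, probs$row[1] + 1L, probs$expected[1], probs$actual[1]))
  }
  expected <- c("frame", "timestamp", "joint", "x", "y", "z",
                "rx", "ry", "rz", "rw", "tracked")
  if (!identical(names(df), expected)) {
    abort(paste0("CSV header must be exactly: ",
                 paste(expected, collapse = ",")))
  }
  df
}

read_recording_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty JSONL recording: ", path))
  frame_list <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
      error = function(e) {
        abort(sprintf("parse error in %s at line %d: %s",
                      path, i, conditionMessage(e)))
      }
    )
    joints <- tibble::as_tibble(obj$joints)
    for (col in c("rx", "ry", "rz", "rw")) {
      if (!col %in% names(joints)) joints[[col]] <- NA_real_
    }
    if (!"tracked" %in% names(joints)) joints$tracked <- TRUE
    frame_list[[i]] <- tibble::tibble(
      frame = as.integer(obj$frame),
      timestamp = as.numeric(obj$timestamp),
      joint = as.character(joints$joint),
      x = as.numeric(joints$x), y = as.numeric(joints$y),
      z = as.numeric(joints$z),
      rx = as.numeric(joints$rx), ry = as.numeric(joints$ry),
      rz = as.numeric(joints$rz), rw = as.numeric(joints$rw),
      tracked = as.logical(joints$tracked)
    )
  }
  dplyr::bind_rows(frame_list)
}

#' Write a skeleton recording
#'
#' Serializes with full double precision so that
#' `read_recording(write_recording(seq))` round-trips to 1e-9. Absent
#' quaternions are written as empty CSV cells / JSON nulls and recovered as
#' absent.
#'
#' @param seq A [skeleton_sequence()].
#' @param path Output file path.
#' @param dialect `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(seq, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (dialect == "csv") {
    df <- tibble::as_tibble(seq)
    num <- function(v) {
      out <- sprintf("%.17g", v)
      out[is.na(v)] <- ""
      out
    }
    lines <- paste(
      df$frame, sprintf("%.17g", df$timestamp), df$joint,
      num(df$x), num(df$y), num(df$z),
      num(df$rx), num(df$ry), num(df$rz), num(df$rw),
      tolower(as.character(df$tracked)),
      sep = ","
    )
    header <- "frame,timestamp,joint,x,y,z,rx,ry,rz,rw,tracked"
    ok <- tryCatch({
      writeLines(c(header, lines), path)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) abort(paste0("cannot write recording to ", path))
  } else {
    frames <- split(tibble::as_tibble(seq), seq$frame)
    frame_ids <- as.integer(names(frames))
    frames <- frames[order(frame_ids)]
    con <- tryCatch(file(path, "w"), error = function(e) NULL)
    if (is.null(con)) abort(paste0("cannot write recording to ", path))
    on.exit(close(con))
    for (fr in frames) {
      obj <- list(
        frame = fr$frame[1],
        timestamp = fr$timestamp[1],
        joints = fr[c("joint", "x", "y", "z", "rx", "ry", "rz", "rw",
                      "tracked")]
      )
      writeLines(
        jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null"),
        con
      )
    }
  }
  invisible(path)
}

#' Read / write subject metadata
#'
#' Subject metadata is a CSV with columns
#' `subject_id,group,age,hamd_score` (group is `PATIENT` or `NORMAL`).
#' [read_subjects()] derives the severity `band` column with [band_score()].
#'
#' @param path CSV path.
#' @return Tibble of subject records with a derived `band` column.
#' @export
read_subjects <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      age = readr::col_double(),
      hamd_score = readr::col_double()
    ),
    progress = FALSE
  )
  bad <- setdiff(unique(df$group), c("PATIENT", "NORMAL"))
  if (length(bad) > 0) {
    abort(paste0("unknown group value(s): ", paste(bad, collapse = ", ")))
  }
  if (any(df$hamd_score < 0)) abort("hamd_score must be non-negative")
  df$band <- band_score(df$hamd_score)
  df
}

#' @param records Tibble with columns `subject_id`, `group`, `age`,
#'   `hamd_score` (a `band` column, if present, is not serialized).
#' @rdname read_subjects
#' @export
write_subjects <- function(records, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    records[c("subject_id", "group", "age", "hamd_score")],
    path, progress = FALSE
  )
  invisible(path)
}
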