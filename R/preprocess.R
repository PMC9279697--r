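# Preprocessing: quaternion conversion, bounding-box validity, per-frame
# feature assembly, cue segmentation, min-max normalization and length
# regularization.

#' Convert Euler angles to a unit quaternion
#'
#' Uses the convention R = Rz(z) %*% Ry(y) %*% Rx(x) (extrinsic x-y-z, i.e.
#' roll about x, then pitch about y, then yaw about z, all in the fixed
#' frame). The returned quaternion components are ordered (x, y, z, w) to
#' match the Kinect channel order (Rx, Ry, Rz, Rw). Vectorized over angle
#' triples.
#'
#' @param x,y,z Rotation angles in radians about the respective fixed axes.
#' @return A length-4 named vector (x, y, z, w), or a matrix with one row per
#'   input triple when the inputs have length > 1.
#' @export
#' @examples
#' euler_to_quaternion(0, 0, 0)      # identity -> (0, 0, 0, 1)
#' euler_to_quaternion(pi, 0, 0)     # half-turn about x -> (1, 0, 0, 0)
euler_to_quaternion <- function(x, y = NULL, z = NULL) {
  if (is.null(y) && is.null(z) && length(x) == 3) {
    z <- x[3]; y <- x[2]; x <- x[1]
  }
  if (!all(is.finite(x), is.finite(y), is.finite(z))) {
    abort("euler_to_quaternion: angles must be finite")
  }
  cx <- cos(x / 2); sx <- sin(x / 2)
  cy <- cos(y / 2); sy <- sin(y / 2)
  cz <- cos(z / 2); sz <- sin(z / 2)
  # q = qz * qy * qx (Hamilton product), components (x, y, z, w)
  qw <- cz * cy * cx + sz * sy * sx
  qx <- cz * cy * sx - sz * sy * cx
  qy <- cz * sy * cx + sz * cy * sx
  qz <- sz * cy * cx - cz * sy * sx
  out <- cbind(x = qx, y = qy, z = qz, w = qw)
  if (nrow(out) == 1) out[1, ] else out
}

#' Rotation matrix from a unit quaternion
#'
#' @param q Length-4 quaternion (x, y, z, w).
#' @return 3x3 rotation matrix.
#' @export
quaternion_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Hamilton product, vectorized over rows of (x, y, z, w) matrices.
quat_multiply <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  w <- a[, 4] * b[, 4] - a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3]
  x <- a[, 4] * b[, 1] + a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2]
  y <- a[, 4] * b[, 2] - a[, 1] * b[, 3] + a[, 2] * b[, 4] + a[, 3] * b[, 1]
  z <- a[, 4] * b[, 3] + a[, 1] * b[, 2] - a[, 2] * b[, 1] + a[, 3] * b[, 4]
  out <- cbind(x = x, y = y, z = z, w = w)
  if (nrow(out) == 1) out[1, ] else out
}

#' Sensor-space bounding box
#'
#' The capture volume within which joints are considered valid. The
#' coordinate naming follows the sensor's view (`x_right <= x <= x_left`,
#' `y_low <= y <= y_top`, `z_front <= z <= z_back`); the constructor
#' validates lo <= hi on each axis.
#'
#' @param x_right,x_left,y_low,y_top,z_front,z_back Box faces in meters.
#' @return A `bounding_box` list.
#' @export
bounding_box <- function(x_right, x_left, y_low, y_top, z_front, z_back) {
  if (x_right > x_left || y_low > y_top || z_front > z_back) {
    abort("bounding_box: each lower face must not exceed its upper face")
  }
  structure(
    list(x_right = x_right, x_left = x_left, y_low = y_low, y_top = y_top,
         z_front = z_front, z_back = z_back),
    class = "bounding_box"
  )
}

#' Is a point inside the capture volume?
#'
#' All three interval conditions are closed: a point exactly on a face is
#' inside. Vectorized over rows of a 3-column matrix.
#'
#' @param p Numeric length-3 vector (x, y, z) or an n x 3 matrix.
#' @param box A [bounding_box()].
#' @return Logical (scalar or length n).
#' @export
in_bounds <- function(p, box) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p[, 1] >= box$x_right & p[, 1] <= box$x_left &
    p[, 2] >= box$y_low & p[, 2] <= box$y_top &
    p[, 3] >= box$z_front & p[, 3] <= box$z_back
}

#' Construct a feature tensor
#'
#' @param values T x 175 numeric matrix (25 joints x 7 channels, canonical
#'   order, channels x,y,z,rx,ry,rz,rw per joint).
#' @param mask T x 175 logical matrix, `TRUE` where the entry was imputed
#'   (absent orientation or padding).
#' @param bounds `NULL`, or a list with numeric vectors `min` and `max`
#'   (length 175) recording the bounds used for normalization.
#' @return A `feature_tensor` object.
#' @export
feature_tensor <- function(values, mask = NULL, bounds = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 175) abort("feature_tensor: values must have 175 columns")
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  colnames(values) <- feature_channel_names()
  structure(list(values = values, mask = mask, bounds = bounds),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("<feature_tensor> %d frames x %d channels, %d imputed entries%s\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              if (is.null(x$bounds)) "" else ", normalized"))
  invisible(x)
}

#' Assemble a per-frame 175-vector from one skeleton frame
#'
#' Concatenates the 25 per-joint 7-vectors (x, y, z, rx, ry, rz, rw) in
#' canonical joint order. Absent orientations are imputed per policy and
#' flagged in the mask.
#'
#' @param frame One frame of a skeleton sequence (25 rows, long format).
#' @param imputation `"zeros"` (default) or `"identity_quat"` ((0,0,0,1)).
#' @return List with `values` (length 175) and `mask` (length-175 logical).
#' @export
assemble_joint_vector <- function(frame, imputation = c("zeros", "identity_quat")) {
  imputation <- match.arg(imputation)
  ord <- match(kinect_joints(), frame$joint)
  if (any(is.na(ord))) abort("assemble_joint_vector: frame is missing joints")
  frame <- frame[ord, ]
  m <- as.matrix(frame[, c("x", "y", "z", "rx", "ry", "rz", "rw")])
  mask <- is.na(m)
  fill <- if (imputation == "zeros") c(0, 0, 0, 0) else c(0, 0, 0, 1)
  for (ch in 4:7) m[is.na(m[, ch]), ch] <- fill[ch - 3]
  list(values = as.vector(t(m)), mask = as.vector(t(mask)))
}

#' Convert a skeleton sequence to a feature tensor
#'
#' Row t of the result is the frame-t joint vector of
#' [assemble_joint_vector()].
#'
#' @param seq A [skeleton_sequence()].
#' @inheritParams assemble_joint_vector
#' @return A [feature_tensor()].
#' @export
as_feature_tensor <- function(seq, imputation = c("zeros", "identity_quat")) {
  imputation <- match.arg(imputation)
  df <- tibble::as_tibble(seq)
  df <- df[order(df$frame), ]
  # canonical order within frame is guaranteed by the schema
  m <- as.matrix(df[, c("x", "y", "z", "rx", "ry", "rz", "rw")])
  t_count <- nrow(m) / 25
  if (t_count != round(t_count)) abort("sequence is not 25 joints per frame")
  mask <- is.na(m)
  fill <- if (imputation == "zeros") c(0, 0, 0, 0) else c(0, 0, 0, 1)
  for (ch in 4:7) m[is.na(m[, ch]), ch] <- fill[ch - 3]
  # rows are (frame, joint); fold joints into columns
  values <- matrix(t(m), nrow = t_count, byrow = TRUE)
  mk <- matrix(t(mask), nrow = t_count, byrow = TRUE)
  feature_tensor(values, mk)
}

#' Segment a recording at cue times
#'
#' Splits a recording into `length(cue_times) + 1` contiguous,
#' non-overlapping segments covering every frame: frames with timestamp
#' strictly before the first cue form segment 1, and so on. Concatenating
#' the segments reproduces the original frame sequence exactly.
#'
#' @param seq A [skeleton_sequence()].
#' @param cue_times Sorted cue times in seconds within the recording span.
#' @param actions Optional character vector of segment labels (length
#'   `length(cue_times) + 1`); defaults to [stimulus_actions()] when the
#'   count matches, otherwise `"SEGMENT_k"`.
#' @return List of `skeleton_sequence` objects.
#' @export
segment_by_cues <- function(seq, cue_times, actions = NULL) {
  if (is.unsorted(cue_times, strictly = TRUE)) {
    abort("segment_by_cues: cue_times must be strictly increasing")
  }
  n_seg <- length(cue_times) + 1
  if (is.null(actions)) {
    actions <- if (n_seg == 6) stimulus_actions()
               else paste0("SEGMENT_", seq_len(n_seg))
  }
  if (length(actions) != n_seg) {
    abort("segment_by_cues: need one action label per segment")
  }
  df <- tibble::as_tibble(seq)
  bin <- findInterval(df$timestamp, cue_times) + 1L
  lapply(seq_len(n_seg), function(k) {
    part <- df[bin == k, ]
    structure(part,
              subject_id = attr(seq, "subject_id"),
              action = actions[k],
              sample_rate = attr(seq, "sample_rate"),
              class = class(seq))
  })
}

#' Min-max normalization of a feature tensor
#'
#' Per-column affine map X* = (X - X_min) / (X_max - X_min). With fresh
#' bounds (the default) each column's observed minimum maps to 0 and maximum
#' to 1; a constant column maps to all zeros. With precomputed
#' (training-split) bounds the map is applied and the result clipped to
#' [0, 1], which prevents information from evaluation data leaking into the
#' scaling.
#'
#' @param ft A [feature_tensor()].
#' @param bounds `NULL` to fit bounds from `ft`, or a list with `min` and
#'   `max` vectors (length 175) as stored in a normalized tensor's `bounds`.
#' @return A normalized [feature_tensor()] carrying the bounds used.
#' @export
minmax_normalize <- function(ft, bounds = NULL) {
  X <- ft$values
  clip <- !is.null(bounds)
  if (is.null(bounds)) {
    bounds <- list(min = apply(X, 2, min), max = apply(X, 2, max))
  }
  rng <- bounds$max - bounds$min
  scale <- ifelse(rng > 0, 1 / rng, 0) # constant column -> all zeros
  Xs <- sweep(sweep(X, 2, bounds$min, "-"), 2, scale, "*")
  if (clip) Xs <- pmin(pmax(Xs, 0), 1)
  feature_tensor(Xs, ft$mask, bounds = bounds)
}

#' Invert a min-max normalization using stored bounds
#'
#' @param ft A normalized [feature_tensor()] with non-`NULL` `bounds`.
#' @return A [feature_tensor()] on the original scale.
#' @export
minmax_invert <- function(ft) {
  if (is.null(ft$bounds)) abort("minmax_invert: tensor carries no bounds")
  rng <- ft$bounds$max - ft$bounds$min
  X <- sweep(sweep(ft$values, 2, rng, "*"), 2, ft$bounds$min, "+")
  feature_tensor(X, ft$mask)
}

#' Regularize the length of a feature tensor
#'
#' Brings a tensor to exactly `target_T` rows so sequences can be batched at
#' a common length. `pad` repeats the last frame (marking padded rows in the
#' mask), `crop` keeps the first `target_T` frames, `resample` linearly
#' interpolates each channel onto `target_T` evenly spaced time points
#' (mask resampled by nearest neighbor). When padding a tensor longer than
#' `target_T`, or cropping a shorter one, the complementary operation is
#' applied so the contract (exactly `target_T` rows) always holds.
#'
#' @param ft A [feature_tensor()].
#' @param target_T Desired number of rows (>= 1).
#' @param mode `"pad"`, `"crop"` or `"resample"`.
#' @return A [feature_tensor()] with `target_T` rows.
#' @export
regularize_length <- function(ft, target_T, mode = c("pad", "crop", "resample")) {
  mode <- match.arg(mode)
  if (target_T < 1) abort("regularize_length: target_T must be >= 1")
  X <- ft$values
  T0 <- nrow(X)
  if (T0 == 0) abort("regularize_length: empty input")
  if (T0 == target_T) return(ft)
  if (mode == "resample") {
    at <- seq(1, T0, length.out = target_T)
    Xn <- apply(X, 2, function(col) approx(seq_len(T0), col, xout = at)$y)
    Xn <- matrix(Xn, nrow = target_T)
    near <- pmin(pmax(round(at), 1), T0)
    Mn <- ft$mask[near, , drop = FALSE]
    return(feature_tensor(Xn, Mn, ft$bounds))
  }
  if (T0 > target_T) { # crop (also the pad fallback for long inputs)
    return(feature_tensor(X[seq_len(target_T), , drop = FALSE],
                          ft$mask[seq_len(target_T), , drop = FALSE],
                          ft$bounds))
  }
  # pad by repeating the last frame, masked as imputed
  extra <- target_T - T0
  Xn <- rbind(X, matrix(rep(X[T0, ], extra), nrow = extra, byrow = TRUE))
  Mn <- rbind(ft$mask, matrix(TRUE, extra, ncol(X)))
  feature_tensor(Xn, Mn, ft$bounds)
}
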