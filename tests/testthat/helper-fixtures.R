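# Shared fixtures built in code.

# A minimal well-formed long-format frame table (t frames, 25 joints).
make_frames <- function(t = 2, quat = TRUE, sample_rate = 30) {
  joints <- kinect_joints()
  do.call(rbind, lapply(seq_len(t) - 1L, function(f) {
    tibble::tibble(
      frame = f, timestamp = f / sample_rate, joint = joints,
      x = seq(0, 1, length.out = 25) + f * 0.01,
      y = seq(1, 2, length.out = 25),
      z = 3,
      rx = if (quat) 0 else NA_real_,
      ry = if (quat) 0 else NA_real_,
      rz = if (quat) 0 else NA_real_,
      rw = if (quat) 1 else NA_real_,
      tracked = TRUE
    )
  }))
}

make_sequence <- function(t = 2, ...) {
  skeleton_sequence(make_frames(t, ...), subject_id = "fix", sample_rate = 30)
}

# Rotation-matrix oracle: compose the three axis rotations directly.
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, byrow = TRUE)
euler_matrix_oracle <- function(x, y, z) rot_z(z) %*% rot_y(y) %*% rot_x(x)

# Brute-force dilated causal convolution: the literal double-loop sum.
brute_dilated_conv <- function(x, f, d, bias = NULL) {
  t_len <- nrow(x)
  k <- dim(f)[1]
  c_out <- dim(f)[3]
  if (is.null(bias)) bias <- numeric(c_out)
  out <- matrix(rep(bias, each = t_len), t_len, c_out)
  for (s in seq_len(t_len)) {
    for (i in 0:(k - 1)) {
      src <- s - d * i
      if (src >= 1) out[s, ] <- out[s, ] + x[src, ] %*% f[i + 1, , ]
    }
  }
  out
}

# Small synthetic labeled dataset for classifier tests: n per class, binary,
# separable via the severity effect profile.
make_binary_dataset <- function(n_per_class = 6, t_len = 60, duration = 2,
                                effect_multiplier = 2, seed = 1) {
  cohort <- generate_cohort(
    n_per_band = c(NONE = n_per_class, PROBABLE = 0, MEDIUM = n_per_class,
                   SEVERE = 0),
    seed = seed, duration = duration, effect_multiplier = effect_multiplier)
  tensors <- lapply(cohort$recordings, function(s) {
    regularize_length(as_feature_tensor(s), t_len, "pad")
  })
  build_dataset(cohort$records, tensors, "binary")
}
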