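# Dilated causal convolution, receptive field, causality, classifier head.

test_that("dilated causal convolution matches the brute-force sum", {
  withr::with_seed(31, {
    for (case in 1:100) {
      t_len <- sample(4:64, 1)
      k <- sample(1:5, 1)
      d <- sample(c(1, 2, 4, 8), 1)
      c_in <- sample(1:4, 1)
      c_out <- sample(1:4, 1)
      x <- matrix(rnorm(t_len * c_in), t_len, c_in)
      f <- array(rnorm(k * c_in * c_out), c(k, c_in, c_out))
      bias <- rnorm(c_out)
      expect_lt(max(abs(dilated_causal_conv(x, f, d, bias) -
                          brute_dilated_conv(x, f, d, bias))), 1e-6)
    }
  })
})

test_that("k = 1 with a unit filter is the identity and d < 1 errors", {
  x <- matrix(rnorm(30), 10, 3)
  f <- array(0, c(1, 3, 3)); f[1, , ] <- diag(3)
  expect_equal(dilated_causal_conv(x, f, d = 5), x, ignore_attr = TRUE)
  expect_error(dilated_causal_conv(x, f, d = 0), "dilation")
})

test_that("d = 1 reduces to a standard causal convolution", {
  withr::with_seed(32, {
    x <- matrix(rnorm(40), 20, 2)
    f <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  })
  out <- dilated_causal_conv(x, f, d = 1)
  # standard convolution: out[s] = sum_i f[i] x[s - i]
  std <- matrix(0, 20, 2)
  for (s in 1:20) for (i in 0:2) {
    if (s - i >= 1) std[s, ] <- std[s, ] + x[s - i, ] %*% f[i + 1, , ]
  }
  expect_equal(out, std, tolerance = 1e-9)
})

test_that("receptive_field_start evaluates the clamped span formula", {
  expect_equal(receptive_field_start(10, 0, 3), 8) # 10 - (2^1 - 1) * 2
  expect_equal(receptive_field_start(10, 1, 3), 4) # 10 - 3 * 2
  expect_equal(receptive_field_start(10, 2, 3), 0) # clamped: 10 - 7 * 2 < 0
  expect_equal(receptive_field_start(5, 3, 1), 5)  # l = 1 sees only itself
  expect_equal(receptive_field_start(1, 2, 5), 0)  # clamp
})

test_that("empirical receptive field of stacked dilated convs matches the formula", {
  # stack of single causal convs, dilation 2^i at layer i, all-ones filters
  run_stack <- function(x, n_layers, l) {
    h <- x
    for (i in 0:(n_layers - 1)) {
      f <- array(1, c(l, 1, 1))
      h <- dilated_causal_conv(h, f, d = 2^i)
    }
    h
  }
  t_len <- 40
  for (l in c(2, 3, 5)) {
    for (i in 0:2) {
      base <- run_stack(matrix(0, t_len, 1), i + 1, l)
      t_probe <- 30 # 0-based output step
      s <- receptive_field_start(t_probe, i, l)
      # an impulse at s must reach the output at t_probe...
      x1 <- matrix(0, t_len, 1); x1[s + 1, 1] <- 1
      out1 <- run_stack(x1, i + 1, l)
      expect_gt(abs(out1[t_probe + 1, 1] - base[t_probe + 1, 1]), 0)
      # ...and an impulse one step earlier must not
      if (s > 0) {
        x0 <- matrix(0, t_len, 1); x0[s, 1] <- 1
        out0 <- run_stack(x0, i + 1, l)
        expect_equal(out0[t_probe + 1, 1], base[t_probe + 1, 1])
      }
    }
  }
})

test_that("temporal blocks and the full TCN are causal", {
  withr::with_seed(33, {
    for (net in 1:10) {
      cfg <- model_config(tcn_channels = rep(sample(4:8, 1), 3),
                          kernel_size = sample(2:3, 1), dropout = 0,
                          input_channels = 6, seed = sample(1e6, 1))
      m <- init_model(cfg)
      t_len <- 20
      x <- array(rnorm(t_len * 6), c(1, t_len, 6))
      y0 <- tcn_forward(m, x)$Y
      t_cut <- 12
      x2 <- x
      x2[1, (t_cut + 1):t_len, ] <- rnorm(6 * (t_len - t_cut), sd = 10)
      y2 <- tcn_forward(m, x2)$Y
      expect_equal(y2[1, 1:t_cut, ], y0[1, 1:t_cut, ], tolerance = 1e-10)
      expect_false(isTRUE(all.equal(y2[1, t_len, ], y0[1, t_len, ])))
    }
  })
})

test_that("a zero-weight temporal block with identity shortcut passes input through", {
  cfg <- model_config(tcn_channels = c(6, 6, 6), input_channels = 6,
                      dropout = 0, seed = 1)
  m <- init_model(cfg)
  for (nm in grep("^tb1_", names(m$params), value = TRUE)) {
    m$params[[nm]][] <- 0
  }
  x <- array(rnorm(2 * 10 * 6), c(2, 10, 6))
  blk <- kinedep:::temporal_block_fwd(x, m$params, 1, 1, 0, FALSE)
  expect_equal(blk$out, x)
})

test_that("the classifier projects to 768 = 3*16*16 and normalizes scores", {
  cfg <- model_config(n_classes = 2, tcn_channels = c(8, 8, 8),
                      input_channels = 6, dropout = 0, seed = 2)
  expect_equal(cfg$projection_dim, 768)
  expect_equal(prod(cfg$reshape_shape), cfg$projection_dim)
  expect_error(model_config(projection_dim = 768, reshape_shape = c(4, 16, 16)),
               "reshape")
  m <- init_model(cfg)
  withr::with_seed(5, {
    y_summary <- matrix(rnorm(3 * 8), 3, 8)
  })
  out <- classifier_forward(m, y_summary)
  expect_equal(rowSums(exp(out$logp)), rep(1, 3), tolerance = 1e-6)
  expect_equal(ncol(out$logp), 2)
  cfg4 <- model_config(n_classes = 4, tcn_channels = c(8, 8, 8),
                       input_channels = 6, dropout = 0, seed = 2)
  out4 <- classifier_forward(init_model(cfg4), y_summary)
  expect_equal(ncol(out4$logp), 4)
})

test_that("the 1-D classifier variant produces normalized scores too", {
  cfg <- model_config(n_classes = 2, tcn_channels = c(8, 8, 8),
                      input_channels = 6, dropout = 0, seed = 3,
                      classifier = "resnet18_1d")
  m <- init_model(cfg)
  withr::with_seed(6, {
    y_summary <- matrix(rnorm(2 * 8), 2, 8)
  })
  out <- classifier_forward(m, y_summary)
  expect_equal(rowSums(exp(out$logp)), rep(1, 2), tolerance = 1e-6)
})

test_that("the classifier head carries the standard ResNet-18 trunk parameter count", {
  m <- init_model(model_config(seed = 1))
  # oracle: layer-by-layer arithmetic of the standard trunk
  conv_p <- function(k, cin, cout) k * k * cin * cout
  bn_p <- function(c) 2 * c
  basic_block <- function(cin, cout, down) {
    p <- conv_p(3, cin, cout) + bn_p(cout) + conv_p(3, cout, cout) + bn_p(cout)
    if (down) p <- p + conv_p(1, cin, cout) + bn_p(cout)
    p
  }
  trunk <- conv_p(7, 3, 64) + bn_p(64) +
    basic_block(64, 64, FALSE) + basic_block(64, 64, FALSE) +
    basic_block(64, 128, TRUE) + basic_block(128, 128, FALSE) +
    basic_block(128, 256, TRUE) + basic_block(256, 256, FALSE) +
    basic_block(256, 512, TRUE) + basic_block(512, 512, FALSE)
  fc <- 512 * 2 + 2 # documented substitution: 2 classes instead of 1000
  expect_equal(n_parameters(m, "r_"), trunk + fc)
  expect_equal(trunk, 11176512) # the standard ResNet-18 trunk size
})

test_that("prediction is deterministic, ties break to the lowest class, shapes are checked", {
  cfg <- model_config(n_classes = 2, tcn_channels = c(8, 8, 8), seed = 4)
  m <- init_model(cfg)
  withr::with_seed(7, {
    ft <- feature_tensor(matrix(runif(20 * 175), 20, 175))
  })
  p1 <- predict(m, ft)
  p2 <- predict(m, ft)
  expect_identical(p1, p2)
  expect_error(predict(m, matrix(0, 10, 100)), "width")
  # tie case: uniform scores resolve to class 0
  scores <- matrix(log(0.5), 1, 2)
  expect_equal(apply(scores, 1, which.max) - 1L, 0L)
  m0 <- m
  m0$params$short_W[] <- 0; m0$params$short_b[] <- 0
  m0$params$r_fc_W[] <- 0; m0$params$r_fc_b[] <- 0
  p0 <- predict(m0, ft)
  expect_equal(p0$label, 0L)
})

test_that("checkpoints restore bit-identical evaluation outputs", {
  cfg <- model_config(n_classes = 2, tcn_channels = c(8, 8, 8), seed = 9)
  m <- init_model(cfg)
  withr::with_seed(8, {
    ft <- feature_tensor(matrix(runif(15 * 175), 15, 175))
  })
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(predict(m2, ft), predict(m, ft))
})
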