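# The TCN-ResNet18 network: stacked dilated causal temporal convolution
# blocks with skip connections, a linear projection and reshape, a ResNet-18
# classifier trunk, a linear shortcut to class logits, and a log-softmax
# residual output C = LogSoftmax(shortcut(Y) + ResNet18(reshape(Y))).

#' Model configuration
#'
#' @param n_classes 2 (binary) or 4 (severity bands).
#' @param input_channels Feature width per step; 175 = 25 joints x 7.
#' @param tcn_channels Channel width of each temporal block; all equal so the
#'   end-to-end skip connections can be summed (default 3 blocks of 64).
#' @param kernel_size Temporal kernel size l (default 3).
#' @param dropout Dropout rate inside the temporal blocks (default 0.2).
#' @param projection_dim Output width of the post-TCN linear layer
#'   (default 768).
#' @param reshape_shape Shape `(channels, height, width)` the 768-vector is
#'   reshaped to before the ResNet-18 trunk; its product must equal
#'   `projection_dim` (default `c(3, 16, 16)`).
#' @param classifier `"resnet18_2d"` (default: 2-D trunk on the reshaped
#'   map, the explicit reading of the printed architecture) or
#'   `"resnet18_1d"` (1-D convolutions along a 256-step axis with 3
#'   channels, the alternative reading).
#' @param summary How the per-step TCN output Y is reduced before the
#'   projection: `"last"` step (default) or `"mean"` over steps.
#' @param seed Integer seed for weight initialization.
#' @return A `model_config` list; dilation of block i is `2^(i-1)`.
#' @export
model_config <- function(n_classes = 2, input_channels = 175,
                         tcn_channels = c(64, 64, 64), kernel_size = 3,
                         dropout = 0.2, projection_dim = 768,
                         reshape_shape = c(3, 16, 16),
                         classifier = c("resnet18_2d", "resnet18_1d"),
                         summary = c("last", "mean"), seed = 42) {
  classifier <- match.arg(classifier)
  summary <- match.arg(summary)
  if (n_classes < 2) abort("model_config: n_classes must be >= 2")
  if (prod(reshape_shape) != projection_dim) {
    abort(sprintf(
      "model_config: prod(reshape_shape) = %d must equal projection_dim = %d",
      prod(reshape_shape), projection_dim))
  }
  if (length(unique(tcn_channels)) != 1) {
    abort("model_config: all temporal blocks must share one channel width (skip connections are summed)")
  }
  structure(
    list(n_classes = n_classes, input_channels = input_channels,
         tcn_channels = tcn_channels, kernel_size = kernel_size,
         dropout = dropout, projection_dim = projection_dim,
         reshape_shape = reshape_shape, classifier = classifier,
         summary = summary, seed = seed,
         dilations = 2^(seq_along(tcn_channels) - 1)),
    class = "model_config"
  )
}

#' Receptive-field start step of a dilated convolution stack
#'
#' For a stack of causal convolutions with kernel size `l` and dilation
#' schedule `d = 2^i`, the output at step `t` of layer `i` (0-based) can see
#' inputs back to step `s = max(0, t - (2^(i+1) - 1) * (l - 1))`.
#'
#' @param t Output step (0-based, >= 0).
#' @param i Layer index (0-based, >= 0).
#' @param l Kernel size (>= 1).
#' @return The first input step (0-based) inside the receptive field.
#' @export
receptive_field_start <- function(t, i, l) {
  pmax(0, t - (2^(i + 1) - 1) * (l - 1))
}

# He (fan-in) initialization helpers ---------------------------------------

he_conv1 <- function(k, c_in, c_out) {
  array(rnorm(k * c_in * c_out, sd = sqrt(2 / (k * c_in))),
        c(k, c_in, c_out))
}
he_conv2 <- function(kh, kw, c_in, c_out) {
  array(rnorm(kh * kw * c_in * c_out, sd = sqrt(2 / (kh * kw * c_in))),
        c(kh, kw, c_in, c_out))
}
he_linear <- function(d_in, d_out) {
  matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out)
}

# Static description of the ResNet-18 trunk: 4 stages of 2 basic blocks,
# widths doubling as the map halves.
resnet18_stages <- function() {
  list(widths = c(64, 128, 256, 512), strides = c(1, 2, 2, 2), blocks = 2)
}

#' Initialize a TCN-ResNet18 model
#'
#' Weights use fan-in-scaled Gaussian (He) initialization under the config
#' seed; batch-norm scales start at 1 with zero shift and unit running
#' variance.
#'
#' @param config A [model_config()].
#' @return A `kinedep_model`: list of `params`, `bn_state`, `config`.
#' @export
init_model <- function(config) {
  build <- function() {
    p <- list()
    bn <- list()
    add_bn <- function(name, c_n) {
      p[[paste0(name, "_g")]] <<- rep(1, c_n)
      p[[paste0(name, "_b")]] <<- rep(0, c_n)
      bn[[name]] <<- list(mean = rep(0, c_n), var = rep(1, c_n))
    }
    # temporal blocks
    c_in <- config$input_channels
    k <- config$kernel_size
    for (b in seq_along(config$tcn_channels)) {
      c_out <- config$tcn_channels[b]
      p[[sprintf("tb%d_c1_W", b)]] <- he_conv1(k, c_in, c_out)
      p[[sprintf("tb%d_c1_b", b)]] <- rep(0, c_out)
      p[[sprintf("tb%d_c2_W", b)]] <- he_conv1(k, c_out, c_out)
      p[[sprintf("tb%d_c2_b", b)]] <- rep(0, c_out)
      if (c_in != c_out) {
        p[[sprintf("tb%d_down_W", b)]] <- he_conv1(1, c_in, c_out)
        p[[sprintf("tb%d_down_b", b)]] <- rep(0, c_out)
      }
      c_in <- c_out
    }
    # projection and logit shortcut
    p$proj_W <- he_linear(c_in, config$projection_dim)
    p$proj_b <- rep(0, config$projection_dim)
    p$short_W <- he_linear(config$projection_dim, config$n_classes)
    p$short_b <- rep(0, config$n_classes)
    # ResNet-18 trunk
    st <- resnet18_stages()
    in_c <- config$reshape_shape[1]
    if (config$classifier == "resnet18_2d") {
      p$r_conv1_W <- he_conv2(7, 7, in_c, 64)
    } else {
      p$r_conv1_W <- he_conv2(1, 7, in_c, 64)
    }
    add_bn("r_bn1", 64)
    cur <- 64
    kern <- if (config$classifier == "resnet18_2d") c(3, 3) else c(1, 3)
    for (l in seq_along(st$widths)) {
      w <- st$widths[l]
      for (blk in seq_len(st$blocks)) {
        pre <- sprintf("r_l%db%d", l, blk)
        p[[paste0(pre, "_c1_W")]] <- he_conv2(kern[1], kern[2], cur, w)
        add_bn(paste0(pre, "_bn1"), w)
        p[[paste0(pre, "_c2_W")]] <- he_conv2(kern[1], kern[2], w, w)
        add_bn(paste0(pre, "_bn2"), w)
        if (blk == 1 && (cur != w || st$strides[l] != 1)) {
          p[[paste0(pre, "_down_W")]] <- he_conv2(1, 1, cur, w)
          add_bn(paste0(pre, "_dbn"), w)
        }
        cur <- w
      }
    }
    p$r_fc_W <- he_linear(512, config$n_classes)
    p$r_fc_b <- rep(0, config$n_classes)
    list(params = p, bn_state = bn)
  }
  built <- if (is.null(config$seed)) build() else
    withr::with_seed(config$seed, build())
  structure(list(params = built$params, bn_state = built$bn_state,
                 config = config),
            class = "kinedep_model")
}

#' @export
print.kinedep_model <- function(x, ...) {
  cat(sprintf(
    "<kinedep_model> %d temporal blocks (k=%d, dilations %s) + %s head, %d classes, %s parameters\n",
    length(x$config$tcn_channels), x$config$kernel_size,
    paste(x$config$dilations, collapse = "/"), x$config$classifier,
    x$config$n_classes, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Parameter counts
#'
#' @param model A `kinedep_model`.
#' @param prefix Count only parameters whose name starts with this prefix
#'   (e.g. `"r_"` for the ResNet-18 classifier head).
#' @return Integer parameter count.
#' @export
n_parameters <- function(model, prefix = NULL) {
  p <- model$params
  if (!is.null(prefix)) p <- p[startsWith(names(p), prefix)]
  sum(vapply(p, length, integer(1)))
}

# ---- forward / backward -------------------------------------------------

temporal_block_fwd <- function(x, p, b, d, dropout, training) {
  c1 <- conv1d_causal_fwd(x, p[[sprintf("tb%d_c1_W", b)]],
                          p[[sprintf("tb%d_c1_b", b)]], d)
  r1 <- relu_fwd(c1$out)
  dr1 <- dropout_fwd(r1$out, dropout, training)
  c2 <- conv1d_causal_fwd(dr1$out, p[[sprintf("tb%d_c2_W", b)]],
                          p[[sprintf("tb%d_c2_b", b)]], d)
  r2 <- relu_fwd(c2$out)
  dr2 <- dropout_fwd(r2$out, dropout, training)
  down_nm <- sprintf("tb%d_down_W", b)
  if (!is.null(p[[down_nm]])) {
    dn <- conv1d_causal_fwd(x, p[[down_nm]],
                            p[[sprintf("tb%d_down_b", b)]], 1)
    res <- dn$out
  } else {
    dn <- NULL
    res <- x
  }
  list(out = dr2$out + res,
       cache = list(c1 = c1, r1 = r1, dr1 = dr1, c2 = c2, r2 = r2,
                    dr2 = dr2, dn = dn, b = b, d = d))
}

temporal_block_bwd <- function(dout, cache, p) {
  b <- cache$b; d <- cache$d
  g <- list()
  dmain <- dropout_bwd(dout, cache$dr2)
  dmain <- relu_bwd(dmain, cache$r2)
  bw2 <- conv1d_causal_bwd(dmain, cache$c2, p[[sprintf("tb%d_c2_W", b)]], d)
  g[[sprintf("tb%d_c2_W", b)]] <- bw2$dW
  g[[sprintf("tb%d_c2_b", b)]] <- bw2$db
  dmain <- dropout_bwd(bw2$dx, cache$dr1)
  dmain <- relu_bwd(dmain, cache$r1)
  bw1 <- conv1d_causal_bwd(dmain, cache$c1, p[[sprintf("tb%d_c1_W", b)]], d)
  g[[sprintf("tb%d_c1_W", b)]] <- bw1$dW
  g[[sprintf("tb%d_c1_b", b)]] <- bw1$db
  dx <- bw1$dx
  if (!is.null(cache$dn)) {
    bwd <- conv1d_causal_bwd(dout, cache$dn, p[[sprintf("tb%d_down_W", b)]], 1)
    g[[sprintf("tb%d_down_W", b)]] <- bwd$dW
    g[[sprintf("tb%d_down_b", b)]] <- bwd$db
    dx <- dx + bwd$dx
  } else {
    dx <- dx + dout
  }
  list(dx = dx, grads = g)
}

#' Forward pass of the temporal convolution stack
#'
#' Runs the dilated causal temporal blocks (dilation `2^(i-1)` for block i)
#' and sums their outputs through end-to-end skip connections.
#'
#' @param model A `kinedep_model`.
#' @param x Numeric array `[N x T x C_in]` (or a `[T x C_in]` matrix for a
#'   single sequence).
#' @param training Enable dropout (default `FALSE`).
#' @return List with `Y` (`[N x T x C]` skip-summed per-step outputs),
#'   `summary` (`[N x C]` pooled per-sequence vector), and `caches`
#'   (internal, for backprop).
#' @export
tcn_forward <- function(model, x, training = FALSE) {
  if (is.matrix(x)) x <- array(x, c(1, nrow(x), ncol(x)))
  p <- model$params
  cfg <- model$config
  caches <- list()
  skip <- NULL
  h <- x
  for (b in seq_along(cfg$tcn_channels)) {
    blk <- temporal_block_fwd(h, p, b, cfg$dilations[b], cfg$dropout,
                              training)
    caches[[b]] <- blk$cache
    h <- blk$out
    skip <- if (is.null(skip)) h else skip + h
  }
  t_len <- dim(skip)[2]
  summ <- if (cfg$summary == "last") {
    matrix(skip[, t_len, , drop = FALSE], dim(skip)[1], dim(skip)[3])
  } else {
    matrix(apply(skip, c(1, 3), mean), dim(skip)[1], dim(skip)[3])
  }
  list(Y = skip, summary = summ, caches = caches)
}

tcn_backward <- function(dY, dsumm, caches, model) {
  cfg <- model$config
  n_b <- length(cfg$tcn_channels)
  d <- dim(dY)
  t_len <- d[2]
  # gradient into the skip sum: dY plus the summary path
  dskip <- dY
  if (!is.null(dsumm)) {
    if (cfg$summary == "last") {
      dskip[, t_len, ] <- dskip[, t_len, , drop = FALSE] +
        array(dsumm, c(d[1], 1, d[3]))
    } else {
      dskip <- dskip + aperm(array(dsumm / t_len, c(d[1], d[3], t_len)),
                             c(1, 3, 2))
    }
  }
  grads <- list()
  dh <- array(0, d) # gradient flowing down the main chain
  for (b in rev(seq_len(n_b))) {
    dblock <- dh + dskip # every block output also feeds the skip sum
    bk <- temporal_block_bwd(dblock, caches[[b]], model$params)
    grads <- c(grads, bk$grads)
    dh <- bk$dx
    if (b == 1) return(list(grads = grads, dx = dh))
  }
}

resblock_fwd <- function(x, p, bn, pre, stride, kern, training) {
  pad <- floor(kern / 2) # 'same' padding at stride 1
  c1 <- conv2d_fwd(x, p[[paste0(pre, "_c1_W")]], numeric(dim(p[[paste0(pre, "_c1_W")]])[4]),
                   stride = stride, pad = pad)
  b1 <- bn_fwd(c1$out, p[[paste0(pre, "_bn1_g")]], p[[paste0(pre, "_bn1_b")]],
               bn[[paste0(pre, "_bn1")]], training)
  bn[[paste0(pre, "_bn1")]] <- b1$state
  r1 <- relu_fwd(b1$out)
  c2 <- conv2d_fwd(r1$out, p[[paste0(pre, "_c2_W")]], numeric(dim(p[[paste0(pre, "_c2_W")]])[4]),
                   stride = c(1, 1), pad = pad)
  b2 <- bn_fwd(c2$out, p[[paste0(pre, "_bn2_g")]], p[[paste0(pre, "_bn2_b")]],
               bn[[paste0(pre, "_bn2")]], training)
  bn[[paste0(pre, "_bn2")]] <- b2$state
  down_nm <- paste0(pre, "_down_W")
  if (!is.null(p[[down_nm]])) {
    dn <- conv2d_fwd(x, p[[down_nm]], numeric(dim(p[[down_nm]])[4]),
                     stride = stride, pad = c(0, 0))
    db <- bn_fwd(dn$out, p[[paste0(pre, "_dbn_g")]], p[[paste0(pre, "_dbn_b")]],
                 bn[[paste0(pre, "_dbn")]], training)
    bn[[paste0(pre, "_dbn")]] <- db$state
    res <- db$out
  } else {
    dn <- NULL; db <- NULL
    res <- x
  }
  rout <- relu_fwd(b2$out + res)
  list(out = rout$out, bn = bn,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, dn = dn,
                    db = db, rout = rout, pre = pre, stride = stride,
                    pad = pad))
}

resblock_bwd <- function(dout, cache, p) {
  pre <- cache$pre
  g <- list()
  dsum <- relu_bwd(dout, cache$rout)
  # main branch
  b2 <- bn_bwd(dsum, cache$b2, p[[paste0(pre, "_bn2_g")]])
  g[[paste0(pre, "_bn2_g")]] <- b2$dgamma
  g[[paste0(pre, "_bn2_b")]] <- b2$dbeta
  c2 <- conv2d_bwd(b2$dx, cache$c2, p[[paste0(pre, "_c2_W")]],
                   stride = c(1, 1), pad = cache$pad)
  g[[paste0(pre, "_c2_W")]] <- c2$dW
  dr1 <- relu_bwd(c2$dx, cache$r1)
  b1 <- bn_bwd(dr1, cache$b1, p[[paste0(pre, "_bn1_g")]])
  g[[paste0(pre, "_bn1_g")]] <- b1$dgamma
  g[[paste0(pre, "_bn1_b")]] <- b1$dbeta
  c1 <- conv2d_bwd(b1$dx, cache$c1, p[[paste0(pre, "_c1_W")]],
                   stride = cache$stride, pad = cache$pad)
  g[[paste0(pre, "_c1_W")]] <- c1$dW
  dx <- c1$dx
  # shortcut branch
  if (!is.null(cache$dn)) {
    db <- bn_bwd(dsum, cache$db, p[[paste0(pre, "_dbn_g")]])
    g[[paste0(pre, "_dbn_g")]] <- db$dgamma
    g[[paste0(pre, "_dbn_b")]] <- db$dbeta
    dn <- conv2d_bwd(db$dx, cache$dn, p[[paste0(pre, "_down_W")]],
                     stride = cache$stride, pad = c(0, 0))
    g[[paste0(pre, "_down_W")]] <- dn$dW
    dx <- dx + dn$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = g)
}

resnet_fwd <- function(z, model, training) {
  cfg <- model$config
  p <- model$params
  bn <- model$bn_state
  rs <- cfg$reshape_shape
  n <- nrow(z)
  if (cfg$classifier == "resnet18_2d") {
    x <- array(z, c(n, rs[2], rs[3], rs[1]))
    kern <- c(3, 3); stride1 <- c(2, 2); pad1 <- c(3, 3)
    pool_s <- c(2, 2); pool_p <- c(1, 1); pool_k <- 3
  } else {
    # 1-D reading: 3 channels along a 256-step axis, height fixed at 1
    x <- array(z, c(n, 1, rs[2] * rs[3], rs[1]))
    kern <- c(1, 3); stride1 <- c(1, 2); pad1 <- c(0, 3)
    pool_s <- c(1, 2); pool_p <- c(0, 1); pool_k <- 3
  }
  caches <- list(xdim = dim(x))
  c1 <- conv2d_fwd(x, p$r_conv1_W, numeric(64), stride = stride1, pad = pad1)
  b1 <- bn_fwd(c1$out, p$r_bn1_g, p$r_bn1_b, bn$r_bn1, training)
  bn$r_bn1 <- b1$state
  r1 <- relu_fwd(b1$out)
  if (cfg$classifier == "resnet18_1d") {
    mp <- maxpool1d_as_2d_fwd(r1$out, pool_k, pool_s, pool_p)
  } else {
    mp <- maxpool2d_fwd(r1$out, k = pool_k, stride = pool_s, pad = pool_p)
  }
  caches$c1 <- c1; caches$b1 <- b1; caches$r1 <- r1; caches$mp <- mp
  h <- mp$out
  st <- resnet18_stages()
  blocks <- list()
  for (l in seq_along(st$widths)) {
    for (blk in seq_len(st$blocks)) {
      pre <- sprintf("r_l%db%d", l, blk)
      stride <- if (blk == 1) {
        if (cfg$classifier == "resnet18_2d") c(st$strides[l], st$strides[l])
        else c(1, st$strides[l])
      } else c(1, 1)
      rb <- resblock_fwd(h, p, bn, pre, stride, kern, training)
      bn <- rb$bn
      h <- rb$out
      blocks[[pre]] <- rb$cache
    }
  }
  caches$blocks <- blocks
  gp <- gap_fwd(h)
  fc <- linear_fwd(gp$out, p$r_fc_W, p$r_fc_b)
  caches$gp <- gp; caches$fc <- fc
  list(logits = fc$out, caches = caches, bn_state = bn)
}

# max pool over the length axis only (height is 1 in the 1-D variant)
maxpool1d_as_2d_fwd <- function(x, k, stride, pad) {
  maxpool2d_fwd(x, k = c(1, k), stride = c(1, stride[2]),
                pad = c(0, pad[2]))
}

resnet_bwd <- function(dlogits, caches, model) {
  p <- model$params
  g <- list()
  fcb <- linear_bwd(dlogits, caches$fc, p$r_fc_W)
  g$r_fc_W <- fcb$dW
  g$r_fc_b <- fcb$db
  dh <- gap_bwd(fcb$dx, caches$gp)
  st <- resnet18_stages()
  for (l in rev(seq_along(st$widths))) {
    for (blk in rev(seq_len(st$blocks))) {
      pre <- sprintf("r_l%db%d", l, blk)
      rb <- resblock_bwd(dh, caches$blocks[[pre]], p)
      g <- c(g, rb$grads)
      dh <- rb$dx
    }
  }
  dmp <- maxpool2d_bwd(dh, caches$mp)
  dr1 <- relu_bwd(dmp, caches$r1)
  b1 <- bn_bwd(dr1, caches$b1, p$r_bn1_g)
  g$r_bn1_g <- b1$dgamma
  g$r_bn1_b <- b1$dbeta
  cfg <- model$config
  stride1 <- if (cfg$classifier == "resnet18_2d") c(2, 2) else c(1, 2)
  pad1 <- if (cfg$classifier == "resnet18_2d") c(3, 3) else c(0, 3)
  c1 <- conv2d_bwd(b1$dx, caches$c1, p$r_conv1_W, stride = stride1,
                   pad = pad1)
  g$r_conv1_W <- c1$dW
  dz <- matrix(c1$dx, nrow(dlogits), cfg$projection_dim)
  list(grads = g, dz = dz)
}

#' Classifier head forward pass
#'
#' Projects the pooled TCN summary to 768 dimensions, reshapes to
#' `(3, 16, 16)`, runs the ResNet-18 trunk to class logits F(Y), adds a
#' learned linear shortcut from the 768-vector to class logits (making the
#' residual sum Y + F(Y) dimensionally coherent), and applies log-softmax.
#'
#' @param model A `kinedep_model`.
#' @param y_summary `[N x C]` pooled TCN output from [tcn_forward()].
#' @param training Enable training-mode batch statistics.
#' @return List with `logp` (`[N x n_classes]` log-probabilities), `caches`,
#'   and updated `bn_state`.
#' @export
classifier_forward <- function(model, y_summary, training = FALSE) {
  p <- model$params
  proj <- linear_fwd(y_summary, p$proj_W, p$proj_b)
  rn <- resnet_fwd(proj$out, model, training)
  sc <- linear_fwd(proj$out, p$short_W, p$short_b)
  logits <- sc$out + rn$logits
  logp <- log_softmax(logits)
  list(logp = logp,
       caches = list(proj = proj, rn = rn$caches, sc = sc, logp = logp),
       bn_state = rn$bn_state)
}

classifier_backward <- function(dlogp, caches, model) {
  p <- model$params
  dlogits <- log_softmax_bwd(dlogp, caches$logp)
  scb <- linear_bwd(dlogits, caches$sc, p$short_W)
  rnb <- resnet_bwd(dlogits, caches$rn, model)
  g <- rnb$grads
  g$short_W <- scb$dW
  g$short_b <- scb$db
  dproj <- scb$dx + rnb$dz
  pjb <- linear_bwd(dproj, caches$proj, p$proj_W)
  g$proj_W <- pjb$dW
  g$proj_b <- pjb$db
  list(grads = g, dsummary = pjb$dx)
}

# Full forward pass: returns log-probabilities, caches and updated BN state.
model_forward <- function(model, x, training = FALSE) {
  tc <- tcn_forward(model, x, training)
  cl <- classifier_forward(model, tc$summary, training)
  list(logp = cl$logp,
       caches = list(tcn = tc$caches, cls = cl$caches,
                     ydim = dim(tc$Y)),
       bn_state = cl$bn_state)
}

model_backward <- function(dlogp, caches, model) {
  clb <- classifier_backward(dlogp, caches$cls, model)
  dY <- array(0, caches$ydim)
  tcb <- tcn_backward(dY, clb$dsummary, caches$tcn, model)
  c(clb$grads, tcb$grads)
}

#' Predict class labels for feature tensors
#'
#' Deterministic (evaluation mode: dropout off, batch norm uses running
#' statistics). Ties in the scores resolve to the lowest class index.
#'
#' @param object A `kinedep_model` (or a `kinedep_fit`; the embedded model
#'   is used).
#' @param newdata A [feature_tensor()], a `[T x 175]` matrix, a list of
#'   either, or a `[N x T x 175]` array.
#' @param ... Unused.
#' @return Tibble with `label` (0-based class index), `class_name`, and one
#'   `logp_*` column of log-probability per class.
#' @export
predict.kinedep_model <- function(object, newdata, ...) {
  x <- as_batch_array(newdata, object$config$input_channels)
  out <- model_forward(object, x, training = FALSE)
  scores <- out$logp
  label <- apply(scores, 1, which.max) - 1L # first max: lowest index wins
  class_names <- attr(newdata, "class_names")
  res <- tibble::tibble(label = as.integer(label))
  res$class_name <- if (!is.null(class_names)) class_names[label + 1L]
                    else as.character(label)
  colnames(scores) <- paste0("logp_", seq_len(ncol(scores)) - 1L)
  dplyr::bind_cols(res, tibble::as_tibble(scores))
}

as_batch_array <- function(newdata, width) {
  if (inherits(newdata, "feature_tensor")) newdata <- list(newdata)
  if (is.array(newdata) && length(dim(newdata)) == 3) return(newdata)
  if (is.matrix(newdata)) newdata <- list(newdata)
  mats <- lapply(newdata, function(el) {
    if (inherits(el, "feature_tensor")) el$values else as.matrix(el)
  })
  widths <- vapply(mats, ncol, integer(1))
  if (any(widths != width)) {
    abort(sprintf("feature width %d does not match model input width %d",
                  widths[which(widths != width)[1]], width))
  }
  t_lens <- vapply(mats, nrow, integer(1))
  if (length(unique(t_lens)) != 1) {
    abort("all sequences in a batch must share one length (regularize_length upstream)")
  }
  x <- array(0, unname(c(length(mats), t_lens[1], width)))
  for (i in seq_along(mats)) x[i, , ] <- mats[[i]]
  x
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive of the weights, batch-norm running
#' statistics and the full [model_config()] (including its seed); loading
#' restores bit-identical evaluation outputs.
#'
#' @param model A `kinedep_model`.
#' @param path Destination file.
#' @return `path` ([save_checkpoint()]) or the restored `kinedep_model`.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(params = obj$params, bn_state = obj$bn_state,
                 config = structure(obj$config, class = "model_config")),
            class = "kinedep_model")
}
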