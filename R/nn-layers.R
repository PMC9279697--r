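# Neural-network primitives on base matrix algebra: causal dilated 1-D
# convolution, 2-D convolution, batch normalization, max/average pooling,
# linear layers, log-softmax, and Adam. Each layer has a forward returning
# (out, cache) and a backward mapping dout -> (dx, parameter gradients).
#
# Array layouts: sequences are [N, T, C]; images are [N, H, W, C]
# (channel-last, column-major), so matrix(x, N*T, C) / matrix(x, N*H*W, C)
# flatten without copying semantics surprises.

# ---- 1-D causal dilated convolution ------------------------------------
#
# With the column-major [N, T, C] layout, flattening to a [N*T, C] matrix
# orders rows with time slowest, so a causal shift of s steps is a
# contiguous shift of N*s rows -- the convolution reduces to k block
# matrix products without any array reshuffling.

wslice1d <- function(W, i) matrix(W[i, , , drop = FALSE], dim(W)[2], dim(W)[3])

conv1d_causal_fwd <- function(x, W, b, d) {
  dims <- dim(x)
  n <- dims[1]; t_len <- dims[2]; c_in <- dims[3]
  k <- dim(W)[1]; c_out <- dim(W)[3]
  xmat <- matrix(x, n * t_len, c_in)
  out <- matrix(b, n * t_len, c_out, byrow = TRUE)
  for (i in seq_len(k)) {
    s <- d * (i - 1)
    if (s == 0) {
      out <- out + xmat %*% wslice1d(W, i)
    } else if (s < t_len) {
      rows <- n * s
      out[(rows + 1):(n * t_len), ] <-
        out[(rows + 1):(n * t_len), , drop = FALSE] +
        xmat[1:(n * t_len - rows), , drop = FALSE] %*% wslice1d(W, i)
    }
  }
  list(out = array(out, c(n, t_len, c_out)), xmat = xmat, dims = dims)
}

conv1d_causal_bwd <- function(dout, cache, W, d) {
  dims <- cache$dims
  n <- dims[1]; t_len <- dims[2]; c_in <- dims[3]
  k <- dim(W)[1]; c_out <- dim(W)[3]
  nt <- n * t_len
  dout_mat <- matrix(dout, nt, c_out)
  xmat <- cache$xmat
  dW <- array(0, dim(W))
  dxmat <- matrix(0, nt, c_in)
  for (i in seq_len(k)) {
    s <- d * (i - 1)
    if (s >= t_len) next
    rows <- n * s
    lead <- 1:(nt - rows)
    lag <- (rows + 1):nt
    dW[i, , ] <- crossprod(xmat[lead, , drop = FALSE],
                           dout_mat[lag, , drop = FALSE])
    dxmat[lead, ] <- dxmat[lead, , drop = FALSE] +
      dout_mat[lag, , drop = FALSE] %*% t(wslice1d(W, i))
  }
  list(dx = array(dxmat, dims), dW = dW, db = colSums(dout_mat))
}

#' Dilated causal convolution of a sequence
#'
#' Computes `out[s, ] = b + sum_{i=0}^{k-1} x[s - d*i, ] %*% f[i, , ]` with
#' zero padding on the left, so the output at step s depends only on inputs
#' at steps at or before s and the sequence length is preserved. With
#' `d = 1` this is a standard causal convolution.
#'
#' @param x Numeric matrix `[T x C_in]`, one row per time step.
#' @param filter Numeric array `[k x C_in x C_out]` of filter weights.
#' @param d Dilation (integer >= 1).
#' @param bias Optional length-`C_out` bias (default zeros).
#' @return Numeric matrix `[T x C_out]`.
#' @export
dilated_causal_conv <- function(x, filter, d = 1, bias = NULL) {
  if (d < 1) abort("dilated_causal_conv: dilation d must be >= 1")
  x <- as.matrix(x)
  if (length(dim(filter)) != 3) abort("filter must be [k x C_in x C_out]")
  if (dim(filter)[2] != ncol(x)) {
    abort("filter C_in does not match input channels")
  }
  if (is.null(bias)) bias <- numeric(dim(filter)[3])
  xb <- array(x, c(1, nrow(x), ncol(x)))
  res <- conv1d_causal_fwd(xb, filter, bias, d)$out
  matrix(res, nrow(x), dim(filter)[3])
}

# ---- 2-D convolution ----------------------------------------------------

pad_nhwc <- function(x, ph, pw, fill = 0) {
  if (ph == 0 && pw == 0) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1], d[2] + 2 * ph, d[3] + 2 * pw, d[4]))
  out[, (ph + 1):(ph + d[2]), (pw + 1):(pw + d[3]), ] <- x
  out
}

wslice2d <- function(W, a, b) {
  matrix(W[a, b, , , drop = FALSE], dim(W)[3], dim(W)[4])
}

conv2d_fwd <- function(x, W, b, stride = c(1, 1), pad = c(0, 0)) {
  kd <- dim(W) # [kh, kw, c_in, c_out]
  xp <- pad_nhwc(x, pad[1], pad[2])
  d <- dim(xp)
  n <- d[1]; c_in <- d[4]; c_out <- kd[4]
  ho <- (d[2] - kd[1]) %/% stride[1] + 1
  wo <- (d[3] - kd[2]) %/% stride[2] + 1
  out <- matrix(b, n * ho * wo, c_out, byrow = TRUE)
  for (a in seq_len(kd[1])) {
    rows <- seq(a, by = stride[1], length.out = ho)
    for (bb in seq_len(kd[2])) {
      cols <- seq(bb, by = stride[2], length.out = wo)
      slice <- xp[, rows, cols, , drop = FALSE]
      out <- out + matrix(slice, n * ho * wo, c_in) %*% wslice2d(W, a, bb)
    }
  }
  list(out = array(out, c(n, ho, wo, c_out)),
       xp = xp, xdim = dim(x), ho = ho, wo = wo)
}

conv2d_bwd <- function(dout, cache, W, stride = c(1, 1), pad = c(0, 0)) {
  kd <- dim(W)
  xp <- cache$xp
  d <- dim(xp)
  n <- d[1]; c_in <- d[4]; c_out <- kd[4]
  ho <- cache$ho; wo <- cache$wo
  dout_mat <- matrix(dout, n * ho * wo, c_out)
  dW <- array(0, kd)
  dxp <- array(0, d)
  for (a in seq_len(kd[1])) {
    rows <- seq(a, by = stride[1], length.out = ho)
    for (bb in seq_len(kd[2])) {
      cols <- seq(bb, by = stride[2], length.out = wo)
      slice <- xp[, rows, cols, , drop = FALSE]
      dW[a, bb, , ] <- crossprod(matrix(slice, n * ho * wo, c_in), dout_mat)
      dpatch <- array(dout_mat %*% t(wslice2d(W, a, bb)), c(n, ho, wo, c_in))
      dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] + dpatch
    }
  }
  xd <- cache$xdim
  dx <- dxp[, (pad[1] + 1):(pad[1] + xd[2]),
            (pad[2] + 1):(pad[2] + xd[3]), , drop = FALSE]
  list(dx = dx, dW = dW, db = colSums(dout_mat))
}

# ---- batch normalization ------------------------------------------------

bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  c_n <- d[length(d)]
  m <- prod(d) / c_n
  xm <- matrix(x, m, c_n)
  if (training) {
    mu <- colMeans(xm)
    v <- pmax(colMeans(xm^2) - mu^2, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var +
      momentum * v * m / max(m - 1, 1)
  } else {
    mu <- state$mean
    v <- state$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, ivar, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = array(out, d), xhat = xhat, ivar = ivar, state = state,
       dims = d)
}

bn_bwd <- function(dout, cache, gamma) {
  d <- cache$dims
  c_n <- d[length(d)]
  m <- prod(d) / c_n
  dm <- matrix(dout, m, c_n)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, gamma, "*")
  dx <- sweep(dxhat, 2, colMeans(dxhat), "-") -
    sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(dx, 2, cache$ivar, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling ------------------------------------------------------------

maxpool2d_fwd <- function(x, k = c(3, 3), stride = c(2, 2), pad = c(1, 1)) {
  if (length(k) == 1) k <- c(k, k)
  xp <- pad_nhwc(x, pad[1], pad[2], fill = -Inf)
  d <- dim(xp)
  n <- d[1]; c_n <- d[4]
  ho <- (d[2] - k[1]) %/% stride[1] + 1
  wo <- (d[3] - k[2]) %/% stride[2] + 1
  best <- array(-Inf, c(n, ho, wo, c_n))
  arg <- array(0L, c(n, ho, wo, c_n))
  idx <- 0L
  for (a in seq_len(k[1])) {
    rows <- seq(a, by = stride[1], length.out = ho)
    for (bb in seq_len(k[2])) {
      cols <- seq(bb, by = stride[2], length.out = wo)
      idx <- idx + 1L
      slice <- xp[, rows, cols, , drop = FALSE]
      upd <- slice > best
      upd[is.na(upd)] <- FALSE
      upd <- upd | (is.na(slice) & !is.na(best)) # propagate NaN inputs
      best[upd] <- slice[upd]
      arg[upd] <- idx
    }
  }
  list(out = best, arg = arg, xdim = dim(x), k = k, stride = stride,
       pad = pad, pdim = d)
}

maxpool2d_bwd <- function(dout, cache) {
  k <- cache$k
  if (length(k) == 1) k <- c(k, k)
  stride <- cache$stride; pad <- cache$pad
  dxp <- array(0, cache$pdim)
  d <- dim(dout)
  ho <- d[2]; wo <- d[3]
  idx <- 0L
  for (a in seq_len(k[1])) {
    rows <- seq(a, by = stride[1], length.out = ho)
    for (bb in seq_len(k[2])) {
      cols <- seq(bb, by = stride[2], length.out = wo)
      idx <- idx + 1L
      contrib <- dout * (cache$arg == idx)
      dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] + contrib
    }
  }
  xd <- cache$xdim
  dxp[, (pad[1] + 1):(pad[1] + xd[2]),
      (pad[2] + 1):(pad[2] + xd[3]), , drop = FALSE]
}

gap_fwd <- function(x) { # global average pool [N,H,W,C] -> [N,C]
  d <- dim(x)
  n <- d[1]; hw <- d[2] * d[3]; c_n <- d[4]
  m <- matrix(x, n, hw * c_n)
  out <- vapply(seq_len(c_n), function(ch) {
    rowMeans(m[, ((ch - 1) * hw + 1):(ch * hw), drop = FALSE])
  }, numeric(n))
  list(out = matrix(out, n, c_n), xdim = d)
}

gap_bwd <- function(dout, cache) {
  d <- cache$xdim
  n <- d[1]; hw <- d[2] * d[3]; c_n <- d[4]
  dxm <- matrix(0, n, hw * c_n)
  for (ch in seq_len(c_n)) {
    dxm[, ((ch - 1) * hw + 1):(ch * hw)] <- dout[, ch] / hw
  }
  array(dxm, d)
}

# ---- elementwise, linear, output ---------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), pos = x > 0)
relu_bwd <- function(dout, cache) dout * cache$pos

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- array((runif(length(x)) >= p) / (1 - p), dim(x))
  list(out = x * mask, mask = mask)
}
dropout_bwd <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

linear_fwd <- function(x, W, b) {
  list(out = sweep(x %*% W, 2, b, "+"), x = x)
}
linear_bwd <- function(dout, cache, W) {
  list(dx = dout %*% t(W), dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

log_softmax <- function(x) {
  mx <- apply(x, 1, max)
  x - (mx + log(rowSums(exp(x - mx))))
}
log_softmax_bwd <- function(dout, logp) {
  dout - exp(logp) * rowSums(dout)
}

# Weighted negative log-likelihood on log-probabilities.
nll_loss <- function(logp, labels, weights = NULL) {
  n <- nrow(logp)
  idx <- cbind(seq_len(n), labels + 1L)
  if (is.null(weights)) weights <- rep(1, n)
  wsum <- sum(weights)
  loss <- -sum(weights * logp[idx]) / wsum
  dlogp <- matrix(0, n, ncol(logp))
  dlogp[idx] <- -weights / wsum
  list(loss = loss, dlogp = dlogp)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
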