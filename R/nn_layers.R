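# Internal layer primitives for the dual-branch 3D U-Net. Tensors are R
# arrays of dim (X, Y, Z, C); the heavy lifting (convolutions, pooling,
# upsampling) lives in compiled code.

conv_fwd <- function(x, W, b, k) {
  d <- dim(x)
  y <- .cpp_conv3d_fwd(as.numeric(x), as.integer(d), W, b, as.integer(k))
  array(y, c(d[1:3], nrow(W)))
}

conv_bwd <- function(x, W, dy, k) {
  d <- dim(x)
  g <- .cpp_conv3d_bwd(as.numeric(x), as.integer(d), W, as.numeric(dy),
                       as.integer(k))
  g$dx <- array(g$dx, d)
  g
}

# Per-channel normalization over the spatial dims of one patch (batch norm
# with a batch of one volume). Inference uses the same per-patch moments as
# training, so the normalization behaviour is identical in both modes;
# running moments are still tracked for diagnostics.
bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  nsp <- prod(d[1:3])
  xm <- matrix(x, nsp, d[4])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  if (training) {
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * v
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xm
  y <- xm
  for (j in seq_len(d[4])) {           # column ops avoid sweep/aperm copies
    xhat[, j] <- (xm[, j] - mu[j]) * inv[j]
    y[, j] <- xhat[, j] * gamma[j] + beta[j]
  }
  list(y = array(y, d), cache = list(xhat = xhat, inv = inv, d = d),
       state = state)
}

bn_bwd <- function(dy, gamma, cache) {
  d <- cache$d
  nsp <- prod(d[1:3])
  dym <- matrix(dy, nsp, d[4])
  dgamma <- numeric(d[4])
  dbeta <- numeric(d[4])
  dx <- dym
  # standard batch-norm gradient through the per-channel moments
  for (j in seq_len(d[4])) {
    xh <- cache$xhat[, j]
    dyj <- dym[, j]
    dgamma[j] <- sum(dyj * xh)
    dbeta[j] <- sum(dyj)
    dxh <- dyj * gamma[j]
    dx[, j] <- cache$inv[j] * (dxh - mean(dxh) - xh * mean(dxh * xh))
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(dy, x) {
  dy[x <= 0] <- 0
  dy
}

pool_fwd <- function(x) {
  d <- dim(x)
  r <- .cpp_maxpool2_fwd(as.numeric(x), as.integer(d))
  list(y = array(r$y, c(d[1:3] %/% 2L, d[4])), idx = r$idx, n_in = length(x))
}

pool_bwd <- function(dy, cache, in_dim) {
  array(.cpp_maxpool2_bwd(as.numeric(dy), cache$idx, cache$n_in), in_dim)
}

upsample_fwd <- function(x) {
  d <- dim(x)
  array(.cpp_upsample2_fwd(as.numeric(x), as.integer(d)),
        c(d[1:3] * 2L, d[4]))
}

upsample_bwd <- function(dy) {
  d <- dim(dy)
  array(.cpp_upsample2_bwd(as.numeric(dy), as.integer(d)),
        c(d[1:3] %/% 2L, d[4]))
}

softmax4 <- function(z) {
  d <- dim(z)
  zm <- matrix(z, prod(d[1:3]), d[4])
  rowmax <- do.call(pmax, lapply(seq_len(d[4]), function(j) zm[, j]))
  e <- exp(zm - rowmax)
  array(e / rowSums(e), d)
}

he_init <- function(cout, cin, k, rnorm_fn = rnorm) {
  fan_in <- cin * k^3
  matrix(rnorm_fn(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in)
}
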