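# Differentiable layer primitives.  Every layer comes as a forward returning
# list(y, cache) and a backward taking (dy, params, cache) returning
# list(dx, g = <grads in the same shape as the params>).

.conv_f <- function(x, p, stride = 1L, pad = 0L) {
  y <- conv2d_fwd_cpp(x, p$w, p$b, as.integer(stride), as.integer(pad))
  list(y = y, cache = list(x = x, stride = stride, pad = pad))
}

.conv_b <- function(dy, p, cache) {
  r <- conv2d_bwd_cpp(cache$x, p$w, dy,
                      as.integer(cache$stride), as.integer(cache$pad))
  list(dx = r$dx, g = list(w = r$dw, b = r$db))
}

# Batch normalization over (H, W, N) per channel.  `state` is an environment
# holding running moments under keys "<key>.rm" / "<key>.rv".
.bn_f <- function(x, p, state, key, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- .ch_sum(x) / m
    xc <- x - .bc_ch(mu, d[1], d[2])
    v <- .ch_sum(xc * xc) / m
    state[[paste0(key, ".rm")]] <-
      (1 - momentum) * state[[paste0(key, ".rm")]] + momentum * mu
    state[[paste0(key, ".rv")]] <-
      (1 - momentum) * state[[paste0(key, ".rv")]] + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- state[[paste0(key, ".rm")]]
    v <- state[[paste0(key, ".rv")]]
    xc <- x - .bc_ch(mu, d[1], d[2])
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * .bc_ch(istd, d[1], d[2])
  y <- xhat * .bc_ch(p$gamma, d[1], d[2]) + .bc_ch(p$beta, d[1], d[2])
  list(y = y, cache = list(xhat = xhat, istd = istd, training = training))
}

.bn_b <- function(dy, p, cache) {
  d <- dim(dy)
  m <- d[1] * d[2] * d[4]
  xhat <- cache$xhat
  dgamma <- .ch_sum(dy * xhat)
  dbeta <- .ch_sum(dy)
  gi <- .bc_ch(p$gamma * cache$istd, d[1], d[2])
  if (cache$training) {
    dx <- gi * (dy - .bc_ch(dbeta / m, d[1], d[2]) -
                  xhat * .bc_ch(dgamma / m, d[1], d[2]))
  } else {
    dx <- gi * dy
  }
  list(dx = dx, g = list(gamma = dgamma, beta = dbeta))
}

.relu_f <- function(x) list(y = pmax(x, 0), cache = x > 0)
.relu_b <- function(dy, cache) dy * cache

# Layer normalization over the feature axis of (M, D, B) token tensors.
.ln_f <- function(x, p, eps = 1e-5) {
  d <- dim(x)
  mu <- colSums(aperm(x, c(2, 1, 3))) / d[2]            # (M, B)
  mu_e <- aperm(array(mu, c(d[1], d[3], d[2])), c(1, 3, 2))
  xc <- x - mu_e
  v <- colSums(aperm(xc * xc, c(2, 1, 3))) / d[2]
  istd <- 1 / sqrt(v + eps)
  istd_e <- aperm(array(istd, c(d[1], d[3], d[2])), c(1, 3, 2))
  xhat <- xc * istd_e
  g_e <- rep(p$g, each = d[1])
  y <- xhat * g_e + rep(p$b, each = d[1])
  list(y = y, cache = list(xhat = xhat, istd_e = istd_e, g_e = g_e))
}

.ln_b <- function(dy, p, cache) {
  d <- dim(dy)
  xhat <- cache$xhat
  dg <- rowSums(colSums(dy * xhat))                     # over (M, B), per D
  db <- rowSums(colSums(dy))
  dxhat <- dy * cache$g_e
  m1 <- colSums(aperm(dxhat, c(2, 1, 3))) / d[2]
  m2 <- colSums(aperm(dxhat * xhat, c(2, 1, 3))) / d[2]
  m1_e <- aperm(array(m1, c(d[1], d[3], d[2])), c(1, 3, 2))
  m2_e <- aperm(array(m2, c(d[1], d[3], d[2])), c(1, 3, 2))
  dx <- cache$istd_e * (dxhat - m1_e - xhat * m2_e)
  list(dx = dx, g = list(g = dg, b = db))
}

# Token-wise linear map: (M, D, B) %*% W (D, Dout) + b, per batch element.
.tlin_f <- function(x, p) {
  d <- dim(x)
  dout <- ncol(p$w)
  y <- array(0, c(d[1], dout, d[3]))
  for (b in seq_len(d[3])) y[, , b] <- x[, , b] %*% p$w
  if (!is.null(p$b)) y <- y + rep(p$b, each = d[1])
  list(y = y, cache = x)
}

.tlin_b <- function(dy, p, cache) {
  d <- dim(cache)
  dx <- array(0, d)
  dw <- matrix(0, nrow(p$w), ncol(p$w))
  for (b in seq_len(d[3])) {
    dx[, , b] <- dy[, , b] %*% t(p$w)
    dw <- dw + crossprod(cache[, , b], dy[, , b])
  }
  g <- list(w = dw)
  if (!is.null(p$b)) g$b <- rowSums(colSums(dy))
  list(dx = dx, g = g)
}

# Causal depthwise 1-D convolution along the token axis of (M, E, B):
# y[t] = sum_j w[j] * x[t - k + j] + bias, zero history padding.
.shift_tok <- function(x, s) {
  if (s == 0L) return(x)
  d <- dim(x)
  y <- array(0, d)
  if (s < d[1]) y[(s + 1L):d[1], , ] <- x[seq_len(d[1] - s), , , drop = FALSE]
  y
}

.dwconv_f <- function(x, p) {
  k <- nrow(p$w)
  d <- dim(x)
  y <- array(rep(p$b, each = d[1]), d)
  for (j in seq_len(k)) {
    y <- y + .shift_tok(x, k - j) * rep(p$w[j, ], each = d[1])
  }
  list(y = y, cache = x)
}

.dwconv_b <- function(dy, p, cache) {
  k <- nrow(p$w)
  d <- dim(dy)
  dx <- array(0, d)
  dw <- matrix(0, k, ncol(p$w))
  for (j in seq_len(k)) {
    s <- k - j
    xs <- .shift_tok(cache, s)
    dw[j, ] <- rowSums(colSums(xs * dy))
    # adjoint of shift-down by s is shift-up by s
    dyj <- dy * rep(p$w[j, ], each = d[1])
    if (s == 0L) {
      dx <- dx + dyj
    } else if (s < d[1]) {
      dx[seq_len(d[1] - s), , ] <- dx[seq_len(d[1] - s), , , drop = FALSE] +
        dyj[(s + 1L):d[1], , , drop = FALSE]
    }
  }
  list(dx = dx, g = list(w = dw, b = rowSums(colSums(dy))))
}

# Bilinear resize with cached separable weight matrices (half-pixel centers).
.resize_f <- function(x, Ho, Wo) {
  d <- dim(x)
  Ah <- .interp_matrix(Ho, d[1])
  Aw <- .interp_matrix(Wo, d[2])
  list(y = .resize_apply(x, Ah, Aw), cache = list(Ah = Ah, Aw = Aw))
}

.resize_b <- function(dy, cache) .resize_apply(dy, t(cache$Ah), t(cache$Aw))
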