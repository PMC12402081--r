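#' Token sequence container
#'
#' A `(M, D, B)` numeric array of token features together with the patch
#' grid `(rows, cols)` it was flattened from (row-major token order).
#'
#' @param values numeric array `(M, D, B)` (a `(M, D)` matrix is promoted).
#' @param grid integer vector `(rows, cols)` with `rows * cols == M`.
#' @return object of class `token_sequence`.
#' @export
token_sequence <- function(values, grid) {
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (prod(grid[1:2]) != dim(values)[1]) {
    stop("grid (", grid[1], "x", grid[2], ") does not match ",
         dim(values)[1], " tokens")
  }
  structure(list(values = values, grid = as.integer(grid[1:2])),
            class = "token_sequence")
}

#' Zero-order-hold discretization of a diagonal state-space model
#'
#' Converts continuous per-token parameters to the discrete recurrence
#' coefficients: `abar = exp(delta * A)` elementwise (exact for a diagonal
#' transition), and the simplified Euler input `bbar = delta * B`.
#'
#' @param A diagonal transition entries (continuous time; decaying states
#'   have `A <= 0`).
#' @param B input projection, same shape as `A` or recyclable against it.
#' @param delta positive step sizes.
#' @return list with elements `abar` and `bbar`.
#' @export
discretize_ssm <- function(A, B, delta) {
  if (any(delta <= 0)) stop("delta must be positive")
  list(abar = exp(delta * A), bbar = delta * B)
}

#' Reference selective-scan recurrence (explicit loop)
#'
#' Runs the left-to-right linear recurrence
#' `h_t = abar_t * h_{t-1} + bbar_t * x_t`, `y_t = sum(C_t * h_t)` with the
#' state initialized to zero.  This is the plain-loop reference that any
#' accelerated implementation must reproduce.
#'
#' @param x numeric vector of scalar inputs, length `M` (one channel slice).
#' @param abar,bbar,Cm `(M, N)` matrices (vectors are treated as `N = 1`).
#' @return numeric vector `y` of length `M`; empty input gives empty output.
#' @export
selective_scan <- function(x, abar, bbar, Cm) {
  M <- length(x)
  if (M == 0L) return(numeric(0))
  if (is.null(dim(abar))) abar <- matrix(abar, M, 1)
  if (is.null(dim(bbar))) bbar <- matrix(bbar, M, 1)
  if (is.null(dim(Cm))) Cm <- matrix(Cm, M, 1)
  h <- numeric(ncol(abar))
  y <- numeric(M)
  for (t in seq_len(M)) {
    h <- abar[t, ] * h + bbar[t, ] * x[t]
    y[t] <- sum(Cm[t, ] * h)
  }
  y
}

#' Vision-Mamba block hyperparameters
#'
#' @param patch_size spatial patch edge for [patch_embed()].
#' @param embed_dim token feature dimension `D`.
#' @param state_dim SSM state size `N` per channel.
#' @param conv_kernel width of the causal depthwise 1-D convolution.
#' @param expand expansion ratio of the inner channel count (`E = expand*D`).
#' @param bidirectional run a token-reversed scan with its own parameters
#'   and average the two directions.
#' @return list of class `vim_config`.
#' @export
vim_config <- function(patch_size = 4L, embed_dim = 64L, state_dim = 16L,
                       conv_kernel = 4L, expand = 2L, bidirectional = TRUE) {
  stopifnot(patch_size >= 1, embed_dim >= 1, state_dim >= 1,
            conv_kernel >= 1, expand >= 1)
  structure(list(patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 state_dim = as.integer(state_dim),
                 conv_kernel = as.integer(conv_kernel),
                 expand = as.integer(expand),
                 bidirectional = isTRUE(bidirectional)),
            class = "vim_config")
}

#' Patch embedding with learned projection and position embedding
#'
#' Splits the image into non-overlapping `patch_size` squares (row-major
#' grid order), flattens each patch, applies the linear projection `W`, and
#' adds the position embedding: `X_0 = [x^1 W; ...; x^M W] + E_pos`.
#'
#' @param image feature map `(H, W)`, `(H, W, C)` or `(H, W, C, N)`; spatial
#'   dims must be divisible by `patch_size`.
#' @param W projection matrix `(patch_size^2 * C, D)`.
#' @param E_pos position embedding `(M, D)` or `NULL` for none.
#' @param patch_size patch edge length.
#' @return a [token_sequence()] with `M = (H/patch)*(W/patch)` tokens.
#' @export
patch_embed <- function(image, W, E_pos = NULL, patch_size = 4L) {
  x <- .as4d(image, "image")
  d <- dim(x)
  ps <- as.integer(patch_size)
  if (d[1] %% ps != 0L || d[2] %% ps != 0L) {
    stop("spatial dims (", d[1], "x", d[2], ") not divisible by patch size ", ps)
  }
  rows <- d[1] %/% ps; cols <- d[2] %/% ps
  M <- rows * cols
  if (nrow(W) != ps * ps * d[3]) {
    stop("projection expects ", nrow(W), " inputs but patches have ",
         ps * ps * d[3])
  }
  out <- array(0, c(M, ncol(W), d[4]))
  for (b in seq_len(d[4])) {
    pm <- matrix(0, M, ps * ps * d[3])
    m <- 1L
    for (r in seq_len(rows)) {
      for (cc in seq_len(cols)) {
        blk <- x[((r - 1L) * ps + 1L):(r * ps),
                 ((cc - 1L) * ps + 1L):(cc * ps), , b, drop = FALSE]
        pm[m, ] <- as.vector(blk)
        m <- m + 1L
      }
    }
    tk <- pm %*% W
    if (!is.null(E_pos)) tk <- tk + E_pos
    out[, , b] <- tk
  }
  token_sequence(out, c(rows, cols))
}

# --- ViM block parameters + forward/backward --------------------------------

.vim_dir_init <- function(E, N, R, k) {
  dt0 <- exp(runif(E, log(0.001), log(0.1)))
  list(
    conv = list(w = matrix(rnorm(k * E, sd = sqrt(1 / k)), k, E),
                b = numeric(E)),
    xproj = list(w = matrix(rnorm(E * (R + 2 * N), sd = sqrt(1 / E)),
                            E, R + 2 * N)),
    dtproj = list(w = matrix(rnorm(R * E, sd = 1 / sqrt(R)), R, E),
                  b = log(expm1(dt0))),
    Alog = matrix(rep(log(seq_len(N)), each = E), E, N),
    Dskip = rep(1, E)
  )
}

#' Initialize the parameters of one ViM block
#'
#' @param cfg a [vim_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return nested parameter list (layer norm, input/output projections, and
#'   per-direction depthwise convolution + SSM parameters).
#' @export
vim_init <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- cfg$embed_dim; E <- cfg$expand * D; N <- cfg$state_dim
  R <- max(1L, as.integer(ceiling(D / 16)))
  p <- list(
    ln = list(g = rep(1, D), b = numeric(D)),
    win = list(w = matrix(rnorm(D * 2 * E, sd = sqrt(2 / (D + 2 * E))),
                          D, 2 * E)),
    fwd = .vim_dir_init(E, N, R, cfg$conv_kernel),
    wout = list(w = matrix(rnorm(E * D, sd = sqrt(1 / E)), E, D))
  )
  if (cfg$bidirectional) p$bwd <- .vim_dir_init(E, N, R, cfg$conv_kernel)
  p
}

.rev_tok <- function(x) x[dim(x)[1]:1, , , drop = FALSE]

.vim_dir_f <- function(xa, dp, R, N) {
  cv <- .dwconv_f(xa, dp$conv)
  u <- .silu(cv$y)
  pr <- .tlin_f(u, dp$xproj)
  dtr <- pr$y[, seq_len(R), , drop = FALSE]
  Bc <- pr$y[, R + seq_len(N), , drop = FALSE]
  Cc <- pr$y[, R + N + seq_len(N), , drop = FALSE]
  dtz <- .tlin_f(dtr, dp$dtproj)
  dt <- .softplus(dtz$y)
  A <- -exp(dp$Alog)
  sc <- scan_fwd_cpp(u, dt, A, Bc, Cc, dp$Dskip, TRUE)
  list(y = sc$y,
       cache = list(cv = cv, u = u, pr = pr, dtr = dtr, Bc = Bc, Cc = Cc,
                    dtz = dtz, dt = dt, A = A, h = sc$h, abar = sc$abar,
                    R = R, N = N))
}

.vim_dir_b <- function(dy, dp, cache) {
  sb <- scan_bwd_cpp(cache$u, cache$dt, cache$A, cache$Bc, cache$Cc,
                     dp$Dskip, cache$h, cache$abar, dy)
  dAlog <- sb$dA * cache$A                       # A = -exp(Alog)
  ddtz <- sb$ddt * .sigmoid(cache$dtz$y)
  tb <- .tlin_b(ddtz, dp$dtproj, cache$dtz$cache)
  dpr <- array(0, dim(cache$pr$y))
  R <- cache$R; N <- cache$N
  dpr[, seq_len(R), ] <- tb$dx
  dpr[, R + seq_len(N), ] <- sb$dBc
  dpr[, R + N + seq_len(N), ] <- sb$dCc
  xb <- .tlin_b(dpr, dp$xproj, cache$pr$cache)
  du <- sb$du + xb$dx
  dcv <- du * .dsilu(cache$cv$y)
  cb <- .dwconv_b(dcv, dp$conv, cache$cv$cache)
  list(dx = cb$dx,
       g = list(conv = cb$g, xproj = xb$g,
                dtproj = tb$g, Alog = dAlog, Dskip = sb$dD))
}

.vim_f <- function(x, p, cfg) {
  D <- cfg$embed_dim; E <- cfg$expand * D; N <- cfg$state_dim
  R <- max(1L, as.integer(ceiling(D / 16)))
  ln <- .ln_f(x, p$ln)
  xz <- .tlin_f(ln$y, p$win)
  xa <- xz$y[, seq_len(E), , drop = FALSE]
  z <- xz$y[, E + seq_len(E), , drop = FALSE]
  f <- .vim_dir_f(xa, p$fwd, R, N)
  if (cfg$bidirectional) {
    b <- .vim_dir_f(.rev_tok(xa), p$bwd, R, N)
    ysum <- (f$y + .rev_tok(b$y)) / 2
  } else {
    b <- NULL
    ysum <- f$y
  }
  sz <- .silu(z)
  yg <- ysum * sz
  out <- .tlin_f(yg, p$wout)
  list(y = x + out$y,
       cache = list(ln = ln, xz = xz, z = z, f = f, b = b, ysum = ysum,
                    sz = sz, out = out, E = E))
}

.vim_b <- function(dy, p, cfg, cache) {
  E <- cache$E
  ob <- .tlin_b(dy, p$wout, cache$out$cache)
  dysum <- ob$dx * cache$sz
  dsz <- ob$dx * cache$ysum
  dz <- dsz * .dsilu(cache$z)
  g <- list(wout = ob$g)
  if (cfg$bidirectional) {
    fb <- .vim_dir_b(dysum / 2, p$fwd, cache$f$cache)
    bb <- .vim_dir_b(.rev_tok(dysum / 2), p$bwd, cache$b$cache)
    dxa <- fb$dx + .rev_tok(bb$dx)
    g$fwd <- fb$g; g$bwd <- bb$g
  } else {
    fb <- .vim_dir_b(dysum, p$fwd, cache$f$cache)
    dxa <- fb$dx
    g$fwd <- fb$g
  }
  dxz <- array(0, dim(cache$xz$y))
  dxz[, seq_len(E), ] <- dxa
  dxz[, E + seq_len(E), ] <- dz
  wb <- .tlin_b(dxz, p$win, cache$xz$cache)
  g$win <- wb$g
  lb <- .ln_b(wb$dx, p$ln, cache$ln$cache)
  g$ln <- lb$g
  list(dx = dy + lb$dx, g = g)
}

#' Bidirectional ViM token mixer
#'
#' Pre-normalizes the tokens, expands them, applies a causal depthwise
#' convolution with SiLU, runs selective scans forward and (token-reversed)
#' backward with separate parameters, modulates by the learned SiLU gate
#' branch, averages the directions, projects back to `D`, and adds the
#' residual: `X_vim = Vim(X_pe) + X_pe`.
#'
#' @param tokens a [token_sequence()] or `(M, D, B)` array.
#' @param params parameters from [vim_init()].
#' @param cfg a [vim_config()].
#' @return same type as `tokens`, same shape.
#' @export
vim_block <- function(tokens, params, cfg) {
  is_ts <- inherits(tokens, "token_sequence")
  x <- if (is_ts) tokens$values else tokens
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[2] != cfg$embed_dim) {
    stop("token dim ", dim(x)[2], " does not match embed_dim ", cfg$embed_dim)
  }
  y <- .vim_f(x, params, cfg)$y
  if (is_ts) token_sequence(y, tokens$grid) else y
}
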