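#' Single-level orthonormal Haar analysis of a feature map
#'
#' Decomposes a feature map into the four half-resolution subbands of a
#' single-level 2-D discrete wavelet transform with orthonormal Haar filters.
#' `lh` is the band approximating the horizontal derivative (high-pass along
#' width), `hl` approximates the vertical derivative (high-pass along
#' height), and `hh` carries the diagonal detail.  The transform is applied
#' independently per channel and batch element.
#'
#' The orthonormal normalization makes the analysis matrix orthogonal, so
#' [idwt2()] is both the inverse and the adjoint; a constant image of value
#' `c` has `ll` identically `2c` and zero detail bands.
#'
#' @param u numeric array with spatial dims first: `(H, W)`, `(H, W, C)` or
#'   `(H, W, C, N)`.  Both spatial dims must be even.
#' @return object of class `wavelet_subbands`: list with elements `ll`,
#'   `lh`, `hl`, `hh`, each of spatial size `(H/2, W/2)`, plus the original
#'   dimensionality so [idwt2()] can restore it.
#' @seealso [idwt2()], [pmd_step()]
#' @export
dwt2 <- function(u) {
  orig <- dim(u)
  if (is.null(orig)) stop("input must be a matrix or array")
  x <- .as4d(u)
  d <- dim(x)
  if (d[1] %% 2L != 0L) stop("subband analysis needs an even height, got ", d[1])
  if (d[2] %% 2L != 0L) stop("subband analysis needs an even width, got ", d[2])
  .check_finite(x)
  oi <- seq(1L, d[1], by = 2L); oj <- seq(1L, d[2], by = 2L)
  a <- x[oi, oj, , , drop = FALSE]       # top-left of each 2x2 block
  b <- x[oi, oj + 1L, , , drop = FALSE]  # top-right
  cc <- x[oi + 1L, oj, , , drop = FALSE] # bottom-left
  dd <- x[oi + 1L, oj + 1L, , , drop = FALSE]
  out <- list(
    ll = (a + b + cc + dd) / 2,
    lh = (a - b + cc - dd) / 2,
    hl = (a + b - cc - dd) / 2,
    hh = (a - b - cc + dd) / 2,
    orig_dim = orig
  )
  class(out) <- "wavelet_subbands"
  out
}

#' Synthesis (inverse) of [dwt2()]
#'
#' Exact inverse of the orthonormal Haar analysis, up to floating point.
#'
#' @param s `wavelet_subbands` object, or a list with numeric arrays `ll`,
#'   `lh`, `hl`, `hh` of identical shape.
#' @return feature map of twice the subband spatial size, with the
#'   dimensionality of the array originally passed to [dwt2()] when known.
#' @export
idwt2 <- function(s) {
  bands <- lapply(s[c("ll", "lh", "hl", "hh")], .as4d, what = "subband")
  d <- dim(bands$ll)
  for (nm in c("lh", "hl", "hh")) {
    if (!identical(dim(bands[[nm]]), d)) {
      stop("subband ", nm, " shape differs from ll")
    }
  }
  u <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  oi <- seq(1L, 2L * d[1], by = 2L); oj <- seq(1L, 2L * d[2], by = 2L)
  ll <- bands$ll; lh <- bands$lh; hl <- bands$hl; hh <- bands$hh
  u[oi, oj, , ] <- (ll + lh + hl + hh) / 2
  u[oi, oj + 1L, , ] <- (ll - lh + hl - hh) / 2
  u[oi + 1L, oj, , ] <- (ll + lh - hl - hh) / 2
  u[oi + 1L, oj + 1L, , ] <- (ll - lh - hl + hh) / 2
  if (!is.null(s$orig_dim)) u <- .restore_dim(u, s$orig_dim)
  u
}

#' Perona-Malik diffusion coefficient
#'
#' `g(m) = 1 / (1 + (m/k)^2)` — large (near 1) in flat regions where the
#' gradient magnitude `m` is small, so diffusion smooths noise there, and
#' near 0 at strong edges, which are therefore preserved.
#'
#' @param grad_mag nonnegative numeric array of gradient magnitudes.
#' @param k positive contrast constant controlling the degree of diffusion
#'   (default 1).
#' @return array of the same shape with values in `(0, 1]`.
#' @export
diffusion_coefficient <- function(grad_mag, k = 1) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("k must be a positive scalar")
  }
  if (any(grad_mag < 0)) stop("grad_mag must be nonnegative")
  1 / (1 + (grad_mag / k)^2)
}

#' Configuration of the DWT-based diffusion update
#'
#' @param k positive contrast constant of the diffusion coefficient.
#' @param n_steps diffusion iterations per block.
#' @param dt diffusion step size; the discrete scheme fixes it to 1.
#' @param mode `"dwt_pmd"` for the wavelet diffusion update, `"sobel_edge"`
#'   for a Sobel-magnitude edge-enhancement branch (ablation), `"off"` for
#'   identity pass-through (ablation).
#' @param update_sign `"additive"` applies the correction with a plus sign
#'   (the printed discrete form); `"subtractive"` negates it, giving an
#'   averaging/diffusive variant.
#' @return list of class `pmd_config`.
#' @export
pmd_config <- function(k = 1, n_steps = 1L, dt = 1,
                       mode = c("dwt_pmd", "sobel_edge", "off"),
                       update_sign = c("additive", "subtractive")) {
  mode <- match.arg(mode)
  update_sign <- match.arg(update_sign)
  if (k <= 0) stop("k must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (dt != 1) stop("the discrete DWT diffusion update fixes dt = 1")
  structure(list(k = k, n_steps = as.integer(n_steps), dt = dt,
                 mode = mode, update_sign = update_sign),
            class = "pmd_config")
}

#' One discrete DWT-domain Perona-Malik diffusion update
#'
#' Computes the Haar subbands of `u`, forms the gradient-magnitude proxy
#' `m = sqrt(lh^2 + hl^2)`, scales the two derivative bands by the diffusion
#' coefficient `g(m, k)`, synthesizes the scaled detail (with `ll` and `hh`
#' slots zeroed) back to full resolution, and adds it to `u` (or subtracts,
#' per `update_sign`).  Constant inputs are exact fixed points: their detail
#' bands vanish, so the correction is identically zero.
#'
#' @param u feature map array, even spatial dims.
#' @param cfg a [pmd_config()] with `mode = "dwt_pmd"`.
#' @return array of the same shape as `u`.
#' @export
pmd_step <- function(u, cfg = pmd_config()) {
  if (cfg$mode != "dwt_pmd") stop("pmd_step requires mode = 'dwt_pmd'")
  orig <- dim(u)
  x <- .as4d(u)
  .check_finite(x)
  s <- dwt2(x)
  g <- diffusion_coefficient(sqrt(s$lh^2 + s$hl^2), cfg$k)
  zero <- array(0, dim(s$ll))
  synth <- idwt2(list(ll = zero, lh = g * s$lh, hl = g * s$hl, hh = zero))
  out <- if (cfg$update_sign == "additive") x + synth else x - synth
  .restore_dim(out, orig)
}

# forward with cache, for backprop through the diffusion branch; odd spatial
# dims (e.g. a 3x3 deepest map from a 96px input) are replicate-padded to
# even size and cropped back after synthesis
.pmd_step_f <- function(x, k, sign) {
  d0 <- dim(x)
  padded <- c(d0[1] %% 2L == 1L, d0[2] %% 2L == 1L)
  if (padded[1]) x <- x[c(seq_len(d0[1]), d0[1]), , , , drop = FALSE]
  if (padded[2]) x <- x[, c(seq_len(d0[2]), d0[2]), , , drop = FALSE]
  s <- dwt2(x)
  m2 <- s$lh^2 + s$hl^2
  g <- 1 / (1 + m2 / k^2)
  zero <- array(0, dim(s$ll))
  synth <- idwt2(list(ll = zero, lh = g * s$lh, hl = g * s$hl, hh = zero))
  y <- x + sign * synth
  if (padded[1]) y <- y[seq_len(d0[1]), , , , drop = FALSE]
  if (padded[2]) y <- y[, seq_len(d0[2]), , , drop = FALSE]
  list(y = y, cache = list(lh = s$lh, hl = s$hl, g = g,
                           k = k, sign = sign, d0 = d0, padded = padded))
}

# adjoint: dwt2 and idwt2 are mutual adjoints (orthonormal filters), and the
# band scaling a = g(m) p, b = g(m) q has the 2x2 pointwise Jacobian below.
.pmd_step_b <- function(dy, cache) {
  d0 <- cache$d0; padded <- cache$padded
  if (any(padded)) {
    # crop adjoint: embed into the padded size with a zero row/col
    dyp <- array(0, c(d0[1] + padded[1], d0[2] + padded[2], d0[3], d0[4]))
    dyp[seq_len(d0[1]), seq_len(d0[2]), , ] <- dy
    dy <- dyp
  }
  db <- dwt2(dy)
  p <- cache$lh; q <- cache$hl; g <- cache$g; k <- cache$k
  common <- (2 * g^2 / k^2) * (p * db$lh + q * db$hl)
  dp <- g * db$lh - p * common
  dq <- g * db$hl - q * common
  zero <- array(0, dim(dp))
  dx <- dy + cache$sign * idwt2(list(ll = zero, lh = dp, hl = dq, hh = zero))
  if (padded[1]) {
    dx[d0[1], , , ] <- dx[d0[1], , , ] + dx[d0[1] + 1L, , , ]
    dx <- dx[seq_len(d0[1]), , , , drop = FALSE]
  }
  if (padded[2]) {
    dx[, d0[2], , ] <- dx[, d0[2], , ] + dx[, d0[2] + 1L, , ]
    dx <- dx[, seq_len(d0[2]), , , drop = FALSE]
  }
  dx
}

# --- Sobel edge-enhancement branch (ablation) -------------------------------

# replicate-boundary index shift along an axis; adjoint handled by .shift_adj
.shift_idx <- function(n, by) pmin(pmax(seq_len(n) + by, 1L), n)

.shift_h <- function(x, by) x[.shift_idx(dim(x)[1], by), , , , drop = FALSE]
.shift_w <- function(x, by) x[, .shift_idx(dim(x)[2], by), , , drop = FALSE]

.shift_adj_h <- function(dy, by) {
  idx <- .shift_idx(dim(dy)[1], by)
  dx <- array(0, dim(dy))
  for (i in seq_along(idx)) dx[idx[i], , , ] <- dx[idx[i], , , ] + dy[i, , , ]
  dx
}
.shift_adj_w <- function(dy, by) {
  idx <- .shift_idx(dim(dy)[2], by)
  dx <- array(0, dim(dy))
  for (i in seq_along(idx)) dx[, idx[i], , ] <- dx[, idx[i], , ] + dy[, i, , ]
  dx
}

# Sobel gradients with replicate borders: smoothing [1,2,1] along one axis,
# central difference along the other, normalized by 1/8.
.sobel_f <- function(x) {
  dw <- (.shift_w(x, 1L) - .shift_w(x, -1L))
  gx <- (.shift_h(dw, 1L) + 2 * dw + .shift_h(dw, -1L)) / 8
  dh <- (.shift_h(x, 1L) - .shift_h(x, -1L))
  gy <- (.shift_w(dh, 1L) + 2 * dh + .shift_w(dh, -1L)) / 8
  m <- sqrt(gx^2 + gy^2 + 1e-12)
  list(y = x + m, cache = list(gx = gx, gy = gy, m = m))
}

.sobel_b <- function(dy, cache) {
  dgx <- dy * cache$gx / cache$m
  dgy <- dy * cache$gy / cache$m
  ddw <- (.shift_adj_h(dgx, 1L) + 2 * dgx + .shift_adj_h(dgx, -1L)) / 8
  dx <- .shift_adj_w(ddw, 1L) - .shift_adj_w(ddw, -1L)
  ddh <- (.shift_adj_w(dgy, 1L) + 2 * dgy + .shift_adj_w(dgy, -1L)) / 8
  dx <- dx + .shift_adj_h(ddh, 1L) - .shift_adj_h(ddh, -1L)
  dy + dx
}

#' Standalone DWT-diffusion block: diffusion steps plus a residual conv stack
#'
#' Applies `cfg$n_steps` diffusion updates (or the Sobel edge branch, or an
#' identity pass-through, per `cfg$mode`) followed by a residual
#' two-convolution block (conv-BN-ReLU-conv-BN plus identity skip).  This is
#' the diffusion expert used inside the full network, exposed with its own
#' weights for direct use; create weights with [pmd_block_init()].
#'
#' @param u feature map `(H, W, C, N)` (lower-dimensional arrays promoted);
#'   channel count must match the block's weights.
#' @param weights parameter list from [pmd_block_init()].
#' @param cfg a [pmd_config()].
#' @param training use batch statistics in the normalization layers.
#' @return array of the same shape as `u`.
#' @export
pmd_block <- function(u, weights, cfg = pmd_config(), training = FALSE) {
  orig <- dim(u)
  x <- .as4d(u)
  cs <- dim(weights$conv1$w)[3]
  if (dim(x)[3] != cs) {
    stop("input has ", dim(x)[3], " channels but the block was built for ", cs)
  }
  if (cfg$mode == "dwt_pmd") {
    sg <- if (cfg$update_sign == "additive") 1 else -1
    for (i in seq_len(cfg$n_steps)) x <- .pmd_step_f(x, cfg$k, sg)$y
  } else if (cfg$mode == "sobel_edge") {
    x <- .sobel_f(x)$y
  }
  st <- weights$state
  c1 <- .conv_f(x, weights$conv1, 1L, 1L)
  b1 <- .bn_f(c1$y, weights$bn1, st, "bn1", training)
  c2 <- .conv_f(pmax(b1$y, 0), weights$conv2, 1L, 1L)
  b2 <- .bn_f(c2$y, weights$bn2, st, "bn2", training)
  .restore_dim(b2$y + x, orig)
}

#' @rdname pmd_block
#' @param channels feature channels the block operates on.
#' @param seed optional seed for reproducible initialization.
#' @export
pmd_block_init <- function(channels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- new.env(parent = emptyenv())
  st[["bn1.rm"]] <- numeric(channels); st[["bn1.rv"]] <- rep(1, channels)
  st[["bn2.rm"]] <- numeric(channels); st[["bn2.rv"]] <- rep(1, channels)
  list(conv1 = .conv_init(3L, 3L, channels, channels),
       bn1 = .bn_init(channels),
       conv2 = .conv_init(3L, 3L, channels, channels),
       bn2 = .bn_init(channels),
       state = st)
}

#' Classical finite-difference Perona-Malik diffusion (reference operator)
#'
#' Explicit four-neighbour scheme for the continuous anisotropic diffusion
#' equation: each step moves `dt * sum(g(|d|) * d)` over the four
#' neighbour differences `d`, with replicate boundary handling.  Because
#' each pairwise flux is antisymmetric and border fluxes vanish, the mean
#' intensity is conserved.  Serves as the behavioural reference the DWT
#' update is compared against: it smooths flat regions (like Gaussian
#' smoothing) while leaving strong edges in place.
#'
#' @param u feature map array.
#' @param k positive contrast constant.
#' @param dt step size; must satisfy `dt <= 0.25` for stability.
#' @param steps number of explicit steps, `>= 1`.
#' @return diffused array, same shape.
#' @export
finite_difference_pmd <- function(u, k = 1, dt = 0.25, steps = 1L) {
  if (dt <= 0 || dt > 0.25) stop("dt must be in (0, 0.25] for stability")
  if (steps < 1) stop("steps must be >= 1")
  orig <- dim(u)
  x <- .as4d(u)
  .check_finite(x)
  for (s in seq_len(steps)) {
    dN <- .shift_h(x, -1L) - x
    dS <- .shift_h(x, 1L) - x
    dW <- .shift_w(x, -1L) - x
    dE <- .shift_w(x, 1L) - x
    x <- x + dt * (diffusion_coefficient(abs(dN), k) * dN +
                   diffusion_coefficient(abs(dS), k) * dS +
                   diffusion_coefficient(abs(dW), k) * dW +
                   diffusion_coefficient(abs(dE), k) * dE)
  }
  .restore_dim(x, orig)
}
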