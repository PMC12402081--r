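# Internal array plumbing.  Feature maps are column-major R arrays with
# dims (H, W, C, N); token tensors are (M, D, B).

.as4d <- function(u, what = "feature map") {
  if (!is.numeric(u)) stop(what, " must be numeric")
  d <- dim(u)
  if (is.null(d)) stop(what, " must be a matrix or array")
  if (length(d) == 2L) dim(u) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(u) <- c(d, 1L)
  else if (length(d) != 4L) stop(what, " must have 2, 3 or 4 dimensions")
  u
}

.restore_dim <- function(u, orig_dim) {
  if (length(orig_dim) < 4L) dim(u) <- dim(u)[seq_along(orig_dim)]
  u
}

.check_finite <- function(u, what = "input") {
  if (!all(is.finite(u))) stop(what, " contains non-finite values")
  invisible(u)
}

# broadcast a per-channel vector over (H, W, C, N) — relies on R recycling
# across the batch axis.
.bc_ch <- function(v, H, W) rep(v, each = H * W)

# per-channel sum over (H, W, N)
.ch_sum <- function(x) {
  d <- dim(x)
  s <- colSums(matrix(x, d[1] * d[2], d[3] * d[4]))
  rowSums(matrix(s, d[3], d[4]))
}

# per-sample, per-channel spatial mean: returns (C, N) matrix
.spatial_mean <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softplus <- function(x) {
  # overflow-safe log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

.silu <- function(x) x * .sigmoid(x)

.dsilu <- function(x) {
  s <- .sigmoid(x)
  s * (1 + x * (1 - s))
}

# Bilinear interpolation weights from n_in to n_out samples, half-pixel
# centers (align_corners = FALSE).  Dense (n_out, n_in) matrix; sizes here
# are small (<= input resolution) so dense is fine.
.interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  w <- src - i0
  lo <- pmin(pmax(i0, 0), n_in - 1) + 1
  hi <- pmin(pmax(i0 + 1, 0), n_in - 1) + 1
  for (i in seq_len(n_out)) {
    A[i, lo[i]] <- A[i, lo[i]] + (1 - w[i])
    A[i, hi[i]] <- A[i, hi[i]] + w[i]
  }
  A
}

# Apply separable resampling matrices to (H, W, C, N).
.resize_apply <- function(x, Ah, Aw) {
  d <- dim(x)
  y <- Ah %*% matrix(x, d[1], d[2] * d[3] * d[4])
  dim(y) <- c(nrow(Ah), d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  y <- Aw %*% matrix(y, d[2], nrow(Ah) * d[3] * d[4])
  dim(y) <- c(nrow(Aw), nrow(Ah), d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}

.seed_stream <- function(seed, offset) {
  # derived RNG seed, kept within 32-bit integer range
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}
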