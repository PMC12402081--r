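# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the Haar oracle works block-by-block with direct
# filter arithmetic, the scan oracle is a plain R loop, the metric oracles
# use raw set arithmetic, and the polygon oracle uses winding angles.

# per-2x2-block orthonormal Haar analysis of a single matrix
haar_block_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  ll <- lh <- hl <- hh <- matrix(0, H / 2, W / 2)
  for (i in seq_len(H / 2)) {
    for (j in seq_len(W / 2)) {
      a <- m[2 * i - 1, 2 * j - 1]; b <- m[2 * i - 1, 2 * j]
      cc <- m[2 * i, 2 * j - 1]; d <- m[2 * i, 2 * j]
      ll[i, j] <- (a + b + cc + d) / 2
      lh[i, j] <- (a - b + cc - d) / 2
      hl[i, j] <- (a + b - cc - d) / 2
      hh[i, j] <- (a - b - cc + d) / 2
    }
  }
  list(ll = ll, lh = lh, hl = hl, hh = hh)
}

# inverse of the block oracle, again by direct arithmetic
haar_block_synth_oracle <- function(ll, lh, hl, hh) {
  H <- 2 * nrow(ll); W <- 2 * ncol(ll)
  m <- matrix(0, H, W)
  for (i in seq_len(nrow(ll))) {
    for (j in seq_len(ncol(ll))) {
      m[2 * i - 1, 2 * j - 1] <- (ll[i, j] + lh[i, j] + hl[i, j] + hh[i, j]) / 2
      m[2 * i - 1, 2 * j] <- (ll[i, j] - lh[i, j] + hl[i, j] - hh[i, j]) / 2
      m[2 * i, 2 * j - 1] <- (ll[i, j] + lh[i, j] - hl[i, j] - hh[i, j]) / 2
      m[2 * i, 2 * j] <- (ll[i, j] - lh[i, j] - hl[i, j] + hh[i, j]) / 2
    }
  }
  m
}

# the full discrete diffusion update, computed from the block oracle only
pmd_step_oracle <- function(m, k = 1, sign = 1) {
  s <- haar_block_oracle(m)
  g <- 1 / (1 + (s$lh^2 + s$hl^2) / k^2)
  z <- matrix(0, nrow(s$ll), ncol(s$ll))
  m + sign * haar_block_synth_oracle(z, g * s$lh, g * s$hl, z)
}

# explicit scalar-state scan loop (independent of the package's reference)
scan_loop_oracle <- function(x, abar, bbar, Cm) {
  N <- ncol(abar)
  h <- numeric(N); y <- numeric(length(x))
  t <- 1
  while (t <= length(x)) {
    h <- abar[t, ] * h + bbar[t, ] * x[t]
    y[t] <- sum(Cm[t, ] * h)
    t <- t + 1
  }
  y
}

# set-arithmetic metric oracle
prd_oracle <- function(pred, ref) {
  pi <- which(pred); ri <- which(ref)
  tp <- length(intersect(pi, ri))
  fp <- length(setdiff(pi, ri)); fn <- length(setdiff(ri, pi))
  if (tp + fp + fn == 0) return(c(1, 1, 1))
  c(if (tp + fp == 0) 0 else tp / (tp + fp),
    if (tp + fn == 0) 0 else tp / (tp + fn),
    2 * tp / (2 * tp + fp + fn))
}

# all-pairs boundary Hausdorff (percentile 100), independent boundary rule
hd_oracle <- function(pred, ref) {
  bound <- function(m) {
    pts <- which(m, arr.ind = TRUE)
    keep <- logical(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      r <- pts[i, 1]; c <- pts[i, 2]
      nb <- c(r == 1, r == nrow(m), c == 1, c == ncol(m))
      if (!nb[1]) nb[1] <- !m[r - 1, c]
      if (!nb[2]) nb[2] <- !m[r + 1, c]
      if (!nb[3]) nb[3] <- !m[r, c - 1]
      if (!nb[4]) nb[4] <- !m[r, c + 1]
      keep[i] <- any(nb)
    }
    pts[keep, , drop = FALSE]
  }
  a <- bound(pred); b <- bound(ref)
  dmin <- function(p, q) {
    sapply(seq_len(nrow(p)), function(i)
      min(sqrt((p[i, 1] - q[, 1])^2 + (p[i, 2] - q[, 2])^2)))
  }
  max(max(dmin(a, b)), max(dmin(b, a)))
}

# winding-angle interior test with boundary tolerance
polygon_oracle <- function(poly, H, W, tol = 1e-9) {
  inside <- matrix(FALSE, H, W)
  n <- nrow(poly)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      ang <- 0; onb <- FALSE
      for (i in seq_len(n)) {
        a <- poly[i, ] - c(cc, r)
        b <- poly[if (i == n) 1 else i + 1, ] - c(cc, r)
        cr <- a[1] * b[2] - a[2] * b[1]
        dt <- a[1] * b[1] + a[2] * b[2]
        seg2 <- sum((b - a)^2)
        if (seg2 > tol) {
          t <- -sum(a * (b - a)) / seg2
          pr <- a + min(max(t, 0), 1) * (b - a)
          if (sum(pr^2) <= tol) onb <- TRUE
        }
        ang <- ang + atan2(cr, dt)
      }
      inside[r, cc] <- onb || abs(ang) > pi
    }
  }
  inside
}

# small random feature maps with a fixed seed
rand_map <- function(seed, d) {
  set.seed(seed)
  array(rnorm(prod(d)), d)
}

# shared synthetic dataset for the training tests (built once per run)
tiny_train_data <- local({
  cache <- NULL
  function(n_train = 8, n_val = 2, seed = 7) {
    key <- paste(n_train, n_val, seed)
    if (!is.null(cache) && cache$key == key) return(cache$val)
    dir <- file.path(tempdir(), paste0("pm_ds_", n_train, "_", seed))
    if (!file.exists(file.path(dir, "manifest.csv"))) {
      generate_echo_dataset(n_train, n_val, 0,
                            echo_phantom_params(image_size = 64),
                            seed = seed, out_dir = dir)
    }
    val <- list(train = load_image_mask_dir(dir, split = "train"),
                val = load_image_mask_dir(dir, split = "val"),
                dir = dir)
    cache <<- list(key = key, val = val)
    val
  }
})

mean_mask_dice <- function(masks, y) {
  n <- dim(masks)[3]
  mean(sapply(seq_len(n), function(i) {
    cc <- confusion_counts(masks[, , i], y[, , 1, i])
    precision_recall_dice(cc)[["dice"]]
  }))
}
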