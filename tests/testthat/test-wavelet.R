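test_that("dwt2 matches hand-derived Haar values and halving contract", {
  # constant image: orthonormal low-pass gain 2, zero detail
  s <- dwt2(matrix(3.7, 4, 4))
  expect_equal(as.vector(s$ll), rep(7.4, 4))
  expect_equal(max(abs(c(s$lh, s$hl, s$hh))), 0)
  # 2x2 hand example under the stated LH/HL orientation convention
  s2 <- dwt2(matrix(c(1, 3, 2, 4), 2, 2))  # rows: (1,2) / (3,4)
  expect_equal(as.numeric(s2$ll), 5)
  expect_equal(as.numeric(s2$lh), -1)
  expect_equal(as.numeric(s2$hl), -2)
  expect_equal(as.numeric(s2$hh), 0)
  # shape contract
  s3 <- dwt2(rand_map(1, c(8, 8, 3, 2)))
  expect_equal(dim(s3$ll), c(4L, 4L, 3L, 2L))
  expect_equal(dim(s3$hh), c(4L, 4L, 3L, 2L))
  expect_error(dwt2(matrix(0, 3, 4)), "height")
  expect_error(dwt2(matrix(0, 4, 5)), "width")
})

test_that("dwt2 agrees with a per-block brute-force oracle", {
  for (seed in 1:5) {
    m <- matrix(rnorm(36, sd = 2), 6, 6)
    s <- dwt2(m)
    o <- haar_block_oracle(m)
    expect_equal(matrix(s$ll, 3, 3), o$ll, tolerance = 1e-12)
    expect_equal(matrix(s$lh, 3, 3), o$lh, tolerance = 1e-12)
    expect_equal(matrix(s$hl, 3, 3), o$hl, tolerance = 1e-12)
    expect_equal(matrix(s$hh, 3, 3), o$hh, tolerance = 1e-12)
  }
})

test_that("idwt2 inverts dwt2 and handles hand and degenerate cases", {
  # hand example inverse
  u <- idwt2(list(ll = matrix(5), lh = matrix(-1), hl = matrix(-2),
                  hh = matrix(0)))
  expect_equal(matrix(u, 2, 2), matrix(c(1, 3, 2, 4), 2, 2))
  # all-zero bands -> zero image
  z <- matrix(0, 2, 2)
  expect_equal(max(abs(idwt2(list(ll = z, lh = z, hl = z, hh = z)))), 0)
  # perfect reconstruction on seeded random inputs
  for (seed in 1:10) {
    x <- rand_map(seed, c(8, 10, 2, 1))
    expect_lt(max(abs(idwt2(dwt2(x)) - x)), 1e-6 * max(abs(x)))
  }
  expect_error(idwt2(list(ll = matrix(0, 2, 2), lh = matrix(0, 2, 3),
                          hl = matrix(0, 2, 2), hh = matrix(0, 2, 2))),
               "shape")
})

test_that("diffusion coefficient has the closed-form values and monotone range", {
  expect_identical(diffusion_coefficient(0, 1), 1)
  expect_identical(diffusion_coefficient(1, 1), 0.5)
  expect_identical(diffusion_coefficient(3, 1), 0.1)
  # scaling in k: g(k) = 0.5, g(3k) = 0.1
  expect_equal(diffusion_coefficient(2.5, 2.5), 0.5)
  expect_equal(diffusion_coefficient(7.5, 2.5), 0.1)
  m <- seq(0, 10, by = 0.1)
  g <- diffusion_coefficient(m, 1.3)
  expect_true(all(g > 0 & g <= 1))
  expect_true(all(diff(g) < 0))
  expect_error(diffusion_coefficient(-1, 1), "nonnegative")
  expect_error(diffusion_coefficient(1, 0), "positive")
})

test_that("pmd_step is exactly the identity on constant and zero inputs", {
  u <- array(2.2, c(4, 4, 2, 1))
  expect_lte(max(abs(pmd_step(u) - u)), 1e-7)
  z <- array(0, c(6, 6, 1, 1))
  expect_identical(max(abs(pmd_step(z))), 0)
})

test_that("pmd_step matches the brute-force per-block oracle", {
  # hand-style vertical step edge
  edge <- matrix(rep(c(0, 0, 1, 1), each = 4), 4, 4)
  got <- pmd_step(edge)
  expect_equal(matrix(got, 4, 4), pmd_step_oracle(edge), tolerance = 1e-12)
  # seeded random maps, both update signs and several k
  for (seed in 1:20) {
    m <- matrix(rnorm(64, sd = 1.5), 8, 8)
    expect_lt(max(abs(pmd_step(m) - pmd_step_oracle(m))), 1e-6)
    cfg <- pmd_config(k = 0.5, update_sign = "subtractive")
    expect_lt(max(abs(pmd_step(m, cfg) - pmd_step_oracle(m, 0.5, -1))), 1e-6)
  }
})

test_that("pmd_step acts per channel independently", {
  x <- rand_map(3, c(8, 8, 4, 2))
  perm <- c(3, 1, 4, 2)
  direct <- pmd_step(x)
  permuted <- pmd_step(x[, , perm, , drop = FALSE])
  expect_equal(permuted[, , order(perm), ], direct, tolerance = 1e-12)
})

test_that("classical finite-difference diffusion conserves mass and keeps edges", {
  expect_error(finite_difference_pmd(matrix(0, 4, 4), dt = 0.3),
               "stability")
  u <- array(2.5, c(6, 6, 1, 1))
  expect_equal(finite_difference_pmd(u, steps = 3), u)
  # conservation on a random map
  x <- rand_map(11, c(16, 16, 1, 1))
  y <- finite_difference_pmd(x, k = 1, dt = 0.25, steps = 10)
  expect_lt(abs(mean(y) - mean(x)), 1e-5 * max(1, abs(mean(x))))
  # noisy step edge: intra-region variance falls, edge position stays
  set.seed(21)
  edge <- matrix(rep(c(0, 1), each = 8 * 16), 16, 16)  # left half 0
  noisy <- edge + matrix(rnorm(256, sd = 0.08), 16, 16)
  cur <- noisy
  v0 <- var(as.vector(cur[, 1:6])) + var(as.vector(cur[, 11:16]))
  for (s in 1:10) {
    cur <- finite_difference_pmd(cur, k = 0.2, dt = 0.25, steps = 1)
    v1 <- var(as.vector(cur[, 1:6])) + var(as.vector(cur[, 11:16]))
    expect_lt(v1, v0)
    v0 <- v1
    rowgrad <- abs(cur[8, -1] - cur[8, -16])
    expect_equal(which.max(rowgrad), 8L)  # jump between cols 8 and 9
  }
})

test_that("diffusion branch gradient matches finite differences", {
  pm <- asNamespace("pmamba")
  set.seed(4)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2, 1))
  dy <- array(rnorm(6 * 6 * 2), c(6, 6, 2, 1))
  for (sg in c(1, -1)) {
    fw <- pm$.pmd_step_f(x, 0.8, sg)
    ana <- pm$.pmd_step_b(dy, fw$cache)
    num <- x * 0
    eps <- 1e-5
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      num[i] <- (sum(pm$.pmd_step_f(xp, 0.8, sg)$y * dy) -
                   sum(pm$.pmd_step_f(xm, 0.8, sg)$y * dy)) / (2 * eps)
    }
    expect_lt(max(abs(ana - num)), 1e-6)
  }
})

test_that("standalone diffusion block honors its identity and shape contracts", {
  # zeroed residual stack with normalization in identity state -> input
  w <- pmd_block_init(3, seed = 1)
  w$conv1$w[] <- 0; w$conv2$w[] <- 0; w$bn2$gamma[] <- 0
  x <- rand_map(2, c(16, 16, 3, 1))
  off <- pmd_config(mode = "off")
  expect_equal(pmd_block(x, w, off), x, tolerance = 1e-12)
  # shape preservation across modes and shapes
  for (d in list(c(16, 16, 3, 1), c(32, 32, 3, 2))) {
    xx <- rand_map(3, d)
    w2 <- pmd_block_init(3, seed = 2)
    for (mode in c("dwt_pmd", "sobel_edge", "off")) {
      y <- pmd_block(xx, w2, pmd_config(mode = mode))
      expect_equal(dim(y), d)
      expect_true(all(is.finite(y)))
    }
  }
  expect_error(pmd_block(rand_map(1, c(8, 8, 2, 1)), w), "channels")
})
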