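# contracts of the gated two-expert block, encoder pyramid, decoder and the
# full forward pass; uses a micro configuration so each check runs in
# seconds

micro_cfg <- function(size = 64, ...) {
  pmamba_tiny_config(size, stage_channels = c(4L, 4L, 8L, 8L),
                     state_dim = 2L, decoder_width = 8L, ...)
}

test_that("gate weight is a sigmoid of pooled features with the stated anchors", {
  H <- rand_map(1, c(6, 6, 5, 3))
  # zero weights and bias -> exactly 0.5
  expect_identical(gate_weight(H, numeric(5), 0), rep(0.5, 3))
  # saturation under a large bias
  expect_true(all(gate_weight(H, numeric(5), 20) >= 1 - 1e-8))
  # permutation of the spatial extent leaves the gate unchanged
  w <- rnorm(5)
  set.seed(2)
  perm <- sample(36)
  Hp <- H
  for (cc in 1:5) for (n in 1:3) {
    Hp[, , cc, n] <- matrix(as.vector(H[, , cc, n])[perm], 6, 6)
  }
  expect_equal(gate_weight(Hp, w, 0.3), gate_weight(H, w, 0.3))
  expect_true(all(gate_weight(H, w, 0.3) > 0 & gate_weight(H, w, 0.3) < 1))
  # channel-scoped gate returns one weight per channel and sample
  wc <- gate_weight(H, matrix(0, 5, 5), numeric(5))
  expect_equal(dim(wc), c(5L, 3L))
  expect_true(all(wc == 0.5))
})

test_that("gated fusion output lies between the two expert outputs", {
  pm <- asNamespace("pmamba")
  cfg <- micro_cfg()
  m <- pmamba_init(cfg, seed = 1)
  # make the gate non-trivial
  m$params$stages[[2]]$blocks[[1]]$gate$w <- rnorm(4)
  m$params$stages[[2]]$blocks[[1]]$gate$b <- 0.3
  x <- rand_map(5, c(16, 16, 4, 2))
  bf <- pm$.block_f(x, m$params$stages[[2]]$blocks[[1]], cfg,
                    pm$.stage_vim_cfg(cfg, 2), m$state, "s2b1",
                    FALSE, 0)
  lo <- pmin(bf$cache$P, bf$cache$V)
  hi <- pmax(bf$cache$P, bf$cache$V)
  expect_true(all(bf$y >= lo - 1e-12 & bf$y <= hi + 1e-12))
  w <- bf$cache$w
  expect_true(all(w > 0 & w < 1))
  # w forced to 1 reproduces the diffusion expert exactly
  m$params$stages[[2]]$blocks[[1]]$gate$b <- 40
  bf1 <- pm$.block_f(x, m$params$stages[[2]]$blocks[[1]], cfg,
                     pm$.stage_vim_cfg(cfg, 2), m$state, "s2b1", FALSE, 0)
  expect_equal(bf1$y, bf1$cache$P, tolerance = 1e-9)
})

test_that("stochastic depth drops whole blocks and is identity at inference", {
  pm <- asNamespace("pmamba")
  cfg <- micro_cfg()
  m <- pmamba_init(cfg, seed = 1)
  x <- rand_map(6, c(16, 16, 4, 2))
  blk <- m$params$stages[[2]]$blocks[[1]]
  vc <- pm$.stage_vim_cfg(cfg, 2)
  # droppath probability 1 in training: only the residual path remains
  b1 <- pm$.block_f(x, blk, cfg, vc, m$state, "s2b1", TRUE, 1)
  expect_identical(b1$y, x)
  # inference ignores droppath entirely
  b0 <- pm$.block_f(x, blk, cfg, vc, m$state, "s2b1", FALSE, 1)
  expect_false(identical(b0$y, x))
})

test_that("residual conv block reduces to identity when zeroed", {
  pm <- asNamespace("pmamba")
  cfg <- micro_cfg(pmd_mode = "off")
  m <- pmamba_init(cfg, seed = 1)
  blk <- m$params$stages[[1]]$blocks[[1]]
  blk$pmd$conv1$w[] <- 0; blk$pmd$conv1$b[] <- 0
  blk$pmd$conv2$w[] <- 0; blk$pmd$conv2$b[] <- 0
  blk$pmd$bn2$gamma[] <- 0   # normalization in identity-output state
  x <- rand_map(7, c(16, 16, 4, 1))
  bf <- pm$.block_f(x, blk, cfg, pm$.stage_vim_cfg(cfg, 1), m$state,
                    "s1b1", FALSE, 0)
  expect_equal(bf$cache$P, x, tolerance = 1e-12)
  # dwt mode on a constant image: the pre-residual tensor equals the input
  cfg2 <- micro_cfg()
  m2 <- pmamba_init(cfg2, seed = 1)
  xc <- array(1.3, c(16, 16, 4, 1))
  bf2 <- pm$.block_f(xc, m2$params$stages[[1]]$blocks[[1]], cfg2,
                     pm$.stage_vim_cfg(cfg2, 1), m2$state, "s1b1", FALSE, 0)
  expect_equal(bf2$cache$u, xc, tolerance = 1e-12)
})

test_that("encoder emits the 1/4..1/32 pyramid for several input sizes", {
  for (size in c(64L, 96L, 128L)) {
    cfg <- micro_cfg(size)
    m <- pmamba_init(cfg, seed = 1)
    pyr <- pmamba_encode(m, array(runif(size * size), c(size, size, 1, 1)))
    expect_equal(vapply(pyr, function(a) dim(a)[1], 0L),
                 size %/% c(4L, 8L, 16L, 32L))
    expect_equal(vapply(pyr, function(a) dim(a)[3], 0L), cfg$stage_channels)
  }
  expect_error(pmamba_config(input_size = 100), "divisible")
})

test_that("decoder maps a pyramid to input-resolution logits", {
  cfg <- micro_cfg()
  m <- pmamba_init(cfg, seed = 2)
  pyr <- pmamba_encode(m, rand_map(1, c(64, 64, 1, 2)))
  logits <- pmamba_decode(m, pyr)
  expect_equal(dim(logits), c(64L, 64L, 1L, 2L))
  expect_true(all(is.finite(logits)))
  expect_error(pmamba_decode(m, pyr[1:3]), "4-level")
  # all-zero decoder weights: logits equal the final bias everywhere
  m0 <- m
  for (nm in names(m0$params$dec)) {
    p <- m0$params$dec[[nm]]
    for (f in names(p)) p[[f]][] <- 0
    m0$params$dec[[nm]] <- p
  }
  m0$params$dec$head$b[] <- 0.7
  l0 <- pmamba_decode(m0, pyr)
  expect_equal(max(abs(l0 - 0.7)), 0, tolerance = 1e-12)
})

test_that("forward pass yields deterministic probabilities in (0,1)", {
  cfg <- micro_cfg()
  m <- pmamba_init(cfg, seed = 3)
  x <- rand_map(4, c(64, 64, 1, 2))
  p1 <- pmamba_forward(m, x)
  p2 <- pmamba_forward(m, x)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_equal(dim(p1), c(64L, 64L, 1L, 2L))
})

test_that("every trainable parameter receives a nonzero gradient", {
  pm <- asNamespace("pmamba")
  cfg <- micro_cfg()
  m <- pmamba_init(cfg, seed = 5)
  set.seed(5)
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  y <- array((rand_map(6, c(64, 64, 1, 2)) > 0.5) * 1, c(64, 64, 1, 2))
  fw <- pm$.model_f(m, x, training = TRUE)
  lg <- pm$.loss_grad(fw$logits, fw$probs, y, "dice_bce")
  bw <- pm$.model_b(m, fw$cache, lg$dlogits)
  fp <- pm$.flatten_params(m$params)
  fg <- pm$.flatten_params(bw$g)
  expect_setequal(names(fg), names(fp))
  dead <- names(fp)[vapply(names(fp),
                           function(k) all(fg[[k]] == 0), TRUE)]
  expect_identical(dead, character(0))
})

test_that("model gradients agree with finite differences on sampled weights", {
  pm <- asNamespace("pmamba")
  cfg <- micro_cfg()
  m <- pmamba_init(cfg, seed = 11)
  set.seed(11)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  y <- array((rand_map(12, c(64, 64, 1, 1)) > 0.8) * 1, c(64, 64, 1, 1))
  fw <- pm$.model_f(m, x, training = TRUE)
  lg <- pm$.loss_grad(fw$logits, fw$probs, y, "dice_bce")
  bw <- pm$.model_b(m, fw$cache, lg$dlogits)
  fg <- pm$.flatten_params(bw$g)
  fp <- pm$.flatten_params(m$params)
  loss_at <- function(params) {
    m2 <- m
    m2$params <- params
    st <- as.list(m$state)
    m2$state <- new.env()
    for (k in names(st)) m2$state[[k]] <- st[[k]]
    f2 <- pm$.model_f(m2, x, training = TRUE)
    pm$.loss_grad(f2$logits, f2$probs, y, "dice_bce")$loss
  }
  set.seed(13)
  keys <- sample(names(fp), 12)
  for (k in keys) {
    idx <- which.max(abs(fg[[k]]))          # best signal-to-noise entry
    eps <- 1e-3
    vp <- fp[[k]]; vp[idx] <- vp[idx] + eps
    vm <- fp[[k]]; vm[idx] <- vm[idx] - eps
    lp <- loss_at(pm$.unflatten_into(m$params, stats::setNames(list(vp), k)))
    lm <- loss_at(pm$.unflatten_into(m$params, stats::setNames(list(vm), k)))
    num <- (lp - lm) / (2 * eps)
    ana <- fg[[k]][idx]
    expect_lt(abs(num - ana) / max(1e-5, abs(num), abs(ana)), 0.05)
  }
})

test_that("ablation variants are expressible through configuration alone", {
  for (cfg in list(micro_cfg(pmd_mode = "off"),
                   micro_cfg(pmd_mode = "sobel_edge"),
                   micro_cfg(fusion_mode = "add"),
                   micro_cfg(update_sign = "subtractive"),
                   micro_cfg(bidirectional = FALSE),
                   micro_cfg(gate_scope = "channel"))) {
    m <- pmamba_init(cfg, seed = 1)
    p <- pmamba_forward(m, rand_map(9, c(64, 64, 1, 1)))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("checkpoints round-trip bitwise through save and load", {
  cfg <- micro_cfg()
  m <- pmamba_init(cfg, seed = 4)
  m$norm <- c(0.4, 0.2)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2))
  before <- predict_pmamba(m, x, return_prob = TRUE)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, history = list(note = "unit"))
  m2 <- load_checkpoint(path)
  after <- predict_pmamba(m2, x, return_prob = TRUE)
  expect_identical(before$prob, after$prob)
  expect_identical(before$mask, after$mask)
  expect_true(file.exists(paste0(path, ".json")))
  cfg_echo <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(cfg_echo$input_size, 64L)
})
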