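#' Training configuration
#'
#' Defaults follow the full training protocol: 50 epochs of decoupled-
#' weight-decay Adam (lr 1e-4, weight decay 0.01), batches of 24 at 256x256,
#' validation every 5 epochs with early stopping after 10 evaluations
#' without improvement.
#'
#' @param epochs maximum training epochs.
#' @param learning_rate initial (and constant) learning rate.
#' @param weight_decay decoupled weight decay on weight matrices/kernels.
#' @param batch_size minibatch size.
#' @param input_size square input resolution, divisible by 32.
#' @param eval_every_epochs validation cadence in epochs.
#' @param early_stop_patience evaluations without a new best validation
#'   Dice tolerated before stopping (`patience_unit = "epochs"` instead
#'   counts epochs since the best evaluation).
#' @param patience_unit `"evaluations"` (default) or `"epochs"`.
#' @param seed integer RNG seed covering initialization, shuffling and
#'   stochastic depth.
#' @param loss `"dice_bce"` (equal-weight soft-Dice + binary cross-entropy),
#'   `"bce"` or `"dice"`.
#' @param max_steps optional cap on total optimization steps (for smoke
#'   experiments); `Inf` for none.
#' @param augment apply random horizontal flips and intensity jitter.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 1e-4,
                         weight_decay = 0.01, batch_size = 24L,
                         input_size = 256L, eval_every_epochs = 5L,
                         early_stop_patience = 10L,
                         patience_unit = c("evaluations", "epochs"),
                         seed = 1L, loss = c("dice_bce", "bce", "dice"),
                         max_steps = Inf, augment = FALSE) {
  loss <- match.arg(loss)
  patience_unit <- match.arg(patience_unit)
  stopifnot(epochs >= 1, learning_rate > 0, weight_decay >= 0,
            batch_size >= 1, input_size %% 32 == 0, eval_every_epochs >= 1,
            early_stop_patience >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size),
                 eval_every_epochs = as.integer(eval_every_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 patience_unit = patience_unit,
                 seed = as.integer(seed), loss = loss,
                 max_steps = max_steps, augment = isTRUE(augment)),
            class = "train_config")
}

#' Segmentation loss: soft-Dice plus binary cross-entropy
#'
#' The soft-Dice term uses additive smoothing 1.0 in numerator and
#' denominator and is averaged per sample; the cross-entropy term is the
#' pixelwise mean with probabilities clamped to `[1e-6, 1 - 1e-6]`.
#' `"dice_bce"` weighs the two equally.
#'
#' @param prob probability map in `(0,1)`, any array shape.
#' @param ref binary reference of the same shape.
#' @param type loss type.
#' @return scalar loss, `>= 0`.
#' @export
seg_loss <- function(prob, ref, type = c("dice_bce", "bce", "dice")) {
  type <- match.arg(type)
  if (!identical(dim(.as4d(prob)), dim(.as4d(ref)))) {
    stop("probability and reference shapes differ")
  }
  p4 <- .as4d(prob); y4 <- .as4d(ref)
  pc <- pmin(pmax(p4, 1e-6), 1 - 1e-6)
  bce <- -mean(y4 * log(pc) + (1 - y4) * log(1 - pc))
  d <- dim(p4)
  pm <- matrix(p4, prod(d[1:3]), d[4]); ym <- matrix(y4, prod(d[1:3]), d[4])
  dice <- mean((2 * colSums(pm * ym) + 1) / (colSums(pm) + colSums(ym) + 1))
  switch(type,
         dice_bce = bce + (1 - dice),
         bce = bce,
         dice = 1 - dice)
}

# loss value + gradient w.r.t. logits (sigmoid folded in for stability)
.loss_grad <- function(logits, probs, y, type) {
  d <- dim(probs)
  npx <- prod(d)
  pc <- pmin(pmax(probs, 1e-6), 1 - 1e-6)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  dl_bce <- (probs - y) / npx
  pm <- matrix(probs, prod(d[1:3]), d[4]); ym <- matrix(y, prod(d[1:3]), d[4])
  sp <- colSums(pm); sy <- colSums(ym); spy <- colSums(pm * ym)
  den <- sp + sy + 1
  dice <- (2 * spy + 1) / den
  # d(1 - dice_n)/dp = -(2*y*den - (2*spy + 1)) / den^2, averaged over batch
  dl_dice_m <- -(2 * ym * rep(den, each = nrow(ym)) -
                   rep(2 * spy + 1, each = nrow(ym))) /
    rep(den^2, each = nrow(ym)) / d[4]
  dl_dice <- array(dl_dice_m, d) * probs * (1 - probs)
  switch(type,
         dice_bce = list(loss = bce + 1 - mean(dice),
                         dlogits = dl_bce + dl_dice),
         bce = list(loss = bce, dlogits = dl_bce),
         dice = list(loss = 1 - mean(dice), dlogits = dl_dice))
}

# --- AdamW ------------------------------------------------------------------

.adamw_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

.adamw_step <- function(flat, grads, opt, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(flat)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * gk
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * gk^2
    upd <- (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + eps)
    if (wd > 0 && grepl("\\.w$", k)) upd <- upd + wd * flat[[k]]
    flat[[k]] <- flat[[k]] - lr * upd
  }
  list(flat = flat, opt = opt)
}

# --- training loop ----------------------------------------------------------

.normalize_images <- function(x, norm) (x - norm[1]) / norm[2]

.batch_dice <- function(pred, ref) {
  # per-image Dice over a (H, W, 1, N) pair of binary arrays
  d <- dim(pred)
  pm <- matrix(pred, prod(d[1:3]), d[4]); ym <- matrix(ref, prod(d[1:3]), d[4])
  tp <- colSums(pm * ym)
  den <- colSums(pm) + colSums(ym)
  ifelse(den == 0, 1, 2 * tp / den)
}

.eval_dice <- function(model, x, y, batch_size) {
  n <- dim(x)[4]
  dices <- numeric(0)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    pr <- .model_f(model, x[, , , ix, drop = FALSE], training = FALSE)$probs
    dices <- c(dices, .batch_dice((pr >= 0.5) * 1, y[, , , ix, drop = FALSE]))
  }
  mean(dices)
}

.log_jsonl <- function(path, rec) {
  if (is.null(path)) return(invisible())
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

#' Train a segmentation model
#'
#' Runs the full pipeline: weight initialization, intensity standardization
#' from the training split, minibatch AdamW on the configured loss,
#' periodic validation (per-image Dice at threshold 0.5), best-checkpoint
#' tracking and early stopping.  Deterministic given
#' `train_cfg$seed`.
#'
#' @param model_cfg a [pmamba_config()] (or an already-built
#'   `pmamba_model`, whose weights are then the starting point).
#' @param data list with `train` and `val` elements, each a list with
#'   `x` (images `(H, W, 1, N)`, values in `[0, 1]`) and `y` (binary masks,
#'   same shape), e.g. from [load_image_mask_dir()].
#' @param train_cfg a [train_config()].
#' @param checkpoint_path optional path; the best model is saved there.
#' @param log_path optional JSONL run-log path (seed, config, per-epoch
#'   loss, per-evaluation metrics).
#' @return list with `model` (best-validation weights), `history`
#'   (per-epoch losses, per-evaluation Dice, stopping info) and `norm`
#'   (the train-split standardization constants, also stored in the model).
#' @export
train_pmamba <- function(model_cfg, data, train_cfg = train_config(),
                         checkpoint_path = NULL, log_path = NULL) {
  if (is.null(data$train) || is.null(data$val)) {
    stop("data must contain train and val splits")
  }
  ntr <- dim(.as4d(data$train$x))[4]
  nva <- dim(.as4d(data$val$x))[4]
  if (ntr == 0) stop("training split is empty")
  if (nva == 0) stop("validation split is empty")
  set.seed(train_cfg$seed)
  model <- if (inherits(model_cfg, "pmamba_model")) model_cfg
           else pmamba_init(model_cfg, seed = .seed_stream(train_cfg$seed, 1L))
  norm <- c(mean(data$train$x), max(stats::sd(data$train$x), 1e-6))
  model$norm <- norm
  xtr <- .normalize_images(.as4d(data$train$x), norm)
  ytr <- .as4d(data$train$y)
  xva <- .normalize_images(.as4d(data$val$x), norm)
  yva <- .as4d(data$val$y)

  flat <- .flatten_params(model$params)
  opt <- .adamw_init(flat)
  history <- list(epoch_loss = data.frame(epoch = integer(), loss = numeric()),
                  evals = data.frame(epoch = integer(), val_dice = numeric()))
  .log_jsonl(log_path, list(event = "start", seed = train_cfg$seed,
                            config = unclass(train_cfg),
                            config_hash = sum(utf8ToInt(paste(
                              deparse(unclass(train_cfg)), collapse = ""))),
                            n_train = ntr, n_val = nva))
  best <- -Inf
  best_params <- model$params
  best_state <- as.list(model$state)
  since_best <- 0L
  epoch_of_best <- 0L
  step <- 0L
  stopped <- FALSE
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample.int(ntr)
    losses <- numeric(0)
    for (ix in split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))) {
      xb <- xtr[, , , ix, drop = FALSE]
      yb <- ytr[, , , ix, drop = FALSE]
      if (train_cfg$augment) {
        for (b in seq_along(ix)) {
          if (runif(1) < 0.5) {
            xb[, , , b] <- xb[, rev(seq_len(dim(xb)[2])), , b]
            yb[, , , b] <- yb[, rev(seq_len(dim(yb)[2])), , b]
          }
        }
        xb <- xb * (1 + rnorm(1, sd = 0.05)) + rnorm(1, sd = 0.02)
      }
      fw <- .model_f(model, xb, training = TRUE)
      lg <- .loss_grad(fw$logits, fw$probs, yb, train_cfg$loss)
      bw <- .model_b(model, fw$cache, lg$dlogits)
      gflat <- .flatten_params(bw$g)
      stp <- .adamw_step(flat, gflat, opt, train_cfg$learning_rate,
                         train_cfg$weight_decay)
      flat <- stp$flat
      opt <- stp$opt
      model$params <- .unflatten_into(model$params, flat)
      losses <- c(losses, lg$loss)
      step <- step + 1L
      if (step >= train_cfg$max_steps) break
    }
    history$epoch_loss <- rbind(history$epoch_loss,
                                data.frame(epoch = epoch, loss = mean(losses)))
    .log_jsonl(log_path, list(event = "epoch", epoch = epoch,
                              loss = mean(losses), step = step))
    do_eval <- (epoch %% train_cfg$eval_every_epochs == 0L) ||
      epoch == train_cfg$epochs || step >= train_cfg$max_steps
    if (do_eval) {
      vd <- .eval_dice(model, xva, yva, train_cfg$batch_size)
      history$evals <- rbind(history$evals,
                             data.frame(epoch = epoch, val_dice = vd))
      .log_jsonl(log_path, list(event = "eval", epoch = epoch, val_dice = vd))
      if (vd > best) {
        best <- vd
        best_params <- model$params
        best_state <- as.list(model$state)
        since_best <- 0L
        epoch_of_best <- epoch
      } else {
        since_best <- since_best +
          if (train_cfg$patience_unit == "evaluations") 1L
          else train_cfg$eval_every_epochs
      }
      if (since_best > train_cfg$early_stop_patience) {
        stopped <- TRUE
      }
    }
    if (stopped || step >= train_cfg$max_steps) break
  }
  model$params <- best_params
  for (k in names(best_state)) model$state[[k]] <- best_state[[k]]
  history$best_val_dice <- best
  history$best_epoch <- epoch_of_best
  history$stopped_early <- stopped
  history$total_steps <- step
  if (!is.null(checkpoint_path)) {
    save_checkpoint(model, checkpoint_path, history)
  }
  .log_jsonl(log_path, list(event = "end", best_val_dice = best,
                            stopped_early = stopped, total_steps = step))
  list(model = model, history = history, norm = norm)
}

#' Predict binary masks for a batch of images
#'
#' Applies the model's stored intensity standardization, runs the forward
#' pass in inference mode and thresholds the probability map.  Images whose
#' size does not match the model's input size are bilinearly resized (with
#' a warning), or rejected in strict mode.
#'
#' @param model a `pmamba_model` (e.g. from [train_pmamba()] or
#'   [load_checkpoint()]).
#' @param images array `(H, W)`, `(H, W, N)` or `(H, W, 1, N)` in `[0, 1]`.
#' @param threshold probability cut for the foreground class.
#' @param strict_size error instead of resizing on a size mismatch.
#' @param batch_size images per forward pass.
#' @param return_prob also return the probability maps.
#' @return binary mask array `(H, W, N)` (input-sized); with
#'   `return_prob = TRUE` a list with `mask` and `prob`.
#' @export
predict_pmamba <- function(model, images, threshold = 0.5,
                           strict_size = FALSE, batch_size = 16L,
                           return_prob = FALSE) {
  x <- images
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  x <- .as4d(x, "images")
  d <- dim(x)
  sz <- model$cfg$input_size
  resized <- FALSE
  if (d[1] != sz || d[2] != sz) {
    if (strict_size) {
      stop("image size ", d[1], "x", d[2], " does not match model input ",
           sz, " (strict mode)")
    }
    warning("resizing ", d[1], "x", d[2], " input to model size ", sz)
    x <- .resize_f(x, sz, sz)$y
    resized <- TRUE
  }
  if (!is.null(model$norm)) x <- .normalize_images(x, model$norm)
  n <- dim(x)[4]
  prob <- array(0, c(sz, sz, 1L, n))
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    prob[, , , ix] <- .model_f(model, x[, , , ix, drop = FALSE],
                               training = FALSE)$probs
  }
  if (resized) prob <- .resize_f(prob, d[1], d[2])$y
  mask <- array((prob >= threshold) * 1, c(d[1], d[2], n))
  if (return_prob) list(mask = mask, prob = array(prob, c(d[1], d[2], n)))
  else mask
}
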