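#' U-net architecture configuration
#'
#' A volumetric encoder--decoder with skip connections.  Each convolution
#' block stacks `convs_per_block` 3x3x3 same-size convolutions with ReLU;
#' a strided (2x2x2) convolution ends each encoder block, halving the
#' spatial size, and the kernel count doubles after each encoder block.
#' The decoder mirrors the encoder with transposed convolutions and
#' concatenating skip connections; the final 3x3x3 convolution is linear
#' with one output channel.  One dropout layer per block (after its last
#' convolution) is active during training only.
#'
#' @param depth number of encoder blocks (default 3).
#' @param convs_per_block convolutions per block (default 3).
#' @param base_channels kernels in the first block (default 32; small test
#'   models use 8).
#' @param dropout_rate dropout probability in [0, 1) (default 0.5).
#' @param kernel kernel side (fixed at 3).
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(depth = 3, convs_per_block = 3, base_channels = 32,
                        dropout_rate = 0.5, kernel = 3) {
  stopifnot(depth >= 1, convs_per_block >= 1, base_channels >= 1,
            dropout_rate >= 0, dropout_rate < 1, kernel == 3)
  structure(list(depth = depth, convs_per_block = convs_per_block,
                 base_channels = base_channels, dropout_rate = dropout_rate,
                 kernel = kernel),
            class = "unet_config")
}

#' Training hyper-parameters
#'
#' @param learning_rate Adam initial learning rate (default 4e-4).
#' @param epochs_per_iteration passes over the paired dataset (default 10).
#' @param batch_size pairs per gradient step (default 8).
#' @param rng_seed seed controlling shuffling and dropout masks.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 4e-4, epochs_per_iteration = 10,
                         batch_size = 8, rng_seed = 1) {
  stopifnot(learning_rate > 0, epochs_per_iteration >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 epochs_per_iteration = epochs_per_iteration,
                 batch_size = batch_size, rng_seed = rng_seed),
            class = "train_config")
}

# Channel width of encoder block b (1-based): base * 2^(b-1).
unet_channels <- function(cfg, b) cfg$base_channels * 2L^(b - 1L)

# ---- parameter initialisation -------------------------------------------

init_conv <- function(cin, cout, k, sd = NULL) {
  fan_in <- cin * k^3
  if (is.null(sd)) sd <- sqrt(2 / fan_in)     # He initialisation for ReLU
  list(W = matrix(stats::rnorm(cout * cin * k^3, sd = sd), cout, cin * k^3),
       b = numeric(cout))
}

# Transposed conv weight, stored as (Cin x Cout*k^3).
init_tconv <- function(cin, cout, k) {
  fan_in <- cin * k^3
  list(W = matrix(stats::rnorm(cin * cout * k^3, sd = sqrt(2 / fan_in)),
                  cin, cout * k^3),
       b = numeric(cout))
}

#' Build a U-net model
#'
#' Allocates and seeds all parameters.  The model maps any cubic volume
#' whose side is divisible by `2^depth` to a volume of the same shape.
#'
#' @param cfg a [unet_config].
#' @param rng_seed seed for parameter initialisation; two builds with the
#'   same seed are identical.
#' @return An object of class `unet_model`.
#' @export
build_model <- function(cfg = unet_config(), rng_seed = 1) {
  k <- cfg$kernel
  m <- cfg$convs_per_block
  params <- list()
  with_seed(rng_seed, {
    for (b in seq_len(cfg$depth)) {
      cin <- if (b == 1) 1L else unet_channels(cfg, b)
      ch <- unet_channels(cfg, b)
      for (j in seq_len(m)) {
        params[[sprintf("enc%d_conv%d", b, j)]] <-
          init_conv(if (j == 1) cin else ch, ch, k)
      }
      params[[sprintf("down%d", b)]] <- init_conv(ch, unet_channels(cfg, b + 1), k)
    }
    chb <- unet_channels(cfg, cfg$depth + 1)
    for (j in seq_len(m))
      params[[sprintf("bot_conv%d", j)]] <- init_conv(chb, chb, k)
    for (b in rev(seq_len(cfg$depth))) {
      ch <- unet_channels(cfg, b)
      params[[sprintf("up%d", b)]] <- init_tconv(unet_channels(cfg, b + 1), ch, k)
      for (j in seq_len(m))
        params[[sprintf("dec%d_conv%d", b, j)]] <-
          init_conv(if (j == 1) 2L * ch else ch, ch, k)
    }
    # small final-layer weights: a fresh model predicts near zero, so the
    # first Fourier merge leaves the originals nearly untouched
    params[["out"]] <- init_conv(unet_channels(cfg, 1), 1L, k, sd = 1e-3)
  })
  structure(list(cfg = cfg, params = params, adam = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("unet_model: depth %d, %d convs/block, base %d channels, %s parameters\n",
              x$cfg$depth, x$cfg$convs_per_block, x$cfg$base_channels,
              format(np, big.mark = ",")))
  invisible(x)
}

# ---- primitive layers ----------------------------------------------------

as_tensor <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  x
}

# vol2col returns patches as rows: (P x C*k^3).  Weights are (Cout x C*k^3)
# for convolutions and (Cin x Cout*k^3) for transposed convolutions, so all
# products below run without explicit transposition.

conv_fwd <- function(x, p, stride = 1L, pad = 1L, k = 3L) {
  col <- vol2col(x, k, stride, pad)
  out <- tcrossprod(col, p$W)                      # (P x Cout)
  out <- out + rep(p$b, each = nrow(col))
  d <- dim(x)[1:3]
  od <- (d + 2L * pad - k) %/% stride + 1L
  dim(out) <- c(od, nrow(p$W))
  out
}

conv_bwd <- function(dout, x, p, stride = 1L, pad = 1L, k = 3L) {
  cout <- dim(dout)[4]
  P <- prod(dim(dout)[1:3])
  doutM <- matrix(dout, P, cout)
  col <- vol2col(x, k, stride, pad)
  dW <- crossprod(doutM, col)                      # (Cout x C*k^3)
  db <- colSums(doutM)
  dcol <- doutM %*% p$W                            # (P x C*k^3)
  dx <- col2vol(dcol, dim(x), k, stride, pad)
  list(dx = dx, dW = dW, db = db)
}

tconv_fwd <- function(y, p, k = 3L) {
  cin <- dim(y)[4]
  P <- prod(dim(y)[1:3])
  ymat <- matrix(y, P, cin)
  cout <- length(p$b)
  od <- dim(y)[1:3] * 2L
  x <- col2vol(ymat %*% p$W, c(od, cout), k, 2L, 1L)
  x + rep(p$b, each = prod(od))
}

tconv_bwd <- function(dx, y, p, k = 3L) {
  cin <- dim(y)[4]
  P <- prod(dim(y)[1:3])
  ymat <- matrix(y, P, cin)
  dcol <- vol2col(dx, k, 2L, 1L)                   # (P x Cout*k^3)
  dy <- tcrossprod(dcol, p$W)                      # (P x Cin)
  dim(dy) <- dim(y)
  dW <- crossprod(ymat, dcol)                      # (Cin x Cout*k^3)
  Pb <- prod(dim(dx)[1:3])
  db <- colSums(matrix(dx, Pb, dim(dx)[4]))
  list(dx = dy, dW = dW, db = db)
}

relu <- function(x) pmax(x, 0)

dropout_mask <- function(dims, rate) {
  keep <- 1 - rate
  array(stats::rbinom(prod(dims), 1L, keep) / keep, dim = dims)
}

# ---- forward / backward through the whole net ---------------------------

unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  k <- cfg$kernel
  m <- cfg$convs_per_block
  p <- model$params
  n <- dim(x)[1]
  if (n %% 2L^cfg$depth != 0)
    stop(sprintf("input side %d not divisible by 2^depth = %d", n, 2L^cfg$depth))
  x <- as_tensor(x)
  drop_on <- training && cfg$dropout_rate > 0
  cache <- list(input = x, blocks = list())
  cur <- x
  skips <- vector("list", cfg$depth)
  for (b in seq_len(cfg$depth)) {
    blk <- list(conv_in = list(), pre = list())
    for (j in seq_len(m)) {
      nm <- sprintf("enc%d_conv%d", b, j)
      blk$conv_in[[j]] <- cur
      pre <- conv_fwd(cur, p[[nm]], 1L, 1L, k)
      blk$pre[[j]] <- pre
      cur <- relu(pre)
    }
    if (drop_on) {
      blk$drop <- dropout_mask(dim(cur), cfg$dropout_rate)
      cur <- cur * blk$drop
    }
    skips[[b]] <- cur
    blk$down_in <- cur
    pre <- conv_fwd(cur, p[[sprintf("down%d", b)]], 2L, 1L, k)
    blk$down_pre <- pre
    cur <- relu(pre)
    cache$blocks[[sprintf("enc%d", b)]] <- blk
  }
  blk <- list(conv_in = list(), pre = list())
  for (j in seq_len(m)) {
    nm <- sprintf("bot_conv%d", j)
    blk$conv_in[[j]] <- cur
    pre <- conv_fwd(cur, p[[nm]], 1L, 1L, k)
    blk$pre[[j]] <- pre
    cur <- relu(pre)
  }
  if (drop_on) {
    blk$drop <- dropout_mask(dim(cur), cfg$dropout_rate)
    cur <- cur * blk$drop
  }
  cache$blocks[["bot"]] <- blk
  for (b in rev(seq_len(cfg$depth))) {
    blk <- list()
    blk$up_in <- cur
    pre <- tconv_fwd(cur, p[[sprintf("up%d", b)]], k)
    blk$up_pre <- pre
    up <- relu(pre)
    ch <- dim(up)[4]
    cur <- array(c(up, skips[[b]]), dim = c(dim(up)[1:3], 2L * ch))
    blk$conv_in <- list()
    blk$pre <- list()
    for (j in seq_len(m)) {
      nm <- sprintf("dec%d_conv%d", b, j)
      blk$conv_in[[j]] <- cur
      pre <- conv_fwd(cur, p[[nm]], 1L, 1L, k)
      blk$pre[[j]] <- pre
      cur <- relu(pre)
    }
    if (drop_on) {
      blk$drop <- dropout_mask(dim(cur), cfg$dropout_rate)
      cur <- cur * blk$drop
    }
    cache$blocks[[sprintf("dec%d", b)]] <- blk
  }
  cache$out_in <- cur
  out <- conv_fwd(cur, p[["out"]], 1L, 1L, k)
  list(out = out, cache = cache)
}

unet_backward <- function(model, cache, dout) {
  cfg <- model$cfg
  k <- cfg$kernel
  m <- cfg$convs_per_block
  p <- model$params
  g <- list()
  bk <- conv_bwd(dout, cache$out_in, p[["out"]], 1L, 1L, k)
  g[["out"]] <- list(W = bk$dW, b = bk$db)
  d <- bk$dx
  dskips <- vector("list", cfg$depth)
  for (b in seq_len(cfg$depth)) {   # decoder blocks, reverse of forward order
    blk <- cache$blocks[[sprintf("dec%d", b)]]
    if (!is.null(blk$drop)) d <- d * blk$drop
    for (j in rev(seq_len(m))) {
      nm <- sprintf("dec%d_conv%d", b, j)
      d <- d * (blk$pre[[j]] > 0)
      bk <- conv_bwd(d, blk$conv_in[[j]], p[[nm]], 1L, 1L, k)
      g[[nm]] <- list(W = bk$dW, b = bk$db)
      d <- bk$dx
    }
    ch <- dim(d)[4] / 2L
    sp <- prod(dim(d)[1:3])
    dmat <- matrix(d, sp, dim(d)[4])
    dup <- array(dmat[, seq_len(ch)], dim = c(dim(d)[1:3], ch))
    dskips[[b]] <- array(dmat[, ch + seq_len(ch)], dim = c(dim(d)[1:3], ch))
    dup <- dup * (blk$up_pre > 0)
    bk <- tconv_bwd(dup, blk$up_in, p[[sprintf("up%d", b)]], k)
    g[[sprintf("up%d", b)]] <- list(W = bk$dW, b = bk$db)
    d <- bk$dx
  }
  blk <- cache$blocks[["bot"]]
  if (!is.null(blk$drop)) d <- d * blk$drop
  for (j in rev(seq_len(m))) {
    nm <- sprintf("bot_conv%d", j)
    d <- d * (blk$pre[[j]] > 0)
    bk <- conv_bwd(d, blk$conv_in[[j]], p[[nm]], 1L, 1L, k)
    g[[nm]] <- list(W = bk$dW, b = bk$db)
    d <- bk$dx
  }
  for (b in rev(seq_len(cfg$depth))) {
    blk <- cache$blocks[[sprintf("enc%d", b)]]
    d <- d * (blk$down_pre > 0)
    bk <- conv_bwd(d, blk$down_in, p[[sprintf("down%d", b)]], 2L, 1L, k)
    g[[sprintf("down%d", b)]] <- list(W = bk$dW, b = bk$db)
    d <- bk$dx + dskips[[b]]
    if (!is.null(blk$drop)) d <- d * blk$drop
    for (j in rev(seq_len(m))) {
      nm <- sprintf("enc%d_conv%d", b, j)
      d <- d * (blk$pre[[j]] > 0)
      bk <- conv_bwd(d, blk$conv_in[[j]], p[[nm]], 1L, 1L, k)
      g[[nm]] <- list(W = bk$dW, b = bk$db)
      d <- bk$dx
    }
  }
  g
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)))
}

adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(model$adam)) model$adam <- adam_init(model$params)
  st <- model$adam
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    for (part in c("W", "b")) {
      gp <- grads[[nm]][[part]]
      st$m[[nm]][[part]] <- beta1 * st$m[[nm]][[part]] + (1 - beta1) * gp
      st$v[[nm]][[part]] <- beta2 * st$v[[nm]][[part]] + (1 - beta2) * gp^2
      model$params[[nm]][[part]] <- model$params[[nm]][[part]] -
        lr * (st$m[[nm]][[part]] / bc1) /
        (sqrt(st$v[[nm]][[part]] / bc2) + eps)
    }
  }
  model$adam <- st
  model
}

# ---- training and inference ---------------------------------------------

#' Train the network on a set of training pairs
#'
#' Minimises the mean absolute error between network output and target with
#' Adam.  Each epoch traverses the whole paired dataset once in a freshly
#' shuffled order; gradients are averaged within batches.  Training aborts
#' on a non-finite loss.
#'
#' @param model a `unet_model`.
#' @param pairs list of `training_pair` objects (see [make_training_pair]);
#'   pairs may carry an element `noisy_input` which is then used as the
#'   network input instead of `input` (targets are always the clean ones).
#' @param cfg a [train_config].
#' @return `list(model =, loss = <per-epoch mean MAE>)`.
#' @export
train_network <- function(model, pairs, cfg = train_config()) {
  stopifnot(inherits(model, "unet_model"), length(pairs) >= 1)
  losses <- numeric(cfg$epochs_per_iteration)
  with_seed(cfg$rng_seed, {
    for (ep in seq_len(cfg$epochs_per_iteration)) {
      ord <- sample.int(length(pairs))
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        grads <- NULL
        batch_loss <- 0
        for (i in idx) {
          xin <- pairs[[i]]$noisy_input
          if (is.null(xin)) xin <- pairs[[i]]$input
          fw <- unet_forward(model, xin, training = TRUE)
          target <- as_tensor(pairs[[i]]$target)
          resid <- fw$out - target
          batch_loss <- batch_loss + mean(abs(resid))
          dout <- array(sign(resid) / (length(resid) * length(idx)),
                        dim = dim(resid))
          gi <- unet_backward(model, fw$cache, dout)
          if (is.null(grads)) grads <- gi
          else for (nm in names(gi)) {
            grads[[nm]]$W <- grads[[nm]]$W + gi[[nm]]$W
            grads[[nm]]$b <- grads[[nm]]$b + gi[[nm]]$b
          }
        }
        batch_loss <- batch_loss / length(idx)
        if (!is.finite(batch_loss))
          stop(sprintf("non-finite training loss at epoch %d; aborting", ep))
        model <- adam_step(model, grads, cfg$learning_rate)
        ep_loss <- ep_loss + batch_loss
        nb <- nb + 1
      }
      losses[ep] <- ep_loss / nb
    }
  })
  list(model = model, loss = losses)
}

#' Apply a model to one cube
#'
#' Inference pass: dropout disabled, deterministic for fixed weights.  The
#' generic also accepts a plain function (useful as a contrived model, e.g.
#' the identity) so downstream machinery can be tested independently of
#' training.
#'
#' @param model a `unet_model`, or a function taking and returning a cube.
#' @param cube 3D array whose side is divisible by `2^depth`.
#' @return 3D array of the same shape.
#' @export
predict_cube <- function(model, cube) UseMethod("predict_cube")

#' @export
predict_cube.unet_model <- function(model, cube) {
  out <- unet_forward(model, as_volume(cube), training = FALSE)$out
  array(out, dim = dim(out)[1:3])
}

#' @export
predict_cube.function <- function(model, cube) {
  out <- model(as_volume(cube))
  stopifnot(identical(dim(out)[1:3], dim(as_volume(cube))[1:3]))
  as_volume(out)
}
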