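# Residual 3D regression network: two-channel voxel image in, per-voxel
# ion probability grid out. The architecture is an input 3x3x3 convolution,
# a stack of residual blocks (two 3x3x3 convolutions with an identity
# shortcut each), and a 1-channel output convolution followed by a sigmoid.
# Stride is 1 everywhere, so the spatial shape is preserved and the network
# accepts any grid size at inference. Convolutions run in compiled code
# (im2col + BLAS); the training loop, Adam optimizer and backpropagation
# live here.

#' Network / training configuration
#'
#' @param n_blocks number of residual blocks (`>= 1`).
#' @param base_channels feature channels per convolution (`>= 1`).
#' @param loss `"mse"` (default) on the Gaussian label, or `"bce"`.
#' @param pos_weight per-voxel loss weight multiplier applied as
#'   `1 + pos_weight * label`: binding voxels are a tiny fraction of a
#'   grid, and without upweighting them the constant-zero prediction is a
#'   near-optimal (and attracting) solution.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size (gradients averaged per batch).
#' @param seed integer seed controlling initialization and shuffling.
#' @return a list of class `model_config`.
#' @export
model_config <- function(n_blocks = 4, base_channels = 16, loss = "mse",
                         pos_weight = 30, lr = 1e-3, epochs = 30,
                         batch_size = 8, seed = 1) {
  stopifnot(n_blocks >= 1, base_channels >= 1, pos_weight >= 0)
  loss <- match.arg(loss, c("mse", "bce"))
  structure(list(n_blocks = n_blocks, base_channels = base_channels,
                 kernel = 3, loss = loss, pos_weight = pos_weight, lr = lr,
                 epochs = epochs, batch_size = batch_size, seed = seed),
            class = "model_config")
}

.he_init <- function(fan_in, n_out) {
  matrix(rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
}

#' Build an (untrained) model
#'
#' Two builds with the same `cfg$seed` have identical initial parameters.
#'
#' @param cfg a [model_config()].
#' @return an object of class `mg_model`.
#' @export
build_model <- function(cfg = model_config()) {
  if (!inherits(cfg, "model_config")) stop("cfg must be a model_config")
  set.seed(cfg$seed)
  C <- cfg$base_channels
  params <- list(Win = .he_init(27 * 2, C), bin = numeric(C))
  for (b in seq_len(cfg$n_blocks)) {
    params[[paste0("W1_", b)]] <- .he_init(27 * C, C)
    params[[paste0("b1_", b)]] <- numeric(C)
    params[[paste0("W2_", b)]] <- .he_init(27 * C, C)
    params[[paste0("b2_", b)]] <- numeric(C)
  }
  params$Wout <- .he_init(27 * C, 1)
  params$bout <- -2 # start predictions near 0.1, away from saturation
  structure(list(cfg = cfg, params = params, history = numeric(0)),
            class = "mg_model")
}

#' @export
print.mg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat("mg_model: ", x$cfg$n_blocks, " residual blocks, ",
      x$cfg$base_channels, " channels, ", np, " parameters, ",
      length(x$history), " training epochs recorded\n", sep = "")
  invisible(x)
}

.lrelu_slope <- 0.1 # leaky ReLU: keeps gradients alive in sparse volumes
.relu <- function(x) ifelse(x > 0, x, .lrelu_slope * x)

# forward pass; x is (V, 2), dims c(n, n, n). Returns p and, optionally,
# the cache of layer inputs needed by the backward pass.
.net_forward <- function(model, x, dims, keep_cache = FALSE) {
  pr <- model$params
  nb <- model$cfg$n_blocks
  cache <- if (keep_cache) list(x = x, h = vector("list", nb + 1),
                                u = vector("list", nb)) else NULL
  h <- .relu(cpp_conv3d_fw(x, pr$Win, pr$bin, dims))
  if (keep_cache) cache$h[[1]] <- h
  for (b in seq_len(nb)) {
    u <- .relu(cpp_conv3d_fw(h, pr[[paste0("W1_", b)]],
                             pr[[paste0("b1_", b)]], dims))
    v <- cpp_conv3d_fw(u, pr[[paste0("W2_", b)]], pr[[paste0("b2_", b)]],
                       dims)
    h <- .relu(h + v)
    if (keep_cache) { cache$u[[b]] <- u; cache$h[[b + 1]] <- h }
  }
  z <- cpp_conv3d_fw(h, pr$Wout, pr$bout, dims)
  p <- 1 / (1 + exp(-z))
  list(p = p, cache = cache)
}

# backward pass from dL/dp (gp); returns parameter gradients and dL/dx
.net_backward <- function(model, fw, gp, dims, gz = NULL) {
  pr <- model$params
  nb <- model$cfg$n_blocks
  cache <- fw$cache
  p <- fw$p
  if (is.null(gz)) gz <- gp * p * (1 - p)
  g <- list()
  bw <- cpp_conv3d_bw(cache$h[[nb + 1]], pr$Wout, gz, dims)
  g$Wout <- bw$gW; g$bout <- bw$gb
  gh <- bw$gx
  for (b in rev(seq_len(nb))) {
    hin <- cache$h[[b]]; hout <- cache$h[[b + 1]]; u <- cache$u[[b]]
    gh <- gh * ifelse(hout > 0, 1, .lrelu_slope)
    bw2 <- cpp_conv3d_bw(u, pr[[paste0("W2_", b)]], gh, dims)
    g[[paste0("W2_", b)]] <- bw2$gW; g[[paste0("b2_", b)]] <- bw2$gb
    ga1 <- bw2$gx * ifelse(u > 0, 1, .lrelu_slope)
    bw1 <- cpp_conv3d_bw(hin, pr[[paste0("W1_", b)]], ga1, dims)
    g[[paste0("W1_", b)]] <- bw1$gW; g[[paste0("b1_", b)]] <- bw1$gb
    gh <- gh + bw1$gx
  }
  ga0 <- gh * ifelse(cache$h[[1]] > 0, 1, .lrelu_slope)
  bw0 <- cpp_conv3d_bw(cache$x, pr$Win, ga0, dims)
  g$Win <- bw0$gW; g$bin <- bw0$gb
  g$gx <- bw0$gx
  g
}

.loss_grad <- function(p, y, loss, pos_weight = 0) {
  V <- length(p)
  w <- 1 + pos_weight * y
  if (loss == "mse") {
    list(loss = mean(w * (p - y)^2), gp = 2 * w * (p - y) / V, gz = NULL)
  } else {
    eps <- 1e-12
    list(loss = -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))),
         gp = NULL, gz = w * (p - y) / V)
  }
}

#' Train the network
#'
#' All randomness (shuffling) derives from `cfg$seed`; two runs with the
#' same seed and data give bitwise-identical models. Training aborts with
#' a diagnostic if the loss becomes non-finite.
#'
#' @param model an `mg_model` from [build_model()].
#' @param images list of `voxel_image`.
#' @param labels list of `probability_grid` (same length and geometry).
#' @param cfg optional [model_config()] overriding the model's training
#'   settings (epochs, lr, batch size, loss, seed).
#' @param verbose print per-epoch loss.
#' @return the trained `mg_model` with a per-epoch `history`.
#' @export
train_model <- function(model, images, labels, cfg = model$cfg,
                        verbose = FALSE) {
  if (!length(images)) stop("empty training set")
  if (length(images) != length(labels))
    stop("images and labels differ in length")
  n <- images[[1]]$n
  dims <- c(n, n, n)
  xs <- lapply(images, .image_matrix)
  ys <- lapply(labels, function(l) as.numeric(l$values))
  set.seed(cfg$seed + 1L)
  adam <- list(m = lapply(model$params, function(p) p * 0),
               v = lapply(model$params, function(p) p * 0), t = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(xs))
    ep_loss <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      acc <- NULL
      for (i in idx) {
        fw <- .net_forward(model, xs[[i]], dims, keep_cache = TRUE)
        lg <- .loss_grad(as.numeric(fw$p), ys[[i]], cfg$loss,
                         cfg$pos_weight)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", ep,
               "; lower the learning rate")
        ep_loss <- ep_loss + lg$loss
        gp <- if (is.null(lg$gp)) NULL else matrix(lg$gp, ncol = 1)
        gz <- if (is.null(lg$gz)) NULL else matrix(lg$gz, ncol = 1)
        g <- .net_backward(model, fw, gp, dims, gz = gz)
        g$gx <- NULL
        if (is.null(acc)) acc <- g
        else for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
      }
      adam$t <- adam$t + 1
      for (nm in names(model$params)) {
        gr <- acc[[nm]] / length(idx)
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * gr
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * gr^2
        mhat <- adam$m[[nm]] / (1 - b1^adam$t)
        vhat <- adam$v[[nm]] / (1 - b2^adam$t)
        model$params[[nm]] <- model$params[[nm]] -
          cfg$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    hist[ep] <- ep_loss / length(xs)
    if (verbose) message("epoch ", ep, "  loss ", signif(hist[ep], 4))
  }
  model$history <- c(model$history, hist)
  model$cfg <- cfg
  model
}

#' Predict the ion probability grid for one image
#'
#' @param model a trained `mg_model`.
#' @param image a `voxel_image`.
#' @return a `probability_grid` with the image's geometry; values in
#'   `[0, 1]`.
#' @export
predict_grid <- function(model, image) {
  if (!inherits(image, "voxel_image")) stop("image must be a voxel_image")
  n <- image$n
  fw <- .net_forward(model, .image_matrix(image), c(n, n, n))
  structure(list(origin = image$origin, spacing = image$spacing, n = n,
                 values = array(as.numeric(fw$p), c(n, n, n))),
            class = "probability_grid")
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the parameters, the config snapshot and the seed.
#'
#' @param model an `mg_model`.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "mg_model")) stop("not a voxmg model checkpoint: ", path)
  m
}
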