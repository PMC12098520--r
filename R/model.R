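# The residual channel-attention feature extractor, gradient reversal layer,
# stage classifier head and subject-domain discriminator head.
#
# Architecture (reference configuration):
#   input (128, 128, 10)
#   encoder: 4 stages, each a stride-2 projection residual block followed by
#     a stride-1 standard residual block; widths 64 -> 128 -> 256 -> 256;
#     every block recalibrates its convolution output with a
#     squeeze-and-excitation (SE) channel-attention module
#     -> (8, 8, 256)
#   decoder: two nearest x2 upsampling stages with skip concatenation from
#     the equal-resolution encoder stage and a 1x1 fusion convolution
#     -> (32, 32, 256), collapsed by a height mean to a (32, 256) sequence
#   Bi-GRU, hidden 128 per direction -> (32, 256)
#   heads: three fully connected layers on the flattened sequence;
#     stage head ends in softmax over 5 stages, domain head (behind the
#     gradient reversal layer) in softmax over the training-subject count.

#' Model configuration
#'
#' @param input_size Side length of the model input; the preprocessed
#'   128 x 128 tensors are average-pooled down when `input_size < 128`
#'   (desk-scale profiles).  Must divide 128 and be a multiple of 16
#'   (four stride-2 stages plus two upsampling stages).
#' @param in_channels Input channel count (10 for the PSG montage).
#' @param widths Encoder stage widths, length 4.
#' @param gru_hidden GRU hidden size per direction.
#' @param head_hidden Hidden widths of the two intermediate fully connected
#'   layers in each head, length 2.
#' @param n_classes Number of sleep stages (5).
#' @param n_domains Number of training subjects (domain classes); may be set
#'   later per fold.
#' @param lambda Adversarial weight on the domain loss (>= 0).
#' @param lambda_schedule `"constant"` or `"dann_ramp"`
#'   (`2/(1 + exp(-10 p)) - 1` over training progress `p`).
#' @param use_se Keep the SE channel-attention recalibration (ablation flag).
#' @param use_discriminator Keep the adversarial domain branch (ablation
#'   flag); when `FALSE` no discriminator parameters exist at all.
#' @param seed Seed for weight initialization.
#' @return Object of class `model_config`.
#' @export
model_config <- function(input_size = 128L, in_channels = 10L,
                         widths = c(64L, 128L, 256L, 256L),
                         gru_hidden = 128L, head_hidden = c(128L, 64L),
                         n_classes = 5L, n_domains = 9L,
                         lambda = 1.0,
                         lambda_schedule = c("constant", "dann_ramp"),
                         use_se = TRUE, use_discriminator = TRUE,
                         seed = 1L) {
  lambda_schedule <- match.arg(lambda_schedule)
  stopifnot(length(widths) == 4, lambda >= 0, n_classes >= 2,
            input_size %% 16 == 0, 128 %% input_size == 0,
            length(head_hidden) == 2)
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 widths = as.integer(widths),
                 gru_hidden = as.integer(gru_hidden),
                 head_hidden = as.integer(head_hidden),
                 n_classes = as.integer(n_classes),
                 n_domains = as.integer(n_domains),
                 lambda = lambda, lambda_schedule = lambda_schedule,
                 use_se = isTRUE(use_se),
                 use_discriminator = isTRUE(use_discriminator),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Desk-scale model configuration
#'
#' A reduced profile for CPU experiments: 32 x 32 pooled input, narrow
#' stages, small GRU and heads. Same architecture, same contracts.
#'
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
model_config_desk <- function(...) {
  args <- list(...)
  defaults <- list(input_size = 32L, widths = c(8L, 16L, 16L, 16L),
                   gru_hidden = 16L, head_hidden = c(32L, 16L))
  do.call(model_config, modifyList(defaults, args))
}

se_reduction <- function(C) max(C %/% 16L, 1L)

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

init_conv <- function(k, cin, cout) {
  list(W = glorot(c(k, k, cin, cout), k * k * cin, k * k * cout),
       b = numeric(cout))
}

init_se <- function(C) {
  Cr <- se_reduction(C)
  list(W1 = glorot(c(Cr, C), C, Cr), b1 = numeric(Cr),
       W2 = glorot(c(C, Cr), Cr, C), b2 = numeric(C))
}

init_gru_dir <- function(D, H) {
  mk <- function(r, c) glorot(c(r, c), c, r)
  list(Wz = mk(H, D), Uz = mk(H, H), bz = numeric(H),
       Wr = mk(H, D), Ur = mk(H, H), br = numeric(H),
       Wn = mk(H, D), Un = mk(H, H), bn = numeric(H))
}

init_head <- function(d_in, hidden, d_out) {
  list(fc1 = list(W = glorot(c(hidden[1], d_in), d_in, hidden[1]),
                  b = numeric(hidden[1])),
       fc2 = list(W = glorot(c(hidden[2], hidden[1]), hidden[1], hidden[2]),
                  b = numeric(hidden[2])),
       fc3 = list(W = glorot(c(d_out, hidden[2]), hidden[2], d_out),
                  b = numeric(d_out)))
}

#' Initialize all model parameters
#'
#' Glorot-uniform weights, zero biases, drawn from the configuration seed.
#' With `use_discriminator = FALSE` the returned set contains no
#' discriminator parameters at all.
#'
#' @param config A [model_config()].
#' @return Nested parameter list of class `model_params`.
#' @export
init_model_params <- function(config) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  w <- config$widths
  cin <- c(config$in_channels, w[1], w[2], w[3])
  enc <- vector("list", 4)
  for (k in 1:4) {
    blk <- list(
      proj = list(conv = init_conv(3, cin[k], w[k]),
                  se = if (config$use_se) init_se(w[k]),
                  short = init_conv(1, cin[k], w[k])),
      std = list(conv = init_conv(3, w[k], w[k]),
                 se = if (config$use_se) init_se(w[k])))
    enc[[k]] <- blk
  }
  names(enc) <- paste0("stage", 1:4)
  Cf <- w[4]
  dec <- list(fuse1 = init_conv(1, w[4] + w[3], Cf),
              fuse2 = init_conv(1, Cf + w[2], Cf))
  gru <- list(fwd = init_gru_dir(Cf, config$gru_hidden),
              bwd = init_gru_dir(Cf, config$gru_hidden))
  seq_len_steps <- config$input_size %/% 4L
  d_feat <- seq_len_steps * 2L * config$gru_hidden
  params <- list(enc = enc, dec = dec, gru = gru,
                 label = init_head(d_feat, config$head_hidden,
                                   config$n_classes))
  if (config$use_discriminator)
    params$domain <- init_head(d_feat, config$head_hidden, config$n_domains)
  structure(params, class = "model_params")
}

#' Squeeze-and-excitation channel recalibration
#'
#' Squeeze: global average pool of each channel, `z_c = mean(o[, , c])`.
#' Excitation: `s = sigmoid(W2 relu(W1 z + b1) + b2)`, a per-channel weight
#' strictly in (0, 1). Scale: `out[, , c] = s_c * o[, , c]`.
#'
#' @param o Feature map `(H, W, C)`.
#' @param p SE parameters (`W1 (C/r x C)`, `b1`, `W2 (C x C/r)`, `b2`).
#' @return List with `out`, `z`, `s` and backward `cache`.
#' @export
se_forward <- function(o, p) {
  d <- dim(o)
  if (ncol(p$W1) != d[3] || nrow(p$W2) != d[3])
    stop("SE weight shapes do not match channel count ", d[3])
  z <- colMeans(matrix(o, ncol = d[3]))
  a <- relu(drop(p$W1 %*% z) + p$b1)
  s <- sigmoid(drop(p$W2 %*% a) + p$b2)
  out <- o * rep(s, each = d[1] * d[2])
  list(out = out, z = z, s = s,
       cache = list(o = o, z = z, a = a, s = s, p = p, d = d))
}

se_backward <- function(dout, cache) {
  d <- cache$d; p <- cache$p
  HW <- d[1] * d[2]
  ds <- colSums(matrix(dout * cache$o, ncol = d[3]))
  dx <- dout * rep(cache$s, each = HW)
  dpre2 <- ds * cache$s * (1 - cache$s)
  dW2 <- tcrossprod(dpre2, cache$a)
  db2 <- dpre2
  da <- drop(crossprod(p$W2, dpre2))
  dpre1 <- da * (cache$a > 0)
  dW1 <- tcrossprod(dpre1, cache$z)
  db1 <- dpre1
  dz <- drop(crossprod(p$W1, dpre1))
  dx <- dx + rep(dz / HW, each = HW)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Residual channel-attention block
#'
#' `out = relu(SE(conv(x)) + shortcut(x))`. The standard variant uses an
#' identity shortcut (channel counts must match); the projection variant a
#' 1x1 strided convolution. With `use_se = FALSE` the SE recalibration is
#' skipped (channel-attention ablation).
#'
#' @param x Input feature map.
#' @param p Block parameters (`conv`, optional `se`, optional `short`).
#' @param variant `"standard"` or `"projection"`.
#' @param stride Convolution stride.
#' @param use_se Apply the SE recalibration.
#' @return List with `out` and backward `cache`.
#' @export
res_cab_forward <- function(x, p, variant = c("standard", "projection"),
                            stride = 1L, use_se = TRUE) {
  variant <- match.arg(variant)
  cf <- conv2d_forward(x, p$conv$W, p$conv$b, stride = stride, pad = 1L)
  se <- if (use_se) se_forward(cf$out, p$se)
  o_tilde <- if (use_se) se$out else cf$out
  if (variant == "standard") {
    if (dim(x)[3] != dim(o_tilde)[3] || stride != 1L)
      stop("standard residual block needs matching channels and stride 1; ",
           "use the projection variant")
    short <- x
    short_cache <- NULL
  } else {
    sf <- conv2d_forward(x, p$short$W, p$short$b, stride = stride, pad = 0L)
    short <- sf$out
    short_cache <- sf$cache
  }
  pre <- o_tilde + short
  list(out = relu(pre),
       cache = list(conv = cf$cache, se = if (use_se) se$cache,
                    short = short_cache, pre = pre, variant = variant,
                    use_se = use_se))
}

res_cab_backward <- function(dout, cache) {
  dpre <- dout * (cache$pre > 0)
  grads <- list()
  if (cache$variant == "projection") {
    sb <- conv2d_backward(dpre, cache$short)
    grads$short <- list(W = sb$dW, b = sb$db)
    dx <- sb$dx
  } else {
    dx <- dpre
  }
  d_conv_out <- dpre
  if (cache$use_se) {
    seb <- se_backward(dpre, cache$se)
    grads$se <- seb$grads
    d_conv_out <- seb$dx
  }
  cb <- conv2d_backward(d_conv_out, cache$conv)
  grads$conv <- list(W = cb$dW, b = cb$db)
  list(dx = dx + cb$dx, grads = grads)
}

# average-pool the (128,128,C) preprocessed tensor down to the model input
# size; identity when they already match
pool_input <- function(x, input_size) {
  d <- dim(x)
  if (d[1] == input_size) return(x)
  f <- d[1] %/% input_size
  out <- array(0, dim = c(input_size, input_size, d[3]))
  for (a in seq_len(f))
    for (b in seq_len(f))
      out <- out + x[seq(a, d[1], by = f), seq(b, d[2], by = f), ,
                     drop = FALSE]
  out / f^2
}

#' Feature extractor forward pass
#'
#' Encoder (4 residual stages, stride 2 each), U-style decoder (two x2
#' upsamplings with skip concatenation and 1x1 fusion), height-mean collapse
#' to a sequence, then a bidirectional GRU. For the reference configuration
#' the shapes are (128,128,10) -> (8,8,256) -> (32,256).
#'
#' @param x Input tensor, `(128, 128, in_channels)` (pooled internally when
#'   `config$input_size < 128`) or already `(input_size, input_size, C)`.
#' @param params [init_model_params()] output.
#' @param config [model_config()].
#' @param keep_cache Keep intermediate activations for the backward pass.
#' @return List with `feat` (the `(T, 2 * gru_hidden)` feature sequence),
#'   `encoder_out` shape, and `cache` when requested.
#' @export
feature_extract <- function(x, params, config, keep_cache = FALSE) {
  d <- dim(x)
  if (length(d) != 3 || d[1] != d[2] || d[3] != config$in_channels)
    stop("expected a square (S, S, ", config$in_channels, ") input, got ",
         paste(d, collapse = " x "))
  x <- pool_input(x, config$input_size)
  if (any(!is.finite(x))) stop("non-finite values in model input")
  stages <- vector("list", 4)
  caches <- list(enc = vector("list", 4))
  h <- x
  for (k in 1:4) {
    pr <- res_cab_forward(h, params$enc[[k]]$proj, "projection", stride = 2L,
                          use_se = config$use_se)
    st <- res_cab_forward(pr$out, params$enc[[k]]$std, "standard",
                          stride = 1L, use_se = config$use_se)
    if (any(!is.finite(st$out)))
      stop("non-finite activations in encoder stage ", k)
    stages[[k]] <- st$out
    caches$enc[[k]] <- list(proj = pr$cache, std = st$cache)
    h <- st$out
  }
  enc_out <- stages[[4]]

  u1 <- upsample2_forward(enc_out)
  cat1 <- array(c(u1, stages[[3]]),
                dim = c(dim(u1)[1], dim(u1)[2], dim(u1)[3] + dim(stages[[3]])[3]))
  f1 <- conv2d_forward(cat1, params$dec$fuse1$W, params$dec$fuse1$b,
                       stride = 1L, pad = 0L)
  r1 <- relu(f1$out)
  u2 <- upsample2_forward(r1)
  cat2 <- array(c(u2, stages[[2]]),
                dim = c(dim(u2)[1], dim(u2)[2], dim(u2)[3] + dim(stages[[2]])[3]))
  f2 <- conv2d_forward(cat2, params$dec$fuse2$W, params$dec$fuse2$b,
                       stride = 1L, pad = 0L)
  r2 <- relu(f2$out)
  hm <- hmean_forward(r2)
  bg <- bigru_forward(hm$out, params$gru$fwd, params$gru$bwd)

  caches$dec <- list(dim_enc = dim(enc_out), dim_u1 = dim(u1),
                     c3 = dim(stages[[3]])[3], c2 = dim(stages[[2]])[3],
                     f1 = f1$cache, pre1 = f1$out, dim_r1 = dim(r1),
                     f2 = f2$cache, pre2 = f2$out, hm_dim = hm$dimx)
  caches$gru <- bg
  out <- list(feat = bg$out, encoder_shape = dim(enc_out))
  if (keep_cache) out$cache <- caches
  out
}

# backward through decoder + encoder given d(feature sequence)
feature_extract_backward <- function(dfeat, cache, config) {
  gb <- bigru_backward(dfeat, cache$gru)
  dc <- cache$dec
  dr2 <- hmean_backward(gb$dX, dc$hm_dim)
  dpre2 <- dr2 * (dc$pre2 > 0)
  f2b <- conv2d_backward(dpre2, dc$f2)
  # split the concat gradients: leading channels came from the upsample,
  # the rest from the skip-connected encoder stage
  n_up2 <- dim(f2b$dx)[3] - dc$c2
  du2 <- f2b$dx[, , seq_len(n_up2), drop = FALSE]
  dskip2 <- f2b$dx[, , (n_up2 + 1):dim(f2b$dx)[3], drop = FALSE]
  dr1 <- upsample2_backward(du2, dc$dim_r1)
  dpre1 <- dr1 * (dc$pre1 > 0)
  f1b <- conv2d_backward(dpre1, dc$f1)
  n_up1 <- dim(f1b$dx)[3] - dc$c3
  du1 <- f1b$dx[, , seq_len(n_up1), drop = FALSE]
  dskip3 <- f1b$dx[, , (n_up1 + 1):dim(f1b$dx)[3], drop = FALSE]
  denc4 <- upsample2_backward(du1, dc$dim_enc)

  grads <- list(enc = vector("list", 4),
                dec = list(fuse1 = list(W = f1b$dW, b = f1b$db),
                           fuse2 = list(W = f2b$dW, b = f2b$db)),
                gru = list(fwd = gb$grads_fwd, bwd = gb$grads_bwd))
  names(grads$enc) <- paste0("stage", 1:4)
  dstage <- list(NULL, dskip2, dskip3, denc4)
  dnext <- NULL
  for (k in 4:1) {
    dout_k <- dstage[[k]] %||% 0
    if (!is.null(dnext)) dout_k <- dout_k + dnext
    sb <- res_cab_backward(dout_k, cache$enc[[k]]$std)
    pb <- res_cab_backward(sb$dx, cache$enc[[k]]$proj)
    grads$enc[[k]] <- list(proj = pb$grads, std = sb$grads)
    dnext <- pb$dx
  }
  grads
}

#' Gradient reversal layer
#'
#' Forward: identity. Backward: multiplies the gradient flowing to its input
#' by `-lambda`, so the feature extractor ascends the domain loss the
#' discriminator descends. `lambda = 0` detaches the adversarial signal.
#'
#' @param x Any numeric array.
#' @param lambda Non-negative reversal weight.
#' @return `x`, with the lambda recorded as an attribute for the paired
#'   backward call.
#' @export
grl_forward <- function(x, lambda) {
  stopifnot(lambda >= 0)
  structure(x, grl_lambda = lambda)
}

#' Backward pass of the gradient reversal layer
#'
#' @param dout Gradient arriving from the discriminator side.
#' @param lambda The reversal weight used in the forward pass.
#' @return `-lambda * dout`.
#' @export
grl_backward <- function(dout, lambda) {
  stopifnot(lambda >= 0)
  -lambda * dout
}

# flatten a (T, D) feature sequence step-major (as.vector of the matrix:
# step index varies fastest)
flatten_feat <- function(feat) as.vector(feat)

head_forward <- function(feat_vec, hp) {
  f1 <- dense_forward(feat_vec, hp$fc1$W, hp$fc1$b, "relu")
  f2 <- dense_forward(f1$out, hp$fc2$W, hp$fc2$b, "relu")
  f3 <- dense_forward(f2$out, hp$fc3$W, hp$fc3$b, "linear")
  list(probs = softmax(f3$out), logits = f3$out,
       cache = list(f1 = f1$cache, f2 = f2$cache, f3 = f3$cache))
}

# backward from d(logits); returns d(feat_vec) and head grads
head_backward <- function(dlogits, cache) {
  b3 <- dense_backward(dlogits, cache$f3)
  b2 <- dense_backward(b3$dx, cache$f2)
  b1 <- dense_backward(b2$dx, cache$f1)
  list(dx = b1$dx,
       grads = list(fc1 = list(W = b1$dW, b = b1$db),
                    fc2 = list(W = b2$dW, b = b2$db),
                    fc3 = list(W = b3$dW, b = b3$db)))
}

#' Stage probabilities for one epoch tensor
#'
#' @param feat Feature sequence from [feature_extract()], or a flattened
#'   feature vector.
#' @param params Model parameters.
#' @return Probability vector over the five stages (sums to 1).
#' @export
label_predict <- function(feat, params) {
  head_forward(flatten_feat(feat), params$label)$probs
}

#' Domain probabilities for one epoch tensor
#'
#' @param feat Feature sequence or flattened feature vector.
#' @param params Model parameters (must contain a discriminator head).
#' @return Probability vector over the training domains (sums to 1).
#' @export
domain_predict <- function(feat, params) {
  if (is.null(params$domain))
    stop("model has no domain discriminator (use_discriminator = FALSE)")
  head_forward(flatten_feat(feat), params$domain)$probs
}

#' Predict stage labels for a list of epochs
#'
#' @param epochs List of `spectrogram_epoch` (or bare tensors).
#' @param params Model parameters.
#' @param config Model configuration.
#' @return Integer vector of 0-based stage labels.
#' @export
predict_stages <- function(epochs, params, config) {
  vapply(epochs, function(e) {
    tn <- if (is.list(e)) e$tensor else e
    fe <- feature_extract(tn, params, config)
    which.max(label_predict(fe$feat, params)) - 1L
  }, integer(1))
}

#' Save a model checkpoint
#'
#' Weights in an RDS container plus a JSON manifest (config, shapes, seed)
#' next to it.
#'
#' @param params Model parameters.
#' @param config Model configuration.
#' @param path Checkpoint path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, config, path) {
  saveRDS(list(params = params, config = unclass(config)), path)
  manifest <- list(config = unclass(config),
                   n_parameters = count_params(params),
                   format = "adgsleep-checkpoint-v1")
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path written by [save_checkpoint()].
#' @return List with `params` and `config`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  ck$config <- structure(ck$config, class = "model_config")
  ck
}

#' Count trainable parameters
#' @param params Nested parameter list.
#' @return Total number of scalar parameters.
#' @export
count_params <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}
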