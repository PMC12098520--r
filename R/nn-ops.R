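# Differentiable primitives: 2-D convolution (im2col + BLAS gemm), dense
# layers, GRU recurrence, nearest-neighbour upsampling, channel concat and
# height-mean collapse.  Every forward returns the cache its backward needs;
# every backward is checked against finite differences in the test suite.
# Feature maps are (H, W, C) arrays; sequences are (T, D) matrices.

.conv_cache <- new.env(parent = emptyenv())

# im2col gather index for a zero-padded input, memoised per geometry.
# Returns list(idx = (Ho*Wo) x (k*k*Cin) index matrix into the flattened
# padded array, Hp, Wp, Ho, Wo).
conv_geometry <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  g <- .conv_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  i0 <- (seq_len(Ho) - 1L) * stride          # top row of each patch (0-based)
  j0 <- (seq_len(Wo) - 1L) * stride
  ki <- 0:(k - 1L); kj <- 0:(k - 1L); cc <- 0:(C - 1L)
  # idx[oi, oj, ki, kj, c] = (i0+ki) + (j0+kj)*Hp + c*Hp*Wp + 1, column-major
  a <- outer(i0, ki, "+")                    # Ho x k
  b <- outer(j0, kj, "+") * Hp               # Wo x k
  idx <- array(0L, dim = c(Ho, Wo, k, k, C))
  for (ci in seq_along(cc))
    for (j2 in seq_len(k))
      for (i2 in seq_len(k))
        idx[, , i2, j2, ci] <- outer(a[, i2], b[, j2], "+") +
          cc[ci] * Hp * Wp + 1L
  g <- list(idx = matrix(as.integer(idx), nrow = Ho * Wo), Hp = Hp, Wp = Wp,
            Ho = Ho, Wo = Wo, i0 = i0, j0 = j0, k = k, C = C,
            stride = stride)
  .conv_cache[[key]] <- g
  g
}

pad_input <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), ] <- x
  xp
}

#' 2-D convolution forward pass
#'
#' "Same"-style zero padding for 3x3 kernels (`pad = 1`), none for 1x1
#' projection shortcuts. Weights are a `(k, k, Cin, Cout)` array.
#'
#' @param x Input `(H, W, Cin)` array.
#' @param W Kernel array `(k, k, Cin, Cout)`.
#' @param b Bias vector, length `Cout`.
#' @param stride Stride (1 or 2 in this architecture).
#' @param pad Zero-padding width.
#' @return List with `out` (`(Ho, Wo, Cout)`) and the backward `cache`.
#' @keywords internal
conv2d_forward <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x); dw <- dim(W)
  stopifnot(d[3] == dw[3])
  g <- conv_geometry(d[1], d[2], d[3], dw[1], stride, pad)
  xp <- pad_input(x, pad)
  cols <- matrix(xp[g$idx], nrow = nrow(g$idx))       # (Ho*Wo) x (k*k*Cin)
  Wm <- matrix(W, ncol = dw[4])                       # (k*k*Cin) x Cout
  out <- cols %*% Wm
  out <- sweep(out, 2, b, "+")
  list(out = array(out, dim = c(g$Ho, g$Wo, dw[4])),
       cache = list(cols = cols, g = g, dimx = d, dimW = dw,
                    stride = stride, pad = pad, W = W))
}

#' 2-D convolution backward pass
#' @param dout Gradient w.r.t. the convolution output.
#' @param cache Cache from [conv2d_forward()].
#' @return List with `dx`, `dW`, `db`.
#' @keywords internal
conv2d_backward <- function(dout, cache) {
  g <- cache$g; dw <- cache$dimW; d <- cache$dimx
  dmat <- matrix(dout, nrow = g$Ho * g$Wo)            # (Ho*Wo) x Cout
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, matrix(cache$W, ncol = dw[4]))
  # col2im: within one (ki, kj) kernel offset the strided target cells are
  # distinct, so the scatter-add is 9 plain vectorized additions
  dc <- array(dcols, dim = c(g$Ho, g$Wo, g$k, g$k, g$C))
  dxp <- array(0, dim = c(g$Hp, g$Wp, d[3]))
  for (kj in seq_len(g$k)) {
    jj <- g$j0 + kj
    for (ki in seq_len(g$k)) {
      ii <- g$i0 + ki
      dxp[ii, jj, ] <- dxp[ii, jj, ] + dc[, , ki, kj, ]
    }
  }
  p <- cache$pad
  dx <- if (p > 0) dxp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , drop = FALSE]
        else dxp
  list(dx = dx, dW = array(dW, dim = dw), db = db)
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(logits) {
  if (any(!is.finite(logits))) stop("non-finite logits")
  e <- exp(logits - max(logits))
  e / sum(e)
}

dense_forward <- function(x, W, b, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  pre <- drop(W %*% x) + b
  out <- if (activation == "relu") relu(pre) else pre
  list(out = out, cache = list(x = x, W = W, pre = pre,
                               activation = activation))
}

dense_backward <- function(dout, cache) {
  dpre <- if (cache$activation == "relu") dout * (cache$pre > 0) else dout
  list(dx = drop(crossprod(cache$W, dpre)),
       dW = tcrossprod(dpre, cache$x), db = dpre)
}

# nearest-neighbour x2 upsampling
upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_backward <- function(dout, dimx) {
  d <- dimx
  i <- rep(seq_len(d[1]), each = 2)
  j <- rep(seq_len(d[2]), each = 2)
  dx <- array(0, dim = d)
  # sum the 2x2 fan-out back into each source cell
  for (a in 0:1)
    for (b in 0:1)
      dx <- dx + dout[seq(1 + a, 2 * d[1], by = 2),
                      seq(1 + b, 2 * d[2], by = 2), , drop = FALSE]
  dx
}

# mean over the height axis: (H, W, C) -> (W, C) sequence of W steps
hmean_forward <- function(x) {
  d <- dim(x)
  out <- matrix(colMeans(matrix(x, nrow = d[1])), d[2], d[3])
  list(out = out, dimx = d)
}

hmean_backward <- function(dout, dimx) {
  H <- dimx[1]
  dx <- array(0, dim = dimx)
  for (h in seq_len(H)) dx[h, , ] <- dout / H
  dx
}

# single-direction GRU over a (T, D) sequence; hidden size from dim(p$Wz)
gru_forward <- function(seq_x, p) {
  Tn <- nrow(seq_x)
  Hn <- nrow(p$Wz)
  h <- numeric(Hn)
  Hs <- matrix(0, Tn, Hn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- seq_x[t, ]
    z <- sigmoid(drop(p$Wz %*% x + p$Uz %*% h) + p$bz)
    r <- sigmoid(drop(p$Wr %*% x + p$Ur %*% h) + p$br)
    uh <- drop(p$Un %*% h)
    n <- tanh(drop(p$Wn %*% x) + r * uh + p$bn)
    h_new <- (1 - z) * n + z * h
    cache[[t]] <- list(x = x, h_prev = h, z = z, r = r, n = n, uh = uh)
    h <- h_new
    Hs[t, ] <- h
  }
  list(out = Hs, cache = cache, p = p)
}

gru_backward <- function(dH, fw) {
  p <- fw$p
  Tn <- nrow(dH)
  grads <- lapply(p, function(w) array(0, dim = dim(w) %||% length(w)))
  dX <- matrix(0, Tn, ncol(p$Wz))
  dh <- numeric(nrow(p$Wz))
  for (t in rev(seq_len(Tn))) {
    cc <- fw$cache[[t]]
    dh <- dh + dH[t, ]
    dn <- dh * (1 - cc$z)
    dz <- dh * (cc$h_prev - cc$n)
    dh_prev <- dh * cc$z
    dpre_n <- dn * (1 - cc$n^2)
    grads$Wn <- grads$Wn + tcrossprod(dpre_n, cc$x)
    grads$bn <- grads$bn + dpre_n
    grads$Un <- grads$Un + tcrossprod(dpre_n * cc$r, cc$h_prev)
    dr <- dpre_n * cc$uh
    dh_prev <- dh_prev + drop(crossprod(p$Un, dpre_n * cc$r))
    dx <- drop(crossprod(p$Wn, dpre_n))
    dpre_z <- dz * cc$z * (1 - cc$z)
    grads$Wz <- grads$Wz + tcrossprod(dpre_z, cc$x)
    grads$bz <- grads$bz + dpre_z
    grads$Uz <- grads$Uz + tcrossprod(dpre_z, cc$h_prev)
    dh_prev <- dh_prev + drop(crossprod(p$Uz, dpre_z))
    dx <- dx + drop(crossprod(p$Wz, dpre_z))
    dpre_r <- dr * cc$r * (1 - cc$r)
    grads$Wr <- grads$Wr + tcrossprod(dpre_r, cc$x)
    grads$br <- grads$br + dpre_r
    grads$Ur <- grads$Ur + tcrossprod(dpre_r, cc$h_prev)
    dh_prev <- dh_prev + drop(crossprod(p$Ur, dpre_r))
    dx <- dx + drop(crossprod(p$Wr, dpre_r))
    dX[t, ] <- dx
    dh <- dh_prev
  }
  grads$bz <- drop(grads$bz); grads$br <- drop(grads$br)
  grads$bn <- drop(grads$bn)
  list(dX = dX, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bidirectional GRU: forward stream + reversed stream, outputs concatenated
bigru_forward <- function(seq_x, p_fwd, p_bwd) {
  fw <- gru_forward(seq_x, p_fwd)
  bw <- gru_forward(seq_x[rev(seq_len(nrow(seq_x))), , drop = FALSE], p_bwd)
  out <- cbind(fw$out, bw$out[rev(seq_len(nrow(seq_x))), , drop = FALSE])
  list(out = out, fw = fw, bw = bw)
}

bigru_backward <- function(dout, cache) {
  Hn <- ncol(cache$fw$out)
  Tn <- nrow(dout)
  g_f <- gru_backward(dout[, 1:Hn, drop = FALSE], cache$fw)
  g_b <- gru_backward(dout[rev(seq_len(Tn)), (Hn + 1):(2 * Hn),
                           drop = FALSE], cache$bw)
  dX <- g_f$dX + g_b$dX[rev(seq_len(Tn)), , drop = FALSE]
  list(dX = dX, grads_fwd = g_f$grads, grads_bwd = g_b$grads)
}
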