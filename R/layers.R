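# Differentiable layers built on the compiled tensor primitives.
# Each *_fw returns the output plus whatever the matching *_bw needs;
# backward functions return input gradients and parameter gradients.
# Tensors are [H, W, C, N] arrays (channels-last, column-major).

conv_fw <- function(x, w, b, ksize) .conv2d_fw(x, w, b, as.integer(ksize))

conv_bw <- function(x, w, gy, ksize) .conv2d_bw(x, w, gy, as.integer(ksize))

#' Parametric ReLU
#'
#' Elementwise activation `x` for positive inputs and `slope * x` otherwise.
#' The slope is a learnable per-channel parameter (initialised at 0.25 by
#' default in [net_config()]); a slope of 0 recovers the plain ReLU.
#'
#' @param x Numeric vector, matrix or array.
#' @param slope Negative-branch slope (scalar or per-channel as used
#'   internally).
#' @return Object shaped like `x`.
#' @examples
#' prelu(3, 0.25)   # 3
#' prelu(-2, 0.25)  # -0.5
#' prelu(-5, 0)     # 0: reduces to ReLU
#' @export
prelu <- function(x, slope) {
  pos <- x > 0
  x * (pos + slope * (1 - pos))
}

# PReLU over [H,W,C,N] with a per-channel slope vector.
act_fw <- function(x, slope) {
  HW <- dim(x)[1] * dim(x)[2]
  m <- (x > 0) + chan_rep(slope, HW) * (x <= 0)
  list(y = x * m, m = m)
}

act_bw <- function(x, m, gy, trainable_slope) {
  gx <- gy * m
  gslope <- if (trainable_slope) chan_sum(gy * x * (x <= 0)) else NULL
  list(gx = gx, gslope = gslope)
}

# Matrix flavour (k x U) for the point-refinement MLP; per-unit slopes.
mact_fw <- function(x, slope) {
  m <- (x > 0) + rep(slope, each = nrow(x)) * (x <= 0)
  list(y = x * m, m = m)
}

mact_bw <- function(x, m, gy, trainable_slope) {
  gslope <- if (trainable_slope) colSums(gy * x * (x <= 0)) else NULL
  list(gx = gy * m, gslope = gslope)
}

# Batch normalisation over (H, W, N) per channel.
bn_fw <- function(x, gamma, beta, rm, rv, training, momentum = 0.1,
                  eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; M <- HW * d[4]
  if (training) {
    mu <- chan_sum(x) / M
    v <- chan_sum(x * x) / M - mu^2
    v[v < 0] <- 0
    rm_new <- (1 - momentum) * rm + momentum * mu
    rv_new <- (1 - momentum) * rv + momentum * v * M / max(M - 1, 1)
  } else {
    mu <- rm; v <- rv; rm_new <- rm; rv_new <- rv
  }
  inv <- 1 / sqrt(v + eps)
  a <- gamma * inv
  y <- x * chan_rep(a, HW) + chan_rep(beta - mu * a, HW)
  list(y = y, mu = mu, inv = inv, rm = rm_new, rv = rv_new)
}

bn_bw <- function(x, mu, inv, gamma, gy) {
  d <- dim(x); HW <- d[1] * d[2]; M <- HW * d[4]
  xhat <- (x - chan_rep(mu, HW)) * chan_rep(inv, HW)
  sg <- chan_sum(gy)
  sgx <- chan_sum(gy * xhat)
  gx <- chan_rep(gamma * inv, HW) *
    (gy - chan_rep(sg / M, HW) - xhat * chan_rep(sgx / M, HW))
  list(gx = gx, ggamma = sgx, gbeta = sg)
}

#' Efficient channel attention (ECA)
#'
#' Re-weights the channels of a feature map: global average pooling over the
#' spatial grid, a bias-free 1-d convolution of size `kernel` across the
#' channel axis (zero-padded at the channel ends), a sigmoid, and a
#' channel-wise broadcast multiplication with the input. The number of
#' channels — and the tensor shape — is unchanged.
#'
#' @param x Feature tensor `[H, W, C]` or `[H, W, C, N]`.
#' @param w Numeric kernel of odd length (default length 3).
#' @return Tensor shaped like `x`.
#' @examples
#' x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
#' a <- eca(x, c(0.25, 0.5, 0.25))
#' stopifnot(identical(dim(a), dim(x)), all(abs(a) <= abs(x) + 1e-12))
#' @export
eca <- function(x, w = c(0.25, 0.5, 0.25)) {
  x4 <- as_batch(x)
  y <- eca_fw(x4, w)$y
  dim(y) <- dim(x)
  y
}

eca_conv1d <- function(g, w) {
  # g: C x N matrix; s[c] = sum_t w[t] * g[c + t - (r+1)], zero padded.
  C <- nrow(g); r <- (length(w) - 1L) / 2L
  s <- matrix(0, C, ncol(g))
  for (t in seq_along(w)) {
    off <- t - r - 1L  # source offset relative to c
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    s[ok, ] <- s[ok, ] + w[t] * g[src[ok], , drop = FALSE]
  }
  s
}

eca_fw <- function(x, w) {
  d <- dim(x); HW <- d[1] * d[2]
  g <- chan_stat_mat(x) / HW              # C x N channel descriptors
  s <- eca_conv1d(g, w)
  omega <- plogis(s)
  y <- x * chanimg_rep(omega, HW)
  list(y = y, g = g, omega = omega)
}

eca_bw <- function(x, g, omega, w, gy) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]
  gomega <- chan_stat_mat(gy * x)
  gs <- gomega * omega * (1 - omega)
  r <- (length(w) - 1L) / 2L
  gw <- numeric(length(w))
  for (t in seq_along(w)) {
    off <- t - r - 1L
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    gw[t] <- sum(gs[ok, , drop = FALSE] * g[src[ok], , drop = FALSE])
  }
  gg <- eca_conv1d(gs, rev(w))            # transpose of the correlation
  gx <- gy * chanimg_rep(omega, HW) + chanimg_rep(gg / HW, HW)
  list(gx = gx, gw = gw)
}

# Extract channel c of [H,W,C,N] as an [H,W,N]-shaped array (N may be 1).
chan_slice <- function(x, c, d) array(x[, , c, ], d[-3])

# Channel softmax over [H,W,C,N].
softmax_fw <- function(z) {
  d <- dim(z); C <- d[3]
  m <- chan_slice(z, 1, d)
  for (c in seq_len(C)[-1]) m <- pmax(m, chan_slice(z, c, d))
  p <- z
  for (c in seq_len(C)) p[, , c, ] <- exp(chan_slice(z, c, d) - m)
  s <- chan_slice(p, 1, d)
  for (c in seq_len(C)[-1]) s <- s + chan_slice(p, c, d)
  for (c in seq_len(C)) p[, , c, ] <- chan_slice(p, c, d) / s
  p
}

softmax_bw <- function(p, gp) {
  d <- dim(p); C <- d[3]
  dot <- chan_slice(p, 1, d) * chan_slice(gp, 1, d)
  for (c in seq_len(C)[-1]) dot <- dot + chan_slice(p, c, d) * chan_slice(gp, c, d)
  gz <- gp
  for (c in seq_len(C)) {
    gz[, , c, ] <- chan_slice(p, c, d) * (chan_slice(gp, c, d) - dot)
  }
  gz
}
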