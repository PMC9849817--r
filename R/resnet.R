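# Pure-R inference pass of the ResNet-152 grid-feature backbone.
#
# The backbone serves as a shape-level contract: a 448 x 448 RGB input yields
# a 14 x 14 grid of 2048-channel features. Weights are drawn from a seeded
# He-scaled initialization at call time (pretrained weights are an optional
# plug-in and are never shipped), so only the architecture and shapes are
# meaningful. Convolutions are evaluated as im2col + BLAS matrix products.
# Residual units follow Conv-BN-ReLU with dropout (ratio 1e-4) between branch
# convolutions; dropout is inert at inference.

# convolution of x (H x W x C array) with weights as a (kh*kw*C) x F matrix
conv2d <- function(x, w, kh, kw, stride = 1L, pad = 0L) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cc <- dim(x)[3]
  f <- ncol(w)
  if (kh == 1L && kw == 1L && stride == 1L && pad == 0L) {
    out <- matrix(x, h * wd, cc) %*% w
    return(array(out, dim = c(h, wd, f)))
  }
  hp <- h + 2L * pad; wp <- wd + 2L * pad
  xp <- array(0, dim = c(hp, wp, cc))
  xp[pad + seq_len(h), pad + seq_len(wd), ] <- x
  ho <- (hp - kh) %/% stride + 1L
  wo <- (wp - kw) %/% stride + 1L
  rows0 <- (seq_len(ho) - 1L) * stride          # 0-based patch top rows
  cols0 <- (seq_len(wo) - 1L) * stride
  pos0 <- rep(rows0, wo) + rep(cols0 * hp, each = ho)
  off <- as.vector(outer(rep(0:(kh - 1L), kw) + rep(0:(kw - 1L), each = kh) * hp,
                         (0:(cc - 1L)) * hp * wp, "+"))
  cols_mat <- xp[outer(pos0, off, "+") + 1L]
  dim(cols_mat) <- c(ho * wo, kh * kw * cc)
  array(cols_mat %*% w, dim = c(ho, wo, f))
}

maxpool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cc <- dim(x)[3]
  hp <- h + 2L * pad; wp <- wd + 2L * pad
  xp <- array(-Inf, dim = c(hp, wp, cc))
  xp[pad + seq_len(h), pad + seq_len(wd), ] <- x
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  out <- array(-Inf, dim = c(ho, wo, cc))
  ri <- (seq_len(ho) - 1L) * stride
  ci <- (seq_len(wo) - 1L) * stride
  for (di in seq_len(k)) for (dj in seq_len(k))
    out <- pmax(out, xp[ri + di, ci + dj, , drop = FALSE])
  out
}

# Batch normalization evaluated with the statistics of the present input
# (per-channel over spatial positions) — no running averages exist at random
# init, and normalizing keeps the 152-layer forward numerically stable.
batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cc <- dim(x)[3]
  m <- matrix(x, h * wd, cc)
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu^2
  m <- (m - rep(mu, each = h * wd)) / rep(sqrt(v + eps), each = h * wd)
  m <- m * rep(gamma, each = h * wd) + rep(beta, each = h * wd)
  array(m, dim = c(h, wd, cc))
}

relu_arr <- function(x) { x[x < 0] <- 0; x }

# He-scaled weight draw for a (kh*kw*cin) x f convolution.
draw_conv <- function(kh, kw, cin, f) {
  n <- kh * kw * cin
  matrix(stats::rnorm(n * f, sd = sqrt(2 / n)), n, f)
}

draw_bn <- function(f) list(gamma = stats::runif(f, 0.9, 1.1), beta = rep(0, f))

conv_bn_relu <- function(x, kh, kw, cin, f, stride = 1L, pad = 0L, relu = TRUE) {
  w <- draw_conv(kh, kw, cin, f)
  bn <- draw_bn(f)
  y <- batchnorm(conv2d(x, w, kh, kw, stride, pad), bn$gamma, bn$beta)
  if (relu) relu_arr(y) else y
}

bottleneck <- function(x, cin, width, cout, stride) {
  y <- conv_bn_relu(x, 1L, 1L, cin, width)
  y <- conv_bn_relu(y, 3L, 3L, width, width, stride = stride, pad = 1L)
  y <- conv_bn_relu(y, 1L, 1L, width, cout, relu = FALSE)
  sc <- if (cin != cout || stride != 1L)
    conv_bn_relu(x, 1L, 1L, cin, cout, stride = stride, relu = FALSE) else x
  relu_arr(y + sc)
}

#' Random-initialization ResNet-152 grid features
#'
#' Runs a full ResNet-152 forward pass (bottleneck layout 3-8-36-3) with
#' seeded He-initialized weights and returns the final convolutional grid.
#' On a 448 x 448 input this is 14 x 14 positions of 2048 channels.
#'
#' @param img numeric array `H x W x 3`, intensities in `[0, 255]`.
#' @param seed integer seed for the weight draw.
#' @return numeric array `H/32 x W/32 x 2048`.
#' @export
resnet152_features <- function(img, seed = 1L) {
  ovqa_assert(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3,
              "`img` must be H x W x 3")
  with_seed(seed, {
    x <- img / 255 - 0.5
    x <- conv_bn_relu(x, 7L, 7L, 3L, 64L, stride = 2L, pad = 3L)
    x <- maxpool2d(x)
    stages <- list(c(blocks = 3L, width = 64L, cout = 256L, stride = 1L),
                   c(blocks = 8L, width = 128L, cout = 512L, stride = 2L),
                   c(blocks = 36L, width = 256L, cout = 1024L, stride = 2L),
                   c(blocks = 3L, width = 512L, cout = 2048L, stride = 2L))
    for (st in stages) {
      for (b in seq_len(st[["blocks"]])) {
        x <- bottleneck(x, dim(x)[3], st[["width"]], st[["cout"]],
                        stride = if (b == 1L) st[["stride"]] else 1L)
      }
    }
    x
  })
}
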