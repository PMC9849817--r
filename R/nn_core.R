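# Minimal neural-network primitives with explicit forward caches and manual
# reverse-mode gradients. All activations are plain matrices (rows = sequence
# positions); parameters are nested named lists so the optimizer and the
# gradient checker can walk them generically.

init_linear <- function(d_in, d_out, scale = NULL) {
  s <- scale %||% (1 / sqrt(d_in))
  list(W = matrix(stats::rnorm(d_in * d_out, sd = s), d_in, d_out),
       b = rep(0, d_out))
}

linear_fwd <- function(x, p) {
  list(out = x %*% p$W + rep(p$b, each = nrow(x)), x = x)
}

linear_bwd <- function(d_out, cache, p) {
  list(d_in = d_out %*% t(p$W),
       grads = list(W = crossprod(cache$x, d_out), b = colSums(d_out)))
}

init_layernorm <- function(d) list(gamma = rep(1, d), beta = rep(0, d))

layernorm_fwd <- function(x, p, eps = 1e-12) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- xc * inv_std
  list(out = xhat * rep(p$gamma, each = nrow(x)) + rep(p$beta, each = nrow(x)),
       xhat = xhat, inv_std = inv_std)
}

layernorm_bwd <- function(d_out, cache, p) {
  n <- nrow(d_out)
  dxhat <- d_out * rep(p$gamma, each = n)
  xhat <- cache$xhat
  d_in <- cache$inv_std *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(d_in = d_in,
       grads = list(gamma = colSums(d_out * xhat), beta = colSums(d_out)))
}

relu_fwd <- function(x) {
  m <- x > 0
  x[!m] <- 0
  list(out = x, mask = m)
}

relu_bwd <- function(d_out, cache) d_out * cache$mask

# Inverted dropout; identity when not training or rate == 0.
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  m <- (matrix(stats::runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(out = x * m, mask = m)
}

dropout_bwd <- function(d_out, cache) {
  if (is.null(cache$mask)) d_out else d_out * cache$mask
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Cross-entropy over answer logits; returns loss and d_logits.
cross_entropy <- function(logits, label_idx) {
  p <- softmax_vec(as.numeric(logits))
  d <- p
  d[label_idx] <- d[label_idx] - 1
  list(loss = -log(max(p[label_idx], 1e-300)), d_logits = d)
}

#' AdamW optimizer state
#'
#' Decoupled-weight-decay Adam, the optimizer used for training (defaults
#' beta1 = 0.9, beta2 = 0.999).
#'
#' @param params parameter tree the state should mirror.
#' @return optimizer state list.
#' @export
adamw_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

#' One AdamW update
#'
#' @param params parameter tree.
#' @param grads gradient tree of the same shape.
#' @param state state from [adamw_init()].
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical stabilizer.
#' @param weight_decay decoupled weight-decay coefficient.
#' @return list with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * (u + weight_decay * p), params, upd)
  list(params = params, state = state)
}
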