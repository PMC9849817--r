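# Modular co-attention: multi-head attention, SA (self-attention) and CA
# (guided attention) units, the stacked MCA layer SA(Y)-SCA(X,Y), and the
# attended reduction to pooled fusion inputs.
#
# Layer normalization is applied pre-sublayer (pre-norm), the feed-forward
# expansion uses ReLU, and the guided direction is question-guided image
# attention: queries come from the image sequence X, keys and values from the
# question sequence Y, with X on the residual path. A `swap_roles` flag on the
# stack reverses the direction for ablation.

#' Attention configuration
#'
#' @param heads number of attention heads (default 8); must divide `hidden`.
#' @param hidden model width (default 512).
#' @param ffn_mult feed-forward expansion factor (default 4).
#' @param L number of stacked MCA layers (default 4, the saturation depth).
#' @param dropout dropout rate on sublayer outputs during training (default 0.5).
#' @param eps layer-norm epsilon (default 1e-12).
#' @param swap_roles if `TRUE`, the guided-attention queries come from the
#'   question instead of the image.
#' @export
attn_config <- function(heads = 8L, hidden = 512L, ffn_mult = 4L, L = 4L,
                        dropout = 0.5, eps = 1e-12, swap_roles = FALSE) {
  ovqa_assert(L >= 1, "`L` must be >= 1", class = "invalid_config")
  ovqa_assert(hidden %% heads == 0, "`hidden` must be divisible by `heads`",
              class = "invalid_config")
  structure(list(heads = as.integer(heads), hidden = as.integer(hidden),
                 ffn_mult = as.integer(ffn_mult), L = as.integer(L),
                 dropout = dropout, eps = eps, swap_roles = isTRUE(swap_roles)),
            class = "vqa_attn_config")
}

init_mha_params <- function(h) {
  list(wq = init_linear(h, h), wk = init_linear(h, h),
       wv = init_linear(h, h), wo = init_linear(h, h))
}

init_ffn_params <- function(h, mult) {
  list(w1 = init_linear(h, h * mult), w2 = init_linear(h * mult, h))
}

init_sa_params <- function(cfg) {
  list(ln1 = init_layernorm(cfg$hidden), mha = init_mha_params(cfg$hidden),
       ln2 = init_layernorm(cfg$hidden), ffn = init_ffn_params(cfg$hidden, cfg$ffn_mult))
}

init_ca_params <- function(cfg) {
  list(ln_q = init_layernorm(cfg$hidden), ln_kv = init_layernorm(cfg$hidden),
       mha = init_mha_params(cfg$hidden),
       ln2 = init_layernorm(cfg$hidden), ffn = init_ffn_params(cfg$hidden, cfg$ffn_mult))
}

#' Initialize parameters of the stacked MCA module
#'
#' Each of the `L` layers holds a question SA unit, an image SA unit, and a
#' question-guided image CA unit. Parameter count grows strictly with `L`.
#'
#' @param cfg an [attn_config()].
#' @param seed integer seed.
#' @return nested parameter list (length `L`).
#' @export
init_mca_params <- function(cfg, seed = 1L) {
  with_seed(seed, lapply(seq_len(cfg$L), function(l)
    list(sa_y = init_sa_params(cfg), sa_x = init_sa_params(cfg),
         ca_x = init_ca_params(cfg))))
}

# ---- multi-head attention ---------------------------------------------------

mha_fwd <- function(q_in, k_in, v_in, p, cfg, key_mask = NULL, training = FALSE) {
  h <- cfg$hidden
  nh <- cfg$heads
  dh <- h %/% nh
  lq <- linear_fwd(q_in, p$wq)
  lk <- linear_fwd(k_in, p$wk)
  lv <- linear_fwd(v_in, p$wv)
  km <- key_mask %||% rep(TRUE, nrow(k_in))
  o <- matrix(0, nrow(q_in), h)
  attn <- vector("list", nh)
  for (g in seq_len(nh)) {
    idx <- ((g - 1L) * dh + 1L):(g * dh)
    s <- tcrossprod(lq$out[, idx, drop = FALSE], lk$out[, idx, drop = FALSE]) / sqrt(dh)
    s[, !km] <- -Inf
    a <- row_softmax(s)   # fully-masked queries get an all-zero row (zero output)
    attn[[g]] <- a
    o[, idx] <- a %*% lv$out[, idx, drop = FALSE]
  }
  lo <- linear_fwd(o, p$wo)
  list(out = lo$out,
       cache = list(lq = lq, lk = lk, lv = lv, lo = lo, attn = attn,
                    dh = dh, km = km),
       attn = attn)
}

mha_bwd <- function(d_out, cache, p, cfg) {
  nh <- cfg$heads
  dh <- cache$dh
  bo <- linear_bwd(d_out, cache$lo, p$wo)
  d_o <- bo$d_in
  dq <- matrix(0, nrow(cache$lq$out), cfg$hidden)
  dk <- matrix(0, nrow(cache$lk$out), cfg$hidden)
  dv <- matrix(0, nrow(cache$lv$out), cfg$hidden)
  for (g in seq_len(nh)) {
    idx <- ((g - 1L) * dh + 1L):(g * dh)
    a <- cache$attn[[g]]
    d_og <- d_o[, idx, drop = FALSE]
    da <- tcrossprod(d_og, cache$lv$out[, idx, drop = FALSE])
    dv[, idx] <- crossprod(a, d_og)
    ds <- a * (da - rowSums(da * a))       # masked keys have a == 0, so ds == 0
    dq[, idx] <- (ds %*% cache$lk$out[, idx, drop = FALSE]) / sqrt(dh)
    dk[, idx] <- (crossprod(ds, cache$lq$out[, idx, drop = FALSE])) / sqrt(dh)
  }
  bq <- linear_bwd(dq, cache$lq, p$wq)
  bk <- linear_bwd(dk, cache$lk, p$wk)
  bv <- linear_bwd(dv, cache$lv, p$wv)
  list(d_q_in = bq$d_in, d_k_in = bk$d_in, d_v_in = bv$d_in,
       grads = list(wq = bq$grads, wk = bk$grads, wv = bv$grads, wo = bo$grads))
}

#' Multi-head scaled dot-product attention
#'
#' Scaled dot products per head, softmax over unmasked keys, head
#' concatenation and output projection. Queries whose keys are all masked
#' produce a zero output row.
#'
#' @param q_in,k_in,v_in input sequences (`T x hidden` matrices); `k_in` and
#'   `v_in` must share their length.
#' @param cfg an [attn_config()].
#' @param params optional parameter list (from the internal initializer);
#'   freshly initialized from `seed` when `NULL`.
#' @param key_mask logical vector over key positions (`TRUE` = attend).
#' @param seed seed for fresh parameter initialization.
#' @return attended sequence (`nrow(q_in) x hidden`) with the per-head
#'   attention matrices attached as attribute `"attention"`.
#' @export
multi_head_attention <- function(q_in, k_in, v_in, cfg = attn_config(),
                                 params = NULL, key_mask = NULL, seed = 1L) {
  ovqa_assert(ncol(q_in) == cfg$hidden && ncol(k_in) == cfg$hidden &&
                ncol(v_in) == cfg$hidden, "inputs must be T x hidden")
  ovqa_assert(nrow(k_in) == nrow(v_in), "`k_in` and `v_in` must align")
  p <- params %||% with_seed(seed, init_mha_params(cfg$hidden))
  r <- mha_fwd(q_in, k_in, v_in, p, cfg, key_mask)
  structure(r$out, attention = r$attn)
}

# ---- SA / CA units ----------------------------------------------------------

sa_fwd <- function(x, p, cfg, mask = NULL, training = FALSE) {
  l1 <- layernorm_fwd(x, p$ln1, cfg$eps)
  at <- mha_fwd(l1$out, l1$out, l1$out, p$mha, cfg, mask, training)
  d1 <- dropout_fwd(at$out, cfg$dropout, training)
  u <- x + d1$out
  l2 <- layernorm_fwd(u, p$ln2, cfg$eps)
  f1 <- linear_fwd(l2$out, p$ffn$w1)
  r1 <- relu_fwd(f1$out)
  f2 <- linear_fwd(r1$out, p$ffn$w2)
  d2 <- dropout_fwd(f2$out, cfg$dropout, training)
  list(out = u + d2$out,
       cache = list(l1 = l1, at = at, d1 = d1, l2 = l2, f1 = f1, r1 = r1,
                    f2 = f2, d2 = d2),
       attn = at$attn)
}

sa_bwd <- function(d_out, cache, p, cfg) {
  d_f2 <- dropout_bwd(d_out, cache$d2)
  b2 <- linear_bwd(d_f2, cache$f2, p$ffn$w2)
  d_r1 <- relu_bwd(b2$d_in, cache$r1)
  b1 <- linear_bwd(d_r1, cache$f1, p$ffn$w1)
  bl2 <- layernorm_bwd(b1$d_in, cache$l2, p$ln2)
  d_u <- d_out + bl2$d_in
  d_at <- dropout_bwd(d_u, cache$d1)
  bm <- mha_bwd(d_at, cache$at$cache, p$mha, cfg)
  d_l1 <- bm$d_q_in + bm$d_k_in + bm$d_v_in
  bl1 <- layernorm_bwd(d_l1, cache$l1, p$ln1)
  list(d_in = d_u + bl1$d_in,
       grads = list(ln1 = bl1$grads, mha = bm$grads, ln2 = bl2$grads,
                    ffn = list(w1 = b1$grads, w2 = b2$grads)))
}

ca_fwd <- function(x, y, p, cfg, key_mask = NULL, training = FALSE) {
  lq <- layernorm_fwd(x, p$ln_q, cfg$eps)
  lkv <- layernorm_fwd(y, p$ln_kv, cfg$eps)
  at <- mha_fwd(lq$out, lkv$out, lkv$out, p$mha, cfg, key_mask, training)
  d1 <- dropout_fwd(at$out, cfg$dropout, training)
  u <- x + d1$out
  l2 <- layernorm_fwd(u, p$ln2, cfg$eps)
  f1 <- linear_fwd(l2$out, p$ffn$w1)
  r1 <- relu_fwd(f1$out)
  f2 <- linear_fwd(r1$out, p$ffn$w2)
  d2 <- dropout_fwd(f2$out, cfg$dropout, training)
  list(out = u + d2$out,
       cache = list(lq = lq, lkv = lkv, at = at, d1 = d1, l2 = l2, f1 = f1,
                    r1 = r1, f2 = f2, d2 = d2),
       attn = at$attn)
}

ca_bwd <- function(d_out, cache, p, cfg) {
  d_f2 <- dropout_bwd(d_out, cache$d2)
  b2 <- linear_bwd(d_f2, cache$f2, p$ffn$w2)
  d_r1 <- relu_bwd(b2$d_in, cache$r1)
  b1 <- linear_bwd(d_r1, cache$f1, p$ffn$w1)
  bl2 <- layernorm_bwd(b1$d_in, cache$l2, p$ln2)
  d_u <- d_out + bl2$d_in
  d_at <- dropout_bwd(d_u, cache$d1)
  bm <- mha_bwd(d_at, cache$at$cache, p$mha, cfg)
  blq <- layernorm_bwd(bm$d_q_in, cache$lq, p$ln_q)
  blkv <- layernorm_bwd(bm$d_k_in + bm$d_v_in, cache$lkv, p$ln_kv)
  list(d_x = d_u + blq$d_in, d_y = blkv$d_in,
       grads = list(ln_q = blq$grads, ln_kv = blkv$grads, mha = bm$grads,
                    ln2 = bl2$grads, ffn = list(w1 = b1$grads, w2 = b2$grads)))
}

#' Self-attention unit
#'
#' Pre-norm multi-head self-attention plus residual, then pre-norm ReLU
#' feed-forward plus residual. With all sublayer weights zero the unit is the
#' identity.
#'
#' @inheritParams multi_head_attention
#' @param s one modality's sequence (`T x hidden`).
#' @param mask logical mask over positions.
#' @return transformed sequence of the same shape, per-head attention in
#'   attribute `"attention"`.
#' @export
sa_unit <- function(s, cfg = attn_config(), params = NULL, mask = NULL, seed = 1L) {
  p <- params %||% with_seed(seed, init_sa_params(cfg))
  r <- sa_fwd(s, p, cfg, mask)
  structure(r$out, attention = r$attn)
}

#' Guided co-attention unit
#'
#' Queries come from the guided modality `x` (image), keys and values from the
#' guiding modality `y` (question); `x` carries the residual path. The
#' feed-forward part matches [sa_unit()].
#'
#' @inheritParams sa_unit
#' @param x guided modality sequence (`T_x x hidden`).
#' @param y guiding modality sequence (`T_y x hidden`).
#' @param key_mask logical mask over `y` positions.
#' @return sequence shaped like `x`, attention maps in attribute `"attention"`.
#' @export
ca_unit <- function(x, y, cfg = attn_config(), params = NULL, key_mask = NULL,
                    seed = 1L) {
  p <- params %||% with_seed(seed, init_ca_params(cfg))
  r <- ca_fwd(x, y, p, cfg, key_mask)
  structure(r$out, attention = r$attn)
}

mca_stack_fwd <- function(x, y, params, cfg, xmask = NULL, ymask = NULL,
                          training = FALSE) {
  caches <- vector("list", length(params))
  attn <- vector("list", length(params))
  for (l in seq_along(params)) {
    p <- params[[l]]
    ry <- sa_fwd(y, p$sa_y, cfg, ymask, training)
    y <- ry$out
    rx <- sa_fwd(x, p$sa_x, cfg, xmask, training)
    x <- rx$out
    if (cfg$swap_roles) {
      rc <- ca_fwd(y, x, p$ca_x, cfg, xmask, training)
      y <- rc$out
    } else {
      rc <- ca_fwd(x, y, p$ca_x, cfg, ymask, training)
      x <- rc$out
    }
    caches[[l]] <- list(sa_y = ry$cache, sa_x = rx$cache, ca = rc$cache)
    attn[[l]] <- list(sa_y = ry$attn, sa_x = rx$attn, ca = rc$attn)
  }
  list(x = x, y = y, caches = caches, attn = attn)
}

mca_stack_bwd <- function(d_x, d_y, caches, params, cfg) {
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    p <- params[[l]]
    cc <- caches[[l]]
    if (cfg$swap_roles) {
      bc <- ca_bwd(d_y, cc$ca, p$ca_x, cfg)
      d_y <- bc$d_x
      d_x <- d_x + bc$d_y
    } else {
      bc <- ca_bwd(d_x, cc$ca, p$ca_x, cfg)
      d_x <- bc$d_x
      d_y <- d_y + bc$d_y
    }
    bx <- sa_bwd(d_x, cc$sa_x, p$sa_x, cfg)
    d_x <- bx$d_in
    by <- sa_bwd(d_y, cc$sa_y, p$sa_y, cfg)
    d_y <- by$d_in
    grads[[l]] <- list(sa_y = by$grads, sa_x = bx$grads, ca_x = bc$grads)
  }
  list(d_x = d_x, d_y = d_y, grads = grads)
}

#' Stacked modular co-attention
#'
#' Applies, per layer and in order: question self-attention, image
#' self-attention, then question-guided image attention — the
#' SA(Y)-SCA(X,Y) layer — repeated `cfg$L` times as an encoder-decoder-style
#' cascade.
#'
#' @inheritParams sa_unit
#' @param x projected image sequence (`P x hidden`).
#' @param y projected question sequence (`T x hidden`).
#' @param xmask,ymask per-modality masks.
#' @return list with final sequences `x` and `y` and per-layer attention maps
#'   in `attn`.
#' @export
mca_stack <- function(x, y, cfg = attn_config(), params = NULL,
                      xmask = NULL, ymask = NULL, seed = 1L) {
  p <- params %||% init_mca_params(cfg, seed)
  r <- mca_stack_fwd(x, y, p, cfg, xmask, ymask)
  list(x = r$x, y = r$y, attn = r$attn)
}

# ---- attended reduction -----------------------------------------------------

init_reduce_params <- function(h) list(w = rep(0, h), b = 0)

reduce_fwd <- function(s, p, mask = NULL) {
  m <- mask %||% rep(TRUE, nrow(s))
  if (!any(m)) ovqa_stop("attended_reduce: all positions masked")
  scores <- as.numeric(s %*% p$w) + p$b
  scores[!m] <- -Inf
  alpha <- as.numeric(row_softmax(matrix(scores, 1)))
  list(out = as.numeric(crossprod(s, alpha)),
       cache = list(s = s, alpha = alpha))
}

reduce_bwd <- function(d_out, cache, p) {
  s <- cache$s
  alpha <- cache$alpha
  d_s <- outer(alpha, d_out)
  d_alpha <- as.numeric(s %*% d_out)
  d_scores <- alpha * (d_alpha - sum(alpha * d_alpha))
  d_s <- d_s + outer(d_scores, p$w)
  list(d_in = d_s,
       grads = list(w = as.numeric(crossprod(s, d_scores)), b = sum(d_scores)))
}

#' Attended reduction of a sequence to one vector
#'
#' Single-glimpse learned scoring: a linear score per position, softmax over
#' unmasked positions, and the weighted sum of the rows. With zero-initialized
#' scoring weights this is the arithmetic mean of the unmasked rows.
#'
#' @param s sequence (`T x d`).
#' @param params optional list with `w` (length d) and `b`; zeros by default.
#' @param mask logical vector over positions.
#' @return length-`d` vector with the attention weights as attribute
#'   `"weights"`.
#' @export
attended_reduce <- function(s, params = NULL, mask = NULL) {
  p <- params %||% init_reduce_params(ncol(s))
  r <- reduce_fwd(s, p, mask)
  structure(r$out, weights = r$cache$alpha)
}
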