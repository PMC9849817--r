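# Bilinear fusion of the pooled question vector q and pooled image vector v.
#
# The full bilinear form contracts a d_q x d_v x |A| tensor T with q and v.
# T is never materialized in the working path: it is Tucker-decomposed into
# factor matrices W_q, W_v, W_o and a small core T_c (t_q x t_v x t_o), and
# every output slice of the core is additionally constrained to rank R (a sum
# of R outer products), so the core holds t_o * R * (t_q + t_v) parameters.
# The squared variant squares the projected image vector element-wise before
# the core contraction, emphasizing image features; it keeps the raw square
# (no signed square root). A full-tensor oracle materializes T for testing.

#' Low-rank Tucker core factors
#'
#' Each of the `t_o` core slices is a sum of `R` outer products of learnable
#' factor pairs. Factors are stored column-blocked: column `(o-1)*R + r` of
#' `A` (`t_q x t_o*R`) and `B` (`t_v x t_o*R`) hold the r-th pair of slice o.
#'
#' @param t_q,t_v,t_o core dimensions.
#' @param rank slice rank R (>= 1).
#' @param seed integer seed.
#' @param scale factor initialization scale.
#' @return list with `A`, `B`, `t_q`, `t_v`, `t_o`, `rank`.
#' @export
build_lowrank_core <- function(t_q, t_v, t_o, rank, seed = 1L, scale = NULL) {
  ovqa_assert(rank >= 1, "`rank` must be >= 1")
  s <- scale %||% (1 / sqrt(sqrt(t_q * t_v) * rank))
  with_seed(seed, list(
    A = matrix(stats::rnorm(t_q * t_o * rank, sd = s), t_q, t_o * rank),
    B = matrix(stats::rnorm(t_v * t_o * rank, sd = s), t_v, t_o * rank),
    t_q = as.integer(t_q), t_v = as.integer(t_v), t_o = as.integer(t_o),
    rank = as.integer(rank)))
}

#' Materialize the core tensor from its low-rank factors
#'
#' @param core a [build_lowrank_core()] result.
#' @return numeric array `t_q x t_v x t_o`.
#' @export
core_to_array <- function(core) {
  tc <- array(0, dim = c(core$t_q, core$t_v, core$t_o))
  for (o in seq_len(core$t_o)) {
    idx <- ((o - 1L) * core$rank + 1L):(o * core$rank)
    tc[, , o] <- core$A[, idx, drop = FALSE] %*% t(core$B[, idx, drop = FALSE])
  }
  tc
}

#' Tucker fusion parameters
#'
#' @param d_q,d_v pooled question / image feature dimensions.
#' @param n_answers answer vocabulary size |A|.
#' @param t_q,t_v,t_o core dimensions (defaults 512, aligning with the hidden
#'   size).
#' @param rank low-rank constraint R on the core slices (default 15).
#' @param glimpses number of independent image projections G, concatenated
#'   before the contraction (default 1); the effective image core dimension is
#'   `t_v * glimpses`.
#' @param seed integer seed.
#' @return a `vqa_tucker_params` list: `W_q` (`d_q x t_q`), `W_v`
#'   (`d_v x t_v*G`), `core` factors, `W_o` (`|A| x t_o`), `b_f` (length |A|).
#' @export
tucker_params <- function(d_q, d_v, n_answers, t_q = 512L, t_v = 512L,
                          t_o = 512L, rank = 15L, glimpses = 1L, seed = 1L) {
  tve <- as.integer(t_v * glimpses)
  p <- with_seed(seed, list(
    W_q = matrix(stats::rnorm(d_q * t_q, sd = 1 / sqrt(d_q)), d_q, t_q),
    W_v = matrix(stats::rnorm(d_v * tve, sd = 1 / sqrt(d_v)), d_v, tve),
    core = build_lowrank_core(t_q, tve, t_o, rank,
                              seed = derive_seed(seed, "core")),
    W_o = matrix(stats::rnorm(n_answers * t_o, sd = 1 / sqrt(t_o)), n_answers, t_o),
    b_f = rep(0, n_answers)))
  structure(c(p, list(d_q = as.integer(d_q), d_v = as.integer(d_v),
                      n_answers = as.integer(n_answers),
                      t_q = as.integer(t_q), t_v = tve, t_o = as.integer(t_o),
                      rank = as.integer(rank), glimpses = as.integer(glimpses))),
            class = "vqa_tucker_params")
}

# trainable leaves of the fusion parameters (core factors included)
tucker_trainables <- function(p) {
  list(W_q = p$W_q, W_v = p$W_v, A = p$core$A, B = p$core$B,
       W_o = p$W_o, b_f = p$b_f)
}

tucker_set_trainables <- function(p, tr) {
  p$W_q <- tr$W_q; p$W_v <- tr$W_v
  p$core$A <- tr$A; p$core$B <- tr$B
  p$W_o <- tr$W_o; p$b_f <- tr$b_f
  p
}

# indicator summing the R columns of each output slot: (t_o*R) x t_o
rank_pool_matrix <- function(t_o, rank) kronecker(diag(t_o), rep(1, rank))

tucker_fwd <- function(q, v, p, squared = FALSE) {
  qm <- if (is.matrix(q)) q else matrix(q, 1)
  vm <- if (is.matrix(v)) v else matrix(v, 1)
  ovqa_assert(ncol(qm) == p$d_q && ncol(vm) == p$d_v,
              "fusion input dimension mismatch")
  qp <- qm %*% p$W_q
  vp <- vm %*% p$W_v
  vs <- if (squared) vp * vp else vp
  u <- qp %*% p$core$A
  w <- vs %*% p$core$B
  m <- rank_pool_matrix(p$t_o, p$rank)
  s <- (u * w) %*% m
  logits <- s %*% t(p$W_o) + rep(p$b_f, each = nrow(s))
  list(out = if (is.matrix(q) || is.matrix(v)) logits else as.numeric(logits),
       cache = list(qm = qm, vm = vm, qp = qp, vp = vp, vs = vs, u = u, w = w,
                    s = s, m = m, squared = squared))
}

tucker_bwd <- function(d_logits, cache, p) {
  dl <- if (is.matrix(d_logits)) d_logits else matrix(d_logits, 1)
  ds <- dl %*% p$W_o
  duw <- ds %*% t(cache$m)
  du <- duw * cache$w
  dw <- duw * cache$u
  dqp <- du %*% t(p$core$A)
  dvs <- dw %*% t(p$core$B)
  dvp <- if (cache$squared) 2 * cache$vp * dvs else dvs
  list(d_q = dqp %*% t(p$W_q),
       d_v = dvp %*% t(p$W_v),
       grads = list(W_q = crossprod(cache$qm, dqp),
                    W_v = crossprod(cache$vm, dvp),
                    A = crossprod(cache$qp, du),
                    B = crossprod(cache$vs, dw),
                    W_o = crossprod(dl, cache$s),
                    b_f = colSums(dl)))
}

#' Tucker-decomposed bilinear fusion
#'
#' Projects both pooled vectors, contracts with the low-rank core over the
#' question then image core modes, expands through `W_o` and adds the bias —
#' without ever materializing the full `d_q x d_v x |A|` tensor.
#'
#' @param q pooled question vector (length `d_q`) or an `n x d_q` matrix.
#' @param v pooled image vector (length `d_v`) or an `n x d_v` matrix.
#' @param params a [tucker_params()].
#' @return answer logits (length `|A|`, or `n x |A|` for matrix input).
#' @export
tucker_fuse <- function(q, v, params) tucker_fwd(q, v, params, squared = FALSE)$out

#' Squared-image-projection Tucker fusion
#'
#' Identical to [tucker_fuse()] except the projected image vector is squared
#' element-wise before the core contraction. The output is an even function of
#' the projected image vector, which re-weights the fusion toward image
#' evidence.
#'
#' @inheritParams tucker_fuse
#' @export
squared_tucker_fuse <- function(q, v, params) tucker_fwd(q, v, params, squared = TRUE)$out

#' Full-bilinear oracle
#'
#' Reference implementation for tests: materializes the complete three-way
#' tensor from the factors (or, for the squared variant, the dense core) and
#' contracts it directly with explicit sums. Refuses instances whose full
#' tensor would exceed the size guard.
#'
#' @inheritParams tucker_fuse
#' @param squared use the element-wise-squared image projection.
#' @param max_cells refuse to materialize more than this many tensor cells.
#' @return answer logits (length `|A|`).
#' @export
full_bilinear_oracle <- function(q, v, params, squared = FALSE, max_cells = 2e6) {
  p <- params
  ovqa_assert(as.double(p$d_q) * p$d_v * p$n_answers <= max_cells,
              "instance too large for the full-tensor oracle", class = "size_guard")
  tc <- core_to_array(p$core)
  if (!squared) {
    # T = ((Tc x1 Wq) x2 Wv) x3 Wo, then logits_k = q' T[,,k] v + b_k
    tt <- array(0, dim = c(p$d_q, p$d_v, p$n_answers))
    for (k in seq_len(p$n_answers)) {
      sl <- matrix(0, p$t_q, p$t_v)
      for (o in seq_len(p$t_o)) sl <- sl + p$W_o[k, o] * tc[, , o]
      tt[, , k] <- p$W_q %*% sl %*% t(p$W_v)
    }
    logits <- vapply(seq_len(p$n_answers),
                     function(k) as.numeric(t(q) %*% tt[, , k] %*% v), 0)
  } else {
    qp <- as.numeric(t(q) %*% p$W_q)
    vs <- as.numeric(t(v) %*% p$W_v)^2
    s <- vapply(seq_len(p$t_o),
                function(o) as.numeric(t(qp) %*% tc[, , o] %*% vs), 0)
    logits <- as.numeric(p$W_o %*% s)
  }
  logits + p$b_f
}

#' Baseline fusion operators
#'
#' `concat`: concatenation followed by a linear map; `mlb`: Hadamard product
#' of linear projections; `mutan`: [tucker_fuse()] without the square (same
#' code path, returns logits).
#'
#' @inheritParams tucker_fuse
#' @param mode one of `"concat"`, `"mlb"`, `"mutan"`.
#' @param params for `"mutan"` a [tucker_params()]; otherwise a list from
#'   [baseline_params()].
#' @return fused vector (`concat`/`mlb`) or logits (`mutan`).
#' @export
baseline_fuse <- function(q, v, params, mode = c("concat", "mlb", "mutan")) {
  mode <- match.arg(mode)
  switch(mode,
    concat = as.numeric(c(q, v) %*% params$W_c) + params$b_c,
    mlb = as.numeric(q %*% params$W_q) * as.numeric(v %*% params$W_v),
    mutan = tucker_fuse(q, v, params))
}

#' Baseline fusion parameters
#'
#' @param d_q,d_v input dimensions.
#' @param out_dim common fused output dimension.
#' @param mode `"concat"` or `"mlb"`.
#' @param seed integer seed.
#' @export
baseline_params <- function(d_q, d_v, out_dim, mode = c("concat", "mlb"), seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, switch(mode,
    concat = list(W_c = matrix(stats::rnorm((d_q + d_v) * out_dim,
                                            sd = 1 / sqrt(d_q + d_v)),
                               d_q + d_v, out_dim),
                  b_c = rep(0, out_dim)),
    mlb = list(W_q = matrix(stats::rnorm(d_q * out_dim, sd = 1 / sqrt(d_q)), d_q, out_dim),
               W_v = matrix(stats::rnorm(d_v * out_dim, sd = 1 / sqrt(d_v)), d_v, out_dim))))
}

#' Classifier head parameters
#'
#' @param d input dimension of the attended vectors.
#' @param d_z fused dimension (default 2048, the bilinear-pooling width).
#' @param n_answers answer vocabulary size.
#' @param seed integer seed.
#' @export
classifier_params <- function(d, d_z = 2048L, n_answers, seed = 1L) {
  with_seed(seed, list(
    W_x = matrix(stats::rnorm(d * d_z, sd = 1 / sqrt(d)), d, d_z),
    W_y = matrix(stats::rnorm(d * d_z, sd = 1 / sqrt(d)), d, d_z),
    ln = init_layernorm(d_z),
    out = init_linear(d_z, n_answers)))
}

#' Additive-projection classifier head
#'
#' Computes `z = LN(W_x' x + W_y' y)`, applies the final linear map, and
#' returns logits, softmax probabilities, and the arg-max prediction. The
#' categorical cross-entropy against a label index is the training loss hook.
#'
#' @param x attended image vector.
#' @param y attended question vector.
#' @param params a [classifier_params()].
#' @param label optional ground-truth answer index for the loss.
#' @return a `vqa_fusion_output`: list with `logits`, `probabilities`,
#'   `prediction` (1-based index), and `loss` when `label` is given.
#' @export
classifier_head <- function(x, y, params, label = NULL) {
  ovqa_assert(length(x) == nrow(params$W_x) && length(y) == nrow(params$W_y),
              "classifier head dimension mismatch")
  z0 <- matrix(as.numeric(x %*% params$W_x + y %*% params$W_y), 1)
  z <- layernorm_fwd(z0, params$ln)$out
  logits <- as.numeric(linear_fwd(z, params$out)$out)
  probs <- softmax_vec(logits)
  out <- list(logits = logits, probabilities = probs,
              prediction = which.max(logits))
  if (!is.null(label)) out$loss <- cross_entropy(logits, label)$loss
  structure(out, class = "vqa_fusion_output")
}

#' Parameter-count report for a fusion configuration
#'
#' Compares the decomposed model's parameter count with the full
#' `d_q * d_v * |A|` bilinear tensor it replaces.
#'
#' @param params a [tucker_params()].
#' @return list with `decomposed`, `full_tensor`, and `ratio`.
#' @export
fusion_param_report <- function(params) {
  dec <- count_params(tucker_trainables(params))
  full <- as.double(params$d_q) * params$d_v * params$n_answers + params$n_answers
  list(decomposed = dec, full_tensor = full, ratio = dec / full)
}
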