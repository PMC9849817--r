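# fusion: Tucker-decomposed bilinear pooling, squared variant, low-rank core,
# full-tensor oracle, baselines, classifier head

small_params <- function(seed, rank = 2L, glimpses = 1L)
  tucker_params(d_q = 3, d_v = 4, n_answers = 5, t_q = 2, t_v = 2, t_o = 3,
                rank = rank, glimpses = glimpses, seed = seed)

test_that("tucker_fuse agrees with the full-tensor oracle", {
  for (s in 1:20) {
    p <- small_params(s)
    set.seed(s + 1000)
    q <- rnorm(3); v <- rnorm(4)
    expect_lt(max(abs(tucker_fuse(q, v, p) - full_bilinear_oracle(q, v, p))), 1e-8)
    expect_lt(max(abs(squared_tucker_fuse(q, v, p) -
                        full_bilinear_oracle(q, v, p, squared = TRUE))), 1e-8)
  }
  # single nonzero core entry with identity-like factors: logit_k = q_i * v_j
  p <- small_params(1)
  p$W_q <- diag(1, 3, 2); p$W_v <- diag(1, 4, 2); p$W_o <- diag(1, 5, 3)
  p$b_f <- rep(0, 5)
  p$core$A <- matrix(0, 2, 6); p$core$B <- matrix(0, 2, 6)
  p$core$A[1, 3] <- 1; p$core$B[2, 3] <- 1   # Tc[1, 2, 2] = 1
  q <- c(2, 0, 7); v <- c(0, 3, 0, 9)
  expect_equal(full_bilinear_oracle(q, v, p),
               c(0, q[1] * v[2], 0, 0, 0))
  expect_equal(tucker_fuse(q, v, p), c(0, q[1] * v[2], 0, 0, 0))
  # zero core -> logits = b_f
  p$core$A[] <- 0
  p$b_f <- rnorm(5)
  expect_equal(full_bilinear_oracle(rnorm(3), rnorm(4), p), p$b_f)
})

test_that("fusion is multilinear in its arguments", {
  p <- small_params(3)
  set.seed(3)
  q <- rnorm(3); v <- rnorm(4); c_ <- 2.7
  b <- p$b_f
  # q = 0 -> logits = b_f exactly, both variants
  expect_equal(tucker_fuse(numeric(3), v, p), b)
  expect_equal(squared_tucker_fuse(numeric(3), v, p), b)
  # linear in q
  expect_equal(tucker_fuse(c_ * q, v, p) - b, c_ * (tucker_fuse(q, v, p) - b),
               tolerance = 1e-10)
  # linear in v for the plain variant, quadratic for the squared variant
  expect_equal(tucker_fuse(q, c_ * v, p) - b, c_ * (tucker_fuse(q, v, p) - b),
               tolerance = 1e-10)
  expect_equal(squared_tucker_fuse(q, c_ * v, p) - b,
               c_^2 * (squared_tucker_fuse(q, v, p) - b), tolerance = 1e-10)
  # even in v: the squared variant is unchanged under v -> -v
  expect_equal(squared_tucker_fuse(q, -v, p), squared_tucker_fuse(q, v, p))
  # all-ones projected image vector makes both variants coincide
  p1 <- small_params(5)
  vp_target <- rep(1, p1$t_v)
  v_src <- qr.solve(t(p1$W_v), vp_target)     # d_v = 4 >= t_v = 2
  expect_equal(squared_tucker_fuse(q, v_src, p1), tucker_fuse(q, v_src, p1),
               tolerance = 1e-8)
  expect_error(tucker_fuse(rnorm(2), v, p), class = "orchardvqa_invalid_input")
})

test_that("low-rank core construction honours rank and parameter count", {
  core <- build_lowrank_core(2, 2, 1, rank = 1, seed = 4)
  expect_equal(qr(core_to_array(core)[, , 1])$rank, 1L)
  expect_equal(count_params(list(core$A, core$B)), 1 * 1 * (2 + 2))
  core2 <- build_lowrank_core(3, 5, 4, rank = 2, seed = 6)
  expect_equal(count_params(list(core2$A, core2$B)), 4 * 2 * (3 + 5))
  for (o in 1:4)
    expect_lte(qr(core_to_array(core2)[, , o])$rank, 2L)
  # R >= min(t_q, t_v): slices can represent any matrix (least-squares fit)
  set.seed(8)
  target <- matrix(rnorm(12), 3, 4)
  a <- matrix(rnorm(9), 3, 3)                  # R = 3 = t_q, generic
  bt <- solve(a, target)                       # target = a %*% bt exactly
  expect_lt(max(abs(a %*% bt - target)), 1e-6)
})

test_that("analytic fusion gradients match finite differences", {
  for (squared in c(FALSE, TRUE)) {
    p <- small_params(11)
    set.seed(11)
    q <- rnorm(3); v <- rnorm(4)
    d_logits <- rnorm(5)
    fwd <- orchardvqa:::tucker_fwd(q, v, p, squared)
    bwd <- orchardvqa:::tucker_bwd(d_logits, fwd$cache, p)
    tr <- orchardvqa:::tucker_trainables(p)
    flat <- orchardvqa:::tree_flatten(tr)
    gflat <- orchardvqa:::tree_flatten(bwd$grads)
    loss_of <- function(vals) {
      tr2 <- orchardvqa:::tree_unflatten(tr, vals)
      p2 <- orchardvqa:::tucker_set_trainables(p, tr2)
      sum(orchardvqa:::tucker_fwd(q, v, p2, squared)$out * d_logits)
    }
    eps <- 1e-6
    idx <- seq(1, length(flat), by = 3)
    num <- vapply(idx, function(i) {
      up <- flat; up[i] <- up[i] + eps
      dn <- flat; dn[i] <- dn[i] - eps
      (loss_of(up) - loss_of(dn)) / (2 * eps)
    }, 0)
    expect_lt(max(abs(num - gflat[idx])), 1e-4)
    # input gradients too
    numq <- vapply(1:3, function(i) {
      qu <- q; qu[i] <- qu[i] + eps
      qd <- q; qd[i] <- qd[i] - eps
      (sum(orchardvqa:::tucker_fwd(qu, v, p, squared)$out * d_logits) -
         sum(orchardvqa:::tucker_fwd(qd, v, p, squared)$out * d_logits)) / (2 * eps)
    }, 0)
    expect_lt(max(abs(numq - as.numeric(bwd$d_q))), 1e-4)
  }
})

test_that("glimpse concatenation widens the image projection", {
  p <- small_params(13, glimpses = 3L)
  expect_equal(ncol(p$W_v), 2L * 3L)
  expect_equal(p$t_v, 6L)
  q <- rnorm(3); v <- rnorm(4)
  expect_lt(max(abs(tucker_fuse(q, v, p) - full_bilinear_oracle(q, v, p))), 1e-8)
})

test_that("baseline fusions behave as declared", {
  q <- rnorm(3); v <- rnorm(4)
  pc <- baseline_params(3, 4, out_dim = 6, mode = "concat", seed = 2)
  expect_equal(nrow(pc$W_c), 7)                # pre-projection length 3 + 4
  expect_length(baseline_fuse(q, v, pc, "concat"), 6)
  pm <- baseline_params(3, 4, out_dim = 6, mode = "mlb", seed = 2)
  expect_equal(baseline_fuse(numeric(3), v, pm, "mlb"), numeric(6))
  pt <- small_params(17)
  expect_identical(baseline_fuse(q, v, pt, "mutan"), tucker_fuse(q, v, pt))
  expect_error(baseline_fuse(q, v, pc, "fft"))
})

test_that("classifier head normalizes, classifies, and reports a loss", {
  set.seed(19)
  p <- classifier_params(d = 6, d_z = 10, n_answers = 4, seed = 3)
  x <- rnorm(6); y <- rnorm(6)
  out <- classifier_head(x, y, p, label = 2L)
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-12)
  expect_true(all(out$probabilities > 0))
  expect_equal(out$prediction, which.max(out$logits))
  expect_equal(out$loss, -log(out$probabilities[2]))
  # uniform logits -> uniform probabilities
  pu <- p
  pu$out$W[] <- 0; pu$out$b[] <- 1.3
  expect_equal(classifier_head(x, y, pu)$probabilities, rep(0.25, 4))
  # pre-affine layer-norm output has mean 0 and unit variance
  z0 <- matrix(as.numeric(x %*% p$W_x + y %*% p$W_y), 1)
  ln <- orchardvqa:::layernorm_fwd(z0, orchardvqa:::init_layernorm(10))
  expect_lt(abs(mean(ln$out)), 1e-6)
  expect_equal(mean(ln$out^2), 1, tolerance = 1e-6)
  expect_error(classifier_head(rnorm(5), y, p), class = "orchardvqa_invalid_input")
})

test_that("the decomposition shrinks the parameter count at published scale", {
  # reference dims: 2400-D question, 2048-D image, core 512, R = 15
  p <- tucker_params(d_q = 2400, d_v = 2048, n_answers = 100,
                     t_q = 512, t_v = 512, t_o = 512, rank = 15, seed = 1)
  rep_ <- fusion_param_report(p)
  expect_lt(rep_$decomposed, rep_$full_tensor)
  expect_equal(rep_$decomposed,
               2400 * 512 + 2048 * 512 + 512 * 15 * (512 + 512) +
                 100 * 512 + 100)
})
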