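# coattention: multi-head attention, SA/CA units, MCA stacking, attended
# reduction

cfg8 <- attn_config(heads = 2, hidden = 8, L = 1, dropout = 0)

test_that("attention rows are probability vectors and collapse to uniform on ties", {
  set.seed(1)
  q <- matrix(rnorm(3 * 8), 3)
  k <- matrix(rep(rnorm(8), 4), 4, byrow = TRUE)   # identical keys
  v <- matrix(rnorm(4 * 8), 4)
  out <- multi_head_attention(q, k, v, cfg8, seed = 2)
  for (a in attr(out, "attention")) {
    expect_equal(rowSums(a), rep(1, 3), tolerance = 1e-12)
    expect_true(all(a >= 0))
    expect_equal(a, matrix(0.25, 3, 4), tolerance = 1e-12)  # equal scores
  }
  # masked keys get zero weight, rows still sum to 1
  km <- c(TRUE, FALSE, TRUE, TRUE)
  out_m <- multi_head_attention(q, k, v, cfg8, seed = 2, key_mask = km)
  for (a in attr(out_m, "attention")) {
    expect_equal(unname(a[, 2]), rep(0, 3))
    expect_equal(rowSums(a), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("single-head attention equals the direct-formula oracle", {
  set.seed(7)
  cfg1 <- attn_config(heads = 1, hidden = 6, L = 1, dropout = 0)
  p <- orchardvqa:::with_seed(3, orchardvqa:::init_mha_params(6))
  q <- matrix(rnorm(4 * 6), 4)
  k <- matrix(rnorm(5 * 6), 5)
  v <- matrix(rnorm(5 * 6), 5)
  got <- multi_head_attention(q, k, v, cfg1, params = p)
  expect_equal(unclass(got), oracle_attention(q, k, v, p),
               tolerance = 1e-6, ignore_attr = TRUE)
  km <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  got_m <- multi_head_attention(q, k, v, cfg1, params = p, key_mask = km)
  expect_equal(unclass(got_m), oracle_attention(q, k, v, p, km),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("SA and CA units are the identity at zero sublayer weights", {
  set.seed(5)
  x <- matrix(rnorm(4 * 8), 4)
  y <- matrix(rnorm(3 * 8), 3)
  p_sa <- zero_params(orchardvqa:::init_sa_params(cfg8))
  p_sa$ln1$gamma <- rep(1, 8); p_sa$ln2$gamma <- rep(1, 8)  # LN stays usable
  expect_equal(unclass(sa_unit(x, cfg8, params = p_sa)), x, ignore_attr = TRUE)
  p_ca <- zero_params(orchardvqa:::init_ca_params(cfg8))
  p_ca$ln_q$gamma <- rep(1, 8); p_ca$ln_kv$gamma <- rep(1, 8)
  p_ca$ln2$gamma <- rep(1, 8)
  expect_equal(unclass(ca_unit(x, y, cfg8, params = p_ca)), x, ignore_attr = TRUE)
  # the full stack inherits the identity
  st_p <- lapply(init_mca_params(attn_config(heads = 2, hidden = 8, L = 2,
                                             dropout = 0)),
                 function(layer) lapply(layer, zero_params))
  st <- mca_stack(x, y, attn_config(heads = 2, hidden = 8, L = 2, dropout = 0),
                  params = st_p)
  expect_equal(st$x, x)
  expect_equal(st$y, y)
})

test_that("units preserve shape and respect masks", {
  set.seed(11)
  for (t in c(1, 3, 7)) {
    s <- matrix(rnorm(t * 8), t)
    expect_equal(dim(sa_unit(s, cfg8, seed = 1)), c(t, 8L))
  }
  # perturbing a masked token's values leaves other positions unchanged
  s <- matrix(rnorm(5 * 8), 5)
  mask <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  base <- sa_unit(s, cfg8, mask = mask, seed = 4)
  s2 <- s
  s2[3, ] <- rnorm(8) * 10
  pert <- sa_unit(s2, cfg8, mask = mask, seed = 4)
  expect_equal(unclass(base)[-3, ], unclass(pert)[-3, ], tolerance = 1e-10)
})

test_that("guided attention with a single key attends it fully and matches the oracle", {
  set.seed(13)
  cfg1 <- attn_config(heads = 1, hidden = 4, L = 1, dropout = 0)
  x <- matrix(rnorm(3 * 4), 3)
  y1 <- matrix(rnorm(4), 1)
  out <- ca_unit(x, y1, cfg1, seed = 9)
  for (a in attr(out, "attention"))
    expect_equal(unname(a), matrix(1, 3, 1))
  # random 3x4 guided-attention equivalence with the direct formula
  p <- orchardvqa:::with_seed(21, orchardvqa:::init_ca_params(cfg1))
  y <- matrix(rnorm(4 * 4), 4)
  got <- ca_unit(x, y, cfg1, params = p)
  lq <- orchardvqa:::layernorm_fwd(x, p$ln_q, cfg1$eps)$out
  lkv <- orchardvqa:::layernorm_fwd(y, p$ln_kv, cfg1$eps)$out
  att <- oracle_attention(lq, lkv, lkv, p$mha)
  u <- x + att
  l2 <- orchardvqa:::layernorm_fwd(u, p$ln2, cfg1$eps)$out
  ff <- pmax(l2 %*% p$ffn$w1$W + rep(p$ffn$w1$b, each = 3), 0) %*% p$ffn$w2$W +
    rep(p$ffn$w2$b, each = 3)
  expect_equal(unclass(got), u + ff, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("MCA stacking composes SA(Y), SA(X), CA(X, Y) and deepens with L", {
  set.seed(17)
  x <- matrix(rnorm(4 * 8), 4)
  y <- matrix(rnorm(3 * 8), 3)
  p1 <- init_mca_params(cfg8, seed = 2)
  st <- mca_stack(x, y, cfg8, params = p1)
  y_exp <- sa_unit(y, cfg8, params = p1[[1]]$sa_y)
  x_exp <- sa_unit(x, cfg8, params = p1[[1]]$sa_x)
  x_exp <- ca_unit(x_exp, y_exp, cfg8, params = p1[[1]]$ca_x)
  expect_equal(st$x, unclass(x_exp), ignore_attr = TRUE)
  expect_equal(st$y, unclass(y_exp), ignore_attr = TRUE)
  # parameter count strictly increases over the published depth grid
  counts <- vapply(c(1L, 2L, 4L, 6L), function(L)
    count_params(init_mca_params(attn_config(heads = 2, hidden = 8, L = L))),
    0)
  expect_true(all(diff(counts) > 0))
  expect_equal(attn_config()$L, 4L)   # default depth
  expect_error(attn_config(L = 0), class = "orchardvqa_invalid_config")
})

test_that("stack output is permutation-equivariant over image positions", {
  set.seed(23)
  x <- matrix(rnorm(5 * 8), 5)
  y <- matrix(rnorm(3 * 8), 3)
  p <- init_mca_params(cfg8, seed = 6)
  st <- mca_stack(x, y, cfg8, params = p)
  perm <- c(4, 1, 5, 2, 3)
  st_p <- mca_stack(x[perm, ], y, cfg8, params = p)
  expect_equal(st_p$x, st$x[perm, ], tolerance = 1e-10)
  expect_equal(st_p$y, st$y, tolerance = 1e-10)
})

test_that("attended_reduce averages under uniform scores and selects single rows", {
  set.seed(29)
  s <- matrix(rnorm(4 * 6), 4)
  out <- attended_reduce(s)                       # zero-init scores -> mean
  expect_equal(unclass(out), colMeans(s), ignore_attr = TRUE)
  expect_equal(sum(attr(out, "weights")), 1)
  m <- c(FALSE, TRUE, FALSE, FALSE)
  expect_equal(unclass(attended_reduce(s, mask = m)), s[2, ], ignore_attr = TRUE)
  expect_error(attended_reduce(s, mask = rep(FALSE, 4)),
               class = "orchardvqa_invalid_input")
  # learned scores: weights still sum to 1 and weight the rows
  p <- list(w = rnorm(6), b = 0.3)
  out2 <- attended_reduce(s, params = p)
  a <- attr(out2, "weights")
  expect_equal(sum(a), 1)
  expect_equal(unclass(out2), as.numeric(crossprod(s, a)), ignore_attr = TRUE)
})

test_that("stack gradients match finite differences on a small instance", {
  set.seed(31)
  cfg <- attn_config(heads = 2, hidden = 6, L = 1, dropout = 0)
  p <- init_mca_params(cfg, seed = 8)
  x <- matrix(rnorm(3 * 6), 3)
  y <- matrix(rnorm(2 * 6), 2)
  loss_of <- function(params) {
    st <- orchardvqa:::mca_stack_fwd(x, y, params, cfg)
    sum(st$x^2) + sum(st$y * 0.5)
  }
  fwd <- orchardvqa:::mca_stack_fwd(x, y, p, cfg)
  bwd <- orchardvqa:::mca_stack_bwd(2 * fwd$x, matrix(0.5, nrow(y), 6),
                                    fwd$caches, p, cfg)
  flat <- orchardvqa:::tree_flatten(p)
  gflat <- orchardvqa:::tree_flatten(bwd$grads)
  idx <- sort(sample(length(flat), 25))
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    (loss_of(orchardvqa:::tree_unflatten(p, up)) -
       loss_of(orchardvqa:::tree_unflatten(p, dn))) / (2 * eps)
  }, 0)
  expect_lt(max(abs(num - gflat[idx])), 1e-5)
})
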