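# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by direct enumeration / the textbook formula, not by the
# package's own code paths.

# Otsu: exhaustive scan of all 256 thresholds maximizing between-class
# variance, computed from first principles on the raw pixel vector.
oracle_otsu <- function(gray_values) {
  g <- pmin(pmax(round(gray_values), 0), 255)
  best_t <- 0L
  best_v <- -Inf
  for (t in 0:255) {
    c0 <- g[g <= t]
    c1 <- g[g > t]
    if (length(c0) == 0 || length(c1) == 0) next
    w0 <- length(c0) / length(g)
    v <- w0 * (1 - w0) * (mean(c0) - mean(c1))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# brute-force binary erosion/dilation/opening with a rectangular SE whose
# anchor matches the package convention (centre, even sizes biased up-left),
# out-of-frame treated as background
oracle_opening <- function(mask, sh, sw) {
  h <- nrow(mask); w <- ncol(mask)
  up <- (sh - 1) %/% 2; down <- sh - 1 - up
  left <- (sw - 1) %/% 2; right <- sw - 1 - left
  er <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rs <- (i - up):(i + down); cs <- (j - left):(j + right)
    if (min(rs) < 1 || max(rs) > h || min(cs) < 1 || max(cs) > w) next
    er[i, j] <- all(mask[rs, cs])
  }
  di <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    rs <- (i - down):(i + up); cs <- (j - right):(j + left)
    rs <- rs[rs >= 1 & rs <= h]; cs <- cs[cs >= 1 & cs <= w]
    di[i, j] <- any(er[rs, cs])
  }
  di
}

# direct single-head scaled dot-product attention from the formula
oracle_attention <- function(q, k, v, w, key_mask = NULL) {
  qp <- q %*% w$wq$W + rep(w$wq$b, each = nrow(q))
  kp <- k %*% w$wk$W + rep(w$wk$b, each = nrow(k))
  vp <- v %*% w$wv$W + rep(w$wv$b, each = nrow(v))
  km <- if (is.null(key_mask)) rep(TRUE, nrow(k)) else key_mask
  s <- qp %*% t(kp) / sqrt(ncol(qp))
  out <- matrix(0, nrow(q), ncol(vp))
  for (i in seq_len(nrow(s))) {
    sc <- s[i, ]
    sc[!km] <- -Inf
    e <- exp(sc - max(sc[km]))
    e[!km] <- 0
    out[i, ] <- colSums(vp * (e / sum(e)))
  }
  out %*% w$wo$W + rep(w$wo$b, each = nrow(q))
}

# set every weight leaf of a parameter tree to zero
zero_params <- function(p) orchardvqa:::tree_map(function(x) x * 0, p)

make_tiny_corpus <- function(n_images = 12, seed = 7, all_train = FALSE,
                             image_size = 48, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  cfg <- synth_config(n_images = n_images, image_size = image_size, seed = seed)
  split <- if (all_train) split_spec(0, 0, seed = seed)
           else split_spec(n_images %/% 10, n_images %/% 10, seed = seed)
  list(manifest = generate_synthetic_corpus(cfg, dir, split = split),
       cfg = cfg, dir = dir)
}
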