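# Full VQA model: linear input projections into the shared hidden space,
# the stacked modular co-attention module, attended reductions to the pooled
# vectors x~ (image) and y~ (question), and a fusion head over the answer
# vocabulary. Forward and reverse passes are explicit so the AdamW engine can
# train the whole composition.

#' Model configuration
#'
#' @param attn an [attn_config()] (desk-scale defaults differ from the
#'   publication-scale 8-head / 512-hidden / L = 4 reference, which remains
#'   one `attn_config()` call away).
#' @param fusion_variant one of `"tucker_squared"` (default; element-wise
#'   squared image projection), `"tucker"`, `"mutan"` (alias of `"tucker"`),
#'   `"mlb"`, `"concat"`.
#' @param t_q,t_v,t_o Tucker core dimensions.
#' @param rank low-rank core constraint R.
#' @param glimpses image projection glimpse count G.
#' @export
model_config <- function(attn = attn_config(), fusion_variant = "tucker_squared",
                         t_q = 64L, t_v = 64L, t_o = 64L, rank = 8L,
                         glimpses = 1L) {
  ovqa_assert(fusion_variant %in% c("tucker", "tucker_squared", "mutan", "mlb", "concat"),
              sprintf("unknown fusion variant '%s'", fusion_variant))
  list(attn = attn, fusion_variant = fusion_variant,
       t_q = as.integer(t_q), t_v = as.integer(t_v), t_o = as.integer(t_o),
       rank = as.integer(rank), glimpses = as.integer(glimpses))
}

#' Build a VQA model
#'
#' @param answer_vocab ordered answer vocabulary.
#' @param d_image image feature channels K (per grid position).
#' @param d_question question feature dimension J (per token).
#' @param cfg a [model_config()].
#' @param seed integer seed for all weight draws.
#' @return a `vqa_model` holding the parameter tree, the configuration and
#'   the vocabulary.
#' @export
build_vqa_model <- function(answer_vocab, d_image, d_question,
                            cfg = model_config(), seed = 1L) {
  h <- cfg$attn$hidden
  n <- length(answer_vocab)
  ovqa_assert(n >= 2, "answer vocabulary must hold at least 2 answers")
  fusion <- switch(cfg$fusion_variant,
    tucker = , tucker_squared = , mutan =
      tucker_trainables(tucker_params(h, h, n, cfg$t_q, cfg$t_v, cfg$t_o,
                                      cfg$rank, cfg$glimpses,
                                      seed = derive_seed(seed, "fusion"))),
    mlb = with_seed(derive_seed(seed, "fusion"), c(
      baseline_params(h, h, cfg$t_o, "mlb", seed = derive_seed(seed, "mlbp")),
      list(W_o = matrix(stats::rnorm(n * cfg$t_o, sd = 1 / sqrt(cfg$t_o)), n, cfg$t_o),
           b_f = rep(0, n)))),
    concat = with_seed(derive_seed(seed, "fusion"), c(
      baseline_params(h, h, cfg$t_o, "concat", seed = derive_seed(seed, "conp")),
      list(W_o = matrix(stats::rnorm(n * cfg$t_o, sd = 1 / sqrt(cfg$t_o)), n, cfg$t_o),
           b_f = rep(0, n)))))
  params <- with_seed(seed, list(
    proj_x = init_linear(d_image, h),
    proj_y = init_linear(d_question, h),
    stack = init_mca_params(cfg$attn, seed = derive_seed(seed, "stack")),
    red_x = init_reduce_params(h),
    red_y = init_reduce_params(h),
    fusion = fusion))
  structure(list(params = params, cfg = cfg, answer_vocab = answer_vocab,
                 d_image = as.integer(d_image), d_question = as.integer(d_question)),
            class = "vqa_model")
}

#' @export
print.vqa_model <- function(x, ...) {
  cat("VQA model:", count_params(x$params), "parameters |",
      x$cfg$fusion_variant, "fusion | L =", x$cfg$attn$L,
      "| hidden =", x$cfg$attn$hidden, "\n")
  invisible(x)
}

# fusion head on the pooled pair (y~ = question, x~ = image) -> logits
fusion_head_fwd <- function(model, y_vec, x_vec) {
  cfg <- model$cfg
  f <- model$params$fusion
  h <- cfg$attn$hidden
  n <- length(model$answer_vocab)
  if (cfg$fusion_variant %in% c("tucker", "tucker_squared", "mutan")) {
    tp <- tucker_set_trainables(
      tucker_params(h, h, n, cfg$t_q, cfg$t_v, cfg$t_o, cfg$rank, cfg$glimpses,
                    seed = 0L), f)
    r <- tucker_fwd(y_vec, x_vec, tp, squared = cfg$fusion_variant == "tucker_squared")
    list(logits = as.numeric(r$out), cache = list(kind = "tucker", r = r, tp = tp))
  } else if (cfg$fusion_variant == "mlb") {
    qp <- as.numeric(y_vec %*% f$W_q)
    vp <- as.numeric(x_vec %*% f$W_v)
    fused <- qp * vp
    list(logits = as.numeric(f$W_o %*% fused) + f$b_f,
         cache = list(kind = "mlb", qp = qp, vp = vp, fused = fused,
                      y = y_vec, x = x_vec))
  } else { # concat
    z <- c(y_vec, x_vec)
    fused <- as.numeric(z %*% f$W_c) + f$b_c
    list(logits = as.numeric(f$W_o %*% fused) + f$b_f,
         cache = list(kind = "concat", z = z, fused = fused))
  }
}

fusion_head_bwd <- function(model, d_logits, cache) {
  f <- model$params$fusion
  h <- model$cfg$attn$hidden
  if (cache$kind == "tucker") {
    b <- tucker_bwd(d_logits, cache$r$cache, cache$tp)
    list(d_y = as.numeric(b$d_q), d_x = as.numeric(b$d_v), grads = b$grads)
  } else if (cache$kind == "mlb") {
    d_fused <- as.numeric(crossprod(f$W_o, d_logits))
    d_qp <- d_fused * cache$vp
    d_vp <- d_fused * cache$qp
    list(d_y = as.numeric(f$W_q %*% d_qp),
         d_x = as.numeric(f$W_v %*% d_vp),
         grads = list(W_q = outer(cache$y, d_qp), W_v = outer(cache$x, d_vp),
                      W_o = outer(d_logits, cache$fused), b_f = d_logits))
  } else {
    d_fused <- as.numeric(crossprod(f$W_o, d_logits))
    d_z <- as.numeric(f$W_c %*% d_fused)
    list(d_y = d_z[seq_len(h)], d_x = d_z[h + seq_len(h)],
         grads = list(W_c = outer(cache$z, d_fused), b_c = d_fused,
                      W_o = outer(d_logits, cache$fused), b_f = d_logits))
  }
}

#' Run the model forward on one encoded example
#'
#' @param model a `vqa_model`.
#' @param x image feature grid (`P x K` matrix).
#' @param y question sequence features (`T x J` matrix, real tokens only).
#' @param training apply dropout.
#' @return list with `logits`, `probabilities`, `prediction` (index into the
#'   answer vocabulary), per-layer attention maps in `attn`, and (internal)
#'   caches for the backward pass.
#' @export
vqa_forward <- function(model, x, y, training = FALSE) {
  p <- model$params
  cfg <- model$cfg$attn
  ovqa_assert(nrow(y) >= 1, "question sequence is empty")
  px <- linear_fwd(x, p$proj_x)
  py <- linear_fwd(y, p$proj_y)
  st <- mca_stack_fwd(px$out, py$out, p$stack, cfg, training = training)
  rx <- reduce_fwd(st$x, p$red_x)
  ry <- reduce_fwd(st$y, p$red_y)
  fh <- fusion_head_fwd(model, ry$out, rx$out)
  list(logits = fh$logits, probabilities = softmax_vec(fh$logits),
       prediction = which.max(fh$logits), attn = st$attn,
       cache = list(px = px, py = py, st = st, rx = rx, ry = ry, fh = fh))
}

# gradients of the loss for one example; returns loss and the gradient tree
vqa_backward <- function(model, fwd, label_idx) {
  p <- model$params
  cfg <- model$cfg$attn
  ce <- cross_entropy(fwd$logits, label_idx)
  bf <- fusion_head_bwd(model, ce$d_logits, fwd$cache$fh$cache)
  brx <- reduce_bwd(bf$d_x, fwd$cache$rx$cache, p$red_x)
  bry <- reduce_bwd(bf$d_y, fwd$cache$ry$cache, p$red_y)
  bs <- mca_stack_bwd(brx$d_in, bry$d_in, fwd$cache$st$caches, p$stack, cfg)
  bpx <- linear_bwd(bs$d_x, fwd$cache$px, p$proj_x)
  bpy <- linear_bwd(bs$d_y, fwd$cache$py, p$proj_y)
  list(loss = ce$loss,
       grads = list(proj_x = bpx$grads, proj_y = bpy$grads, stack = bs$grads,
                    red_x = brx$grads, red_y = bry$grads, fusion = bf$grads))
}

#' Encode the inputs of every annotated record in a manifest
#'
#' Reads each image once, encodes it with the image contract, tokenizes and
#' encodes each question, and collapses the annotations to the majority
#' label. Used by the training and evaluation engine.
#'
#' @param manifest a `vqa_manifest` whose records carry readable image paths.
#' @param image_contract an [image_encoder_contract()].
#' @param question_mode question encoder mode (see [encode_question()]).
#' @param question_dim tiny-encoder dimension J.
#' @param vocab optional word-piece vocabulary (trained on the manifest's
#'   train questions when `NULL`).
#' @param splits which splits to encode.
#' @param seed seed forwarded to stochastic backbones.
#' @return list with `examples` (one per record: features, label index, type,
#'   split, question id, candidates) and `vocab`.
#' @export
prepare_examples <- function(manifest, image_contract = image_encoder_contract("tiny"),
                             question_mode = "tiny", question_dim = 32L,
                             vocab = NULL, splits = c("train", "val"), seed = 1L) {
  recs <- Filter(function(r) r$split %in% splits, manifest$records)
  ovqa_assert(length(recs) > 0, "no records in the requested splits")
  if (is.null(vocab)) {
    train_q <- vapply(Filter(function(r) r$split == "train", manifest$records),
                      `[[`, "", "question")
    vocab <- train_wordpiece_vocab(train_q)
  }
  grids <- new.env(parent = emptyenv())
  examples <- lapply(recs, function(r) {
    g <- get0(r$image_id, envir = grids)
    if (is.null(g)) {
      img <- read_ppm(r$image_path)
      g <- encode_image(img, image_contract, seed = seed)
      assign(r$image_id, g, envir = grids)
    }
    qf <- encode_question(tokenize_and_pad(r$question, vocab), question_mode,
                          question_dim)
    label <- record_label(r)
    list(x = g$grid, y = qf$sequence, question_id = r$question_id,
         question_type = r$question_type, split = r$split,
         label = label, label_idx = match(label, manifest$answer_vocab),
         candidates = r$candidates)
  })
  list(examples = examples, vocab = vocab,
       d_image = image_contract$channels,
       d_question = question_encoder_contract(question_mode, question_dim)$J)
}
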