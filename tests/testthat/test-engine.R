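# engine: training loop, prediction modes, strict-accuracy reports, k-fold
# cross-validation, confusion statistics

tiny_setup <- function(n_images = 8, seed = 3, all_train = FALSE,
                       env = parent.frame()) {
  fx <- make_tiny_corpus(n_images = n_images, seed = seed,
                         all_train = all_train, env = env)
  prep <- prepare_examples(fx$manifest, image_encoder_contract("tiny"),
                           "tiny", 12L)
  mcfg <- model_config(attn = attn_config(heads = 2, hidden = 16, L = 1,
                                          dropout = 0),
                       t_q = 16, t_v = 16, t_o = 16, rank = 2)
  model <- build_vqa_model(fx$manifest$answer_vocab, prep$d_image,
                           prep$d_question, mcfg, seed = seed)
  list(fx = fx, prep = prep, model = model, mcfg = mcfg)
}

test_that("zero-epoch training returns the untrained model with empty history", {
  s <- tiny_setup()
  fit <- train_vqa(s$model, s$prep$examples, train_config(max_epochs = 0))
  expect_identical(fit$model$params, s$model$params)
  expect_equal(nrow(fit$history), 0)
  expect_equal(fit$best_epoch, 0L)
})

test_that("training is deterministic given one seed and tracks the best epoch", {
  s <- tiny_setup(n_images = 10, seed = 9)
  cfg <- train_config(learning_rate = 3e-3, batch_size = 8, dropout = 0.2,
                      weight_decay = 0, max_epochs = 4, seed = 12)
  f1 <- train_vqa(s$model, s$prep$examples, cfg)
  f2 <- train_vqa(s$model, s$prep$examples, cfg)
  expect_identical(f1$history$loss, f2$history$loss)       # bitwise loss curve
  expect_identical(f1$model$params, f2$model$params)
  # early stopping never selects an epoch with worse val accuracy
  expect_equal(f1$history$val_accuracy[f1$best_epoch],
               max(f1$history$val_accuracy))
  # a different seed changes the trajectory
  f3 <- train_vqa(s$model, s$prep$examples,
                  train_config(learning_rate = 3e-3, batch_size = 8,
                               dropout = 0.2, weight_decay = 0,
                               max_epochs = 4, seed = 13))
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("training validates its inputs", {
  s <- tiny_setup()
  only_val <- Filter(function(e) e$split == "val", s$prep$examples)
  expect_error(train_vqa(s$model, only_val, train_config(max_epochs = 1)),
               class = "orchardvqa_invalid_input")
})

test_that("multiple-choice prediction restricts the arg-max to candidates", {
  s <- tiny_setup(n_images = 6, seed = 21, all_train = TRUE)
  e <- s$prep$examples[[1]]
  open_pred <- predict_vqa(s$model, e, mode = "open")
  expect_true(open_pred %in% s$model$answer_vocab)
  # candidates excluding the global arg-max force the best candidate
  vocab <- s$model$answer_vocab
  fwd <- vqa_forward(s$model, e$x, e$y)
  others <- vocab[vocab != vocab[fwd$prediction]]
  e$candidates <- utils::head(others, 4)
  mc_pred <- predict_vqa(s$model, e, mode = "mc")
  expect_true(mc_pred %in% e$candidates)
  expect_identical(mc_pred,
                   e$candidates[which.max(fwd$logits[match(e$candidates, vocab)])])
  # candidates outside the vocabulary fall back to the global arg-max
  e$candidates <- c("zz1", "zz2", "zz3", "zz4")
  expect_identical(predict_vqa(s$model, e, mode = "mc"), vocab[fwd$prediction])
})

test_that("strict accuracy recombines per-type accuracies by type counts", {
  s <- tiny_setup(n_images = 12, seed = 33, all_train = TRUE)
  rep_ <- evaluate_vqa(s$model, s$prep$examples, split = "train")
  expect_true(rep_$accuracy_overall >= 0 && rep_$accuracy_overall <= 1)
  ok <- !is.na(rep_$accuracy_by_type)
  expect_equal(sum(rep_$accuracy_by_type[ok] * rep_$n_by_type[ok]) /
                 sum(rep_$n_by_type[ok]),
               rep_$accuracy_overall, tolerance = 1e-12)
  expect_equal(sum(rep_$n_by_type), rep_$n)
  # purity: identical inputs give identical reports
  rep2 <- evaluate_vqa(s$model, s$prep$examples, split = "train")
  expect_identical(rep_$predictions, rep2$predictions)
})

test_that("evaluating an unlabeled split is refused with guidance", {
  s <- tiny_setup(n_images = 10, seed = 41)
  test_recs <- Filter(function(r) r$split == "test", s$fx$manifest$records)
  expect_gt(length(test_recs), 0)
  exs <- lapply(test_recs, function(r) {
    img <- read_ppm(r$image_path)
    g <- encode_image(img, image_encoder_contract("tiny"))
    qf <- encode_question(tokenize_and_pad(r$question, s$prep$vocab), "tiny", 12L)
    list(x = g$grid, y = qf$sequence, question_id = r$question_id,
         question_type = r$question_type, split = "test",
         label = NA_character_, label_idx = NA_integer_, candidates = r$candidates)
  })
  expect_error(evaluate_vqa(s$model, exs, split = "test"),
               class = "orchardvqa_unlabeled_split")
})

test_that("k-fold partitions are disjoint, covering, near-equal and seeded", {
  p10 <- kfold_partition(10, 10, seed = 1)
  expect_equal(sort(unique(p10)), 1:10)
  expect_true(all(table(p10) == 1))
  p103 <- kfold_partition(103, 10, seed = 2)
  expect_equal(length(p103), 103)
  expect_true(all(table(p103) %in% c(10, 11)))
  expect_equal(sum(table(p103)), 103)
  expect_identical(kfold_partition(50, 5, seed = 7), kfold_partition(50, 5, seed = 7))
  expect_false(identical(kfold_partition(50, 5, seed = 7),
                         kfold_partition(50, 5, seed = 8)))
  expect_error(kfold_partition(5, 6), class = "orchardvqa_invalid_input")
})

test_that("cross-validation rotates every fold through the test role", {
  s <- tiny_setup(n_images = 6, seed = 51, all_train = TRUE)
  factory <- function(seed) build_vqa_model(s$fx$manifest$answer_vocab,
                                            s$prep$d_image, s$prep$d_question,
                                            s$mcfg, seed = seed)
  res <- kfold_cross_validate(s$prep$examples, factory, k = 3, runs = 2,
                              cfg = train_config(learning_rate = 3e-3,
                                                 batch_size = 8, dropout = 0,
                                                 max_epochs = 1, seed = 1),
                              seed = 5)
  expect_length(res, 2)
  for (run in res) {
    expect_equal(nrow(run$folds), 3)
    expect_equal(sum(run$folds$n), length(s$prep$examples))
    expect_true(run$accuracy >= 0 && run$accuracy <= 1)
  }
  expect_false(identical(res[[1]]$partition, res[[2]]$partition))
})

test_that("confusion statistics compute the five indicators and aggregate", {
  runs <- list(
    list(pred = c(TRUE, TRUE, FALSE, FALSE), truth = c(TRUE, FALSE, TRUE, FALSE)),
    list(pred = c(TRUE, FALSE, TRUE, FALSE), truth = c(TRUE, FALSE, FALSE, FALSE))
  )
  cs <- confusion_stats(runs)
  expect_equal(cs$per_run$sensitivity, c(0.5, 1))
  expect_equal(cs$per_run$specificity, c(0.5, 2 / 3))
  expect_equal(cs$per_run$precision, c(0.5, 0.5))
  expect_equal(cs$per_run$accuracy, c(0.5, 0.75))
  expect_equal(cs$per_run$f1, c(0.5, 2 * 0.5 * 1 / 1.5))
  # sample SD (n - 1) oracle
  expect_equal(unname(cs$sd["accuracy"]), stats::sd(c(0.5, 0.75)))
  # zero denominators: TP = FN = 5, TN = FP = 0 -> specificity undefined
  degen <- list(list(pred = c(rep(TRUE, 5), rep(FALSE, 5)), truth = rep(TRUE, 10)))
  expect_warning(cs2 <- confusion_stats(degen), "zero denominator")
  expect_equal(cs2$per_run$sensitivity, 0.5)
  expect_true(is.na(cs2$per_run$specificity))
  # precomputed indicator rows aggregate with mean/sd oracles
  rows <- data.frame(sensitivity = c(90, 92, 95), specificity = c(88, 91, 90),
                     precision = c(89, 90, 91), accuracy = c(90, 91, 92),
                     f1 = c(89.5, 90.5, 91.5))
  cs3 <- confusion_stats(rows)
  expect_equal(unname(cs3$mean), unname(colMeans(rows)))
  expect_equal(unname(cs3$sd), unname(vapply(rows, stats::sd, 0)))
})
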