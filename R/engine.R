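# Training and evaluation engine: AdamW optimization with per-epoch
# checkpoints and early stopping on validation strict accuracy, prediction in
# open-ended and multiple-choice modes, strict-accuracy reports per question
# type, k-fold cross-validation, and confusion statistics for the yes/no
# classifier.

#' Training configuration
#'
#' Publication-scale defaults: AdamW with beta1 = 0.9, beta2 = 0.999,
#' learning rate 1e-4, mini-batch size 64, dropout 0.5, early stopping on
#' validation strict accuracy.
#'
#' @param learning_rate AdamW learning rate.
#' @param beta1,beta2 AdamW moment decays.
#' @param weight_decay decoupled weight decay.
#' @param batch_size mini-batch size.
#' @param dropout dropout rate applied during training.
#' @param lr_decay multiplicative per-epoch learning-rate decay factor
#'   (default 1 = constant rate).
#' @param max_epochs epoch budget (0 returns the untrained model).
#' @param patience early-stop patience in epochs without validation
#'   improvement (`Inf` disables).
#' @param seed integer seed governing init-independent training randomness
#'   (shuffles, dropout).
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 0.01, batch_size = 64L, dropout = 0.5,
                         lr_decay = 1, max_epochs = 10L, patience = Inf, seed = 1L) {
  ovqa_assert(learning_rate > 0 && batch_size >= 1 && max_epochs >= 0,
              "rates and sizes must be positive")
  list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
       weight_decay = weight_decay, batch_size = as.integer(batch_size),
       dropout = dropout, lr_decay = lr_decay, max_epochs = as.integer(max_epochs),
       patience = patience, seed = as.integer(seed))
}

example_accuracy <- function(model, examples) {
  if (length(examples) == 0) return(NA_real_)
  ok <- vapply(examples, function(e) {
    pred <- predict_vqa(model, e)
    identical(pred, e$label)
  }, logical(1))
  mean(ok)
}

#' Train a VQA model
#'
#' Minimizes the categorical cross-entropy with AdamW. After every epoch the
#' parameters are checkpointed and validation strict accuracy is measured;
#' the returned model carries the parameters of the best validation epoch
#' (the final epoch when no validation examples exist). Training is a pure
#' function of the model, data, and `cfg$seed`.
#'
#' @param model a [build_vqa_model()] model.
#' @param examples list of encoded examples from [prepare_examples()]; train
#'   examples are those with `split == "train"`, validation those with
#'   `split == "val"`.
#' @param cfg a [train_config()].
#' @param refit if `TRUE`, after epoch selection the model is refit once on
#'   train + validation examples for the selected number of epochs.
#' @return list with `model` (best checkpoint), `history` (data frame of
#'   epoch, mean loss, validation accuracy), and `best_epoch`.
#' @export
train_vqa <- function(model, examples, cfg = train_config(), refit = FALSE) {
  train_ex <- Filter(function(e) e$split == "train", examples)
  val_ex <- Filter(function(e) e$split == "val", examples)
  ovqa_assert(length(train_ex) > 0, "no training examples")
  ovqa_assert(all(vapply(train_ex, function(e) !is.na(e$label_idx), TRUE)),
              "training example with label outside the answer vocabulary")
  model$cfg$attn$dropout <- cfg$dropout
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  if (cfg$max_epochs == 0L)
    return(list(model = model, history = history, best_epoch = 0L))

  run_fit <- function(model, exs, n_epochs, track_val) {
    state <- adamw_init(model$params)
    best <- list(acc = -Inf, params = model$params, epoch = 0L)
    hist <- history
    stale <- 0L
    with_seed(cfg$seed, {
      for (epoch in seq_len(n_epochs)) {
        lr_e <- cfg$learning_rate * cfg$lr_decay^(epoch - 1L)
        idx <- sample(length(exs))
        losses <- numeric(0)
        for (start in seq(1, length(exs), by = cfg$batch_size)) {
          batch <- idx[start:min(start + cfg$batch_size - 1L, length(exs))]
          acc_grads <- NULL
          bl <- 0
          for (i in batch) {
            e <- exs[[i]]
            fwd <- vqa_forward(model, e$x, e$y, training = TRUE)
            bwd <- vqa_backward(model, fwd, e$label_idx)
            bl <- bl + bwd$loss
            acc_grads <- if (is.null(acc_grads)) bwd$grads
                         else tree_map2(`+`, acc_grads, bwd$grads)
          }
          if (!is.finite(bl))
            ovqa_stop("training diverged: non-finite loss", class = "divergence")
          acc_grads <- tree_map(function(g) g / length(batch), acc_grads)
          upd <- adamw_step(model$params, acc_grads, state,
                            lr = lr_e, beta1 = cfg$beta1,
                            beta2 = cfg$beta2, weight_decay = cfg$weight_decay)
          model$params <- upd$params
          state <- upd$state
          losses <- c(losses, bl / length(batch))
        }
        vacc <- if (track_val && length(val_ex) > 0)
          example_accuracy(model, val_ex) else NA_real_
        hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                       val_accuracy = vacc))
        if (!is.na(vacc)) {
          if (vacc > best$acc) {
            best <- list(acc = vacc, params = model$params, epoch = epoch)
            stale <- 0L
          } else {
            stale <- stale + 1L
            if (stale >= cfg$patience) break
          }
        } else {
          best <- list(acc = NA_real_, params = model$params, epoch = epoch)
        }
      }
    })
    list(model = model, best = best, history = hist)
  }

  fit <- run_fit(model, train_ex, cfg$max_epochs, track_val = TRUE)
  model <- fit$model
  model$params <- fit$best$params
  best_epoch <- fit$best$epoch
  if (refit && length(val_ex) > 0) {
    refit_model <- model
    refit_model$params <- tree_map(identity, model$params)
    re <- run_fit(refit_model, c(train_ex, val_ex), max(best_epoch, 1L),
                  track_val = FALSE)
    model <- re$model
  }
  list(model = model, history = fit$history, best_epoch = best_epoch)
}

#' Predict the answer for one encoded example
#'
#' Open-ended mode takes the arg-max over the full answer vocabulary;
#' multiple-choice mode restricts the arg-max to the example's four candidate
#' answers (candidates missing from the vocabulary are unscorable and are
#' dropped; if none remain, the global arg-max is returned). Ties resolve to
#' the lowest index.
#'
#' @param model a `vqa_model`.
#' @param example one encoded example from [prepare_examples()].
#' @param mode `"open"` or `"mc"`.
#' @return predicted answer string.
#' @export
predict_vqa <- function(model, example, mode = c("open", "mc")) {
  mode <- match.arg(mode)
  fwd <- vqa_forward(model, example$x, example$y, training = FALSE)
  vocab <- model$answer_vocab
  if (mode == "mc" && !is.null(example$candidates)) {
    cand_idx <- match(example$candidates, vocab)
    cand_idx <- cand_idx[!is.na(cand_idx)]
    if (length(cand_idx) > 0) {
      return(vocab[cand_idx[which.max(fwd$logits[cand_idx])]])
    }
  }
  vocab[fwd$prediction]
}

#' Strict-accuracy evaluation report
#'
#' Exact string-match accuracy of the predictions against the collapsed
#' majority labels, overall and per question type. Overall accuracy equals
#' the question-count-weighted mean of the per-type accuracies.
#'
#' @param model a `vqa_model`.
#' @param examples encoded examples.
#' @param split which split to evaluate.
#' @param mode prediction mode, see [predict_vqa()].
#' @return a `vqa_eval_report`: list with `accuracy_overall`, `accuracy_by_type`,
#'   `n_by_type`, `n`, and the per-example `predictions` data frame.
#' @export
evaluate_vqa <- function(model, examples, split = "val", mode = "open") {
  exs <- Filter(function(e) e$split == split, examples)
  ovqa_assert(length(exs) > 0, sprintf("no examples in split '%s'", split))
  if (any(vapply(exs, function(e) is.na(e$label), TRUE)))
    ovqa_stop(paste0("split '", split, "' has unlabeled records; strict accuracy ",
                     "is undefined — use predict_vqa() for label-free export"),
              class = "unlabeled_split")
  preds <- data.frame(
    question_id = vapply(exs, `[[`, "", "question_id"),
    question_type = vapply(exs, `[[`, "", "question_type"),
    label = vapply(exs, `[[`, "", "label"),
    prediction = vapply(exs, function(e) predict_vqa(model, e, mode), ""),
    stringsAsFactors = FALSE)
  preds$correct <- preds$prediction == preds$label
  by_type <- vapply(QUESTION_TYPES, function(tp) {
    sel <- preds$question_type == tp
    if (!any(sel)) NA_real_ else mean(preds$correct[sel])
  }, 0)
  structure(list(accuracy_overall = mean(preds$correct),
                 accuracy_by_type = by_type,
                 n_by_type = vapply(QUESTION_TYPES,
                                    function(tp) sum(preds$question_type == tp), 0L),
                 n = nrow(preds), predictions = preds),
            class = "vqa_eval_report")
}

#' @export
print.vqa_eval_report <- function(x, ...) {
  cat(sprintf("strict accuracy: %.4f over %d questions\n", x$accuracy_overall, x$n))
  for (tp in names(x$accuracy_by_type))
    cat(sprintf("  %-9s %6s  (n=%d)\n", tp,
                ifelse(is.na(x$accuracy_by_type[[tp]]), "-",
                       sprintf("%.4f", x$accuracy_by_type[[tp]])),
                x$n_by_type[[tp]]))
  invisible(x)
}

#' Seeded k-fold partition
#'
#' Disjoint covering folds of near-equal size (difference at most one).
#'
#' @param n number of records.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return integer vector of fold assignments in `1..k`.
#' @export
kfold_partition <- function(n, k, seed = 1L) {
  ovqa_assert(k >= 2, "`k` must be >= 2")
  ovqa_assert(k <= n, "`k` must not exceed the number of records")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' k-fold cross-validation of the VQA pipeline
#'
#' For each of `runs` repetitions: a seeded partition of the labeled examples
#' into `k` near-equal folds; each fold serves once as the test set while the
#' remaining folds train a fresh model; fold accuracies are aggregated per
#' run.
#'
#' @param examples labeled encoded examples (see [prepare_examples()]).
#' @param model_factory `function(seed)` returning a fresh `vqa_model`.
#' @param k number of folds (default 10).
#' @param runs number of repeated partitions (default 10).
#' @param cfg a [train_config()].
#' @param seed base seed; run r uses `seed + r - 1` for its partition.
#' @return list of per-run results, each with `folds` (data frame: fold, n,
#'   accuracy) and `accuracy` (mean over fold questions).
#' @export
kfold_cross_validate <- function(examples, model_factory, k = 10L, runs = 10L,
                                 cfg = train_config(), seed = 1L) {
  n <- length(examples)
  ovqa_assert(n >= k, "`k` exceeds the dataset size")
  lapply(seq_len(runs), function(r) {
    part <- kfold_partition(n, k, seed = seed + r - 1L)
    fold_rows <- lapply(seq_len(k), function(fold) {
      test <- examples[part == fold]
      train <- examples[part != fold]
      train <- lapply(train, function(e) { e$split <- "train"; e })
      test <- lapply(test, function(e) { e$split <- "val"; e })
      fit <- train_vqa(model_factory(seed + r - 1L), train, cfg)
      rep_ <- evaluate_vqa(fit$model, test, split = "val")
      data.frame(fold = fold, n = length(test), accuracy = rep_$accuracy_overall)
    })
    folds <- do.call(rbind, fold_rows)
    list(folds = folds, partition = part,
         accuracy = sum(folds$accuracy * folds$n) / sum(folds$n))
  })
}

#' Confusion statistics for a binary (yes/no) classifier
#'
#' Accepts either a list of per-run results — each with logical vectors
#' `pred` and `truth` (`TRUE` = positive = "yes") — or a per-run data frame /
#' matrix of precomputed indicator rows with columns among `sensitivity`,
#' `specificity`, `precision`, `accuracy`, `f1`. Computes the five indicators
#' per run (sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision
#' TP/(TP+FP), accuracy, F1) and their mean and sample standard deviation
#' (n - 1 denominator) across runs. Indicators with a zero denominator are
#' reported as `NA`, excluded from the aggregate with a warning.
#'
#' @param per_run list of per-run `pred`/`truth` pairs, or a data frame of
#'   per-run indicator rows.
#' @return a `vqa_confusion_stats`: list with `per_run` (data frame), `mean`,
#'   `sd`.
#' @export
confusion_stats <- function(per_run) {
  inds <- c("sensitivity", "specificity", "precision", "accuracy", "f1")
  if (is.matrix(per_run)) per_run <- as.data.frame(per_run)
  if (is.data.frame(per_run)) {
    rows <- per_run[, intersect(names(per_run), inds), drop = FALSE]
  } else {
    rows <- do.call(rbind, lapply(per_run, function(run) {
      p <- as.logical(run$pred); t <- as.logical(run$truth)
      tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
      sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      acc <- (tp + tn) / length(p)
      f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
        2 * prec * sens / (prec + sens) else NA_real_
      data.frame(sensitivity = sens, specificity = spec, precision = prec,
                 accuracy = acc, f1 = f1)
    }))
  }
  if (anyNA(rows))
    warning("undefined indicator(s) (zero denominator) excluded from the mean",
            call. = FALSE)
  structure(list(per_run = rows,
                 mean = colMeans(rows, na.rm = TRUE),
                 sd = vapply(rows, function(c) stats::sd(c[!is.na(c)]), 0)),
            class = "vqa_confusion_stats")
}

#' @export
print.vqa_confusion_stats <- function(x, ...) {
  for (nm in names(x$mean))
    cat(sprintf("%-12s %6.2f +/- %.2f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  invisible(x)
}
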