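# Question encoder contracts.
#
# Declared pooled dimensions J: skip-thought 2400, Bert (second-to-last
# hidden) 768, recurrent 1024. Real backends are optional plug-ins registered
# at run time; asking for an unregistered one raises a classed
# `not_installed` error, never a silent fallback. The "tiny" encoder is a
# weight-free seeded hash embedding with masked mean pooling, used by tests
# and desk-scale training.

.q_encoder_registry <- new.env(parent = emptyenv())

#' Question encoder contract
#'
#' @param mode one of `"skipthought"`, `"bert"`, `"recurrent"`, `"tiny"`.
#' @param dim pooled dimension J for `"tiny"` (default 32); fixed for the
#'   named backends (2400 / 768 / 1024).
#' @return list with `mode` and `J`.
#' @export
question_encoder_contract <- function(mode = c("tiny", "skipthought", "bert", "recurrent"),
                                      dim = 32L) {
  mode <- match.arg(mode)
  J <- switch(mode, skipthought = 2400L, bert = 768L, recurrent = 1024L,
              tiny = as.integer(dim))
  list(mode = mode, J = J)
}

#' Register a question encoder backend
#'
#' @param mode backend name.
#' @param fn `function(token_seq)` returning a list with `sequence`
#'   (`T x J` matrix over real tokens) and `pooled` (length-J vector).
#' @export
register_question_encoder <- function(mode, fn) {
  assign(mode, fn, envir = .q_encoder_registry)
  invisible(mode)
}

# Deterministic per-token embedding derived from a fixed hash of the token id;
# never reads masked positions.
tiny_token_embedding <- function(token_id, dim) {
  with_seed(derive_seed(20260909L, paste0("tiny_tok_", token_id, "_", dim)),
            stats::rnorm(dim))
}

#' Encode a tokenized question
#'
#' Produces token-level sequence features over the real (unmasked) tokens and
#' a pooled vector of the mode's declared dimension J. The pooled vector is
#' the masked mean; an all-pad sequence pools to the zero vector. Bert-style
#' backends pool the second-to-last layer's token states (the plug-in's
#' responsibility).
#'
#' @param seq a `vqa_token_seq` from [tokenize_and_pad()].
#' @param mode encoder mode; see [question_encoder_contract()].
#' @param dim pooled dimension for `"tiny"`.
#' @return a `vqa_question_feature`: list with `sequence` (`T x J`, `T` = real
#'   token count, possibly 0 rows), `pooled` (length J), `J`, `mode`.
#' @export
encode_question <- function(seq, mode = "tiny", dim = 32L) {
  ovqa_assert(inherits(seq, "vqa_token_seq"), "`seq` must come from tokenize_and_pad()")
  contract <- question_encoder_contract(mode, dim)
  if (exists(mode, envir = .q_encoder_registry)) {
    out <- get(mode, envir = .q_encoder_registry)(seq)
    ovqa_assert(length(out$pooled) == contract$J,
                sprintf("backend '%s' emitted J=%d, contract requires %d",
                        mode, length(out$pooled), contract$J),
                class = "contract_violation")
  } else if (mode == "tiny") {
    real <- seq$tokens[seq$mask]
    sequence <- if (length(real) > 0)
      t(vapply(real, tiny_token_embedding, numeric(contract$J), dim = contract$J))
    else matrix(0, 0, contract$J)
    pooled <- if (nrow(sequence) > 0) colMeans(sequence) else numeric(contract$J)
    out <- list(sequence = sequence, pooled = pooled)
  } else {
    ovqa_stop(sprintf(
      "question encoder '%s' is an optional backend and is not installed; register it with register_question_encoder()",
      mode), class = "not_installed")
  }
  structure(list(sequence = out$sequence, pooled = out$pooled,
                 J = contract$J, mode = mode),
            class = "vqa_question_feature")
}
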