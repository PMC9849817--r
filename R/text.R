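# Question text processing: normalization, word-piece vocabulary training,
# greedy longest-match tokenization with fixed-length padding, and text
# augmentation.

#' Normalize question text
#'
#' Lower-cases, replaces punctuation with spaces (so "A,B" becomes two words
#' rather than fusing), and collapses whitespace.
#'
#' @param text character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(text) {
  out <- tolower(text)
  out <- gsub("[[:punct:]]+", " ", out)
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

PAD_TOKEN <- "[PAD]"
UNK_TOKEN <- "[UNK]"

#' Train a word-piece vocabulary
#'
#' Frequency-driven merge training on the corpus: words start as character
#' pieces (continuations prefixed `##`) and the most frequent adjacent pair is
#' merged repeatedly until the size cap is reached or no pairs remain.
#' Ids 1 and 2 are reserved for `[PAD]` and `[UNK]`.
#'
#' @param texts character vector of (raw) question texts.
#' @param max_size vocabulary size cap (default 4000).
#' @return character vector of vocabulary pieces, `[PAD]` first.
#' @export
train_wordpiece_vocab <- function(texts, max_size = 4000L) {
  words <- unlist(strsplit(normalize_text(texts), " ", fixed = TRUE))
  words <- words[nzchar(words)]
  ovqa_assert(length(words) > 0, "no words in training texts")
  wfreq <- table(words)
  # symbol sequences per distinct word
  seqs <- lapply(names(wfreq), function(w) {
    ch <- strsplit(w, "")[[1]]
    if (length(ch) > 1) ch[-1] <- paste0("##", ch[-1])
    ch
  })
  freqs <- as.integer(wfreq)
  base <- unique(unlist(seqs))
  vocab <- c(PAD_TOKEN, UNK_TOKEN, sort(base))
  merge_symbols <- character(0)
  while (length(vocab) + length(merge_symbols) < max_size) {
    pair_counts <- new.env(parent = emptyenv())
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      if (length(s) < 2) next
      prs <- paste(s[-length(s)], s[-1], sep = "\r")
      for (p in unique(prs))
        assign(p, (get0(p, envir = pair_counts, ifnotfound = 0)) +
                 freqs[i] * sum(prs == p), envir = pair_counts)
    }
    keys <- ls(pair_counts)
    if (length(keys) == 0) break
    cnt <- vapply(keys, function(k) get(k, envir = pair_counts), 0)
    if (max(cnt) < 1) break
    best <- sort(keys[cnt == max(cnt)])[1]          # deterministic tie-break
    parts <- strsplit(best, "\r", fixed = TRUE)[[1]]
    merged <- paste0(parts[1], sub("^##", "", parts[2]))
    merge_symbols <- c(merge_symbols, merged)
    seqs <- lapply(seqs, function(s) {
      if (length(s) < 2) return(s)
      out <- character(0)
      i <- 1L
      while (i <= length(s)) {
        if (i < length(s) && s[i] == parts[1] && s[i + 1] == parts[2]) {
          out <- c(out, merged); i <- i + 2L
        } else { out <- c(out, s[i]); i <- i + 1L }
      }
      out
    })
  }
  unique(c(vocab, merge_symbols))[seq_len(min(max_size, length(vocab) + length(merge_symbols)))]
}

# Greedy longest-match word-piece split of one word; NULL when no piece
# matches (the caller substitutes UNK for the whole word).
wordpiece_split <- function(word, vocab_set) {
  pieces <- character(0)
  start <- 1L
  n <- nchar(word)
  while (start <= n) {
    found <- NA_character_
    for (end in n:start) {
      cand <- substr(word, start, end)
      if (start > 1L) cand <- paste0("##", cand)
      if (cand %in% vocab_set) { found <- cand; break }
    }
    if (is.na(found)) return(NULL)
    pieces <- c(pieces, found)
    start <- start + nchar(sub("^##", "", found))
  }
  pieces
}

#' Tokenize a question and pad to fixed length
#'
#' Normalizes, splits into words, applies greedy longest-match word-piece
#' segmentation, maps unknown words to `[UNK]`, and zero-pads or truncates to
#' `max_len` tokens (26, the corpus's maximum question length).
#'
#' @param text question text.
#' @param vocab vocabulary from [train_wordpiece_vocab()].
#' @param max_len fixed sequence length (default 26).
#' @return a `vqa_token_seq`: list with `tokens` (integer ids, length
#'   `max_len`; pad id 1), `mask` (logical, `TRUE` at real tokens), `raw`
#'   (normalized text).
#' @export
tokenize_and_pad <- function(text, vocab, max_len = 26L) {
  norm <- normalize_text(text)
  words <- strsplit(norm, " ", fixed = TRUE)[[1]]
  words <- words[nzchar(words)]
  ids <- integer(0)
  for (w in words) {
    pieces <- wordpiece_split(w, vocab)
    ids <- c(ids, if (is.null(pieces)) 2L else match(pieces, vocab))
  }
  ids[is.na(ids)] <- 2L
  n_real <- min(length(ids), max_len)
  tokens <- rep(1L, max_len)
  if (n_real > 0) tokens[seq_len(n_real)] <- ids[seq_len(n_real)]
  structure(list(tokens = tokens,
                 mask = seq_len(max_len) <= n_real,
                 raw = norm),
            class = "vqa_token_seq")
}

#' Augment a question text
#'
#' One variant per operator: synonym replacement from a supplied lexicon,
#' single-word deletion (skipped on one-word texts), character-level noise at
#' a fixed rate, and template resampling. The question type of templated
#' questions is preserved because replacements and templates stay in-type.
#'
#' @param text non-empty normalized question text.
#' @param seed integer seed.
#' @param lexicon named list mapping words to character vectors of synonyms
#'   (`NULL` or empty leaves text unchanged).
#' @param templates optional character vector of same-type question templates
#'   for the resampling operator (`NULL` leaves text unchanged).
#' @param noise_rate per-character substitution probability (default 0.05).
#' @return named list of text variants
#'   (`replace`, `delete` when applicable, `noise`, `resample`).
#' @export
augment_text <- function(text, seed = 1L, lexicon = NULL, templates = NULL,
                         noise_rate = 0.05) {
  ovqa_assert(nzchar(text), "`text` must be non-empty")
  with_seed(seed, {
    words <- strsplit(text, " ", fixed = TRUE)[[1]]
    out <- list()

    replaceable <- which(words %in% names(lexicon))
    out$replace <- if (length(replaceable) > 0) {
      i <- if (length(replaceable) == 1) replaceable else sample(replaceable, 1)
      words2 <- words
      syn <- lexicon[[words[i]]]
      words2[i] <- if (length(syn) == 1) syn else sample(syn, 1)
      paste(words2, collapse = " ")
    } else text

    if (length(words) > 1) {
      i <- sample(length(words), 1)
      out$delete <- paste(words[-i], collapse = " ")
    }

    chars <- strsplit(text, "")[[1]]
    flip <- stats::runif(length(chars)) < noise_rate & chars != " "
    if (any(flip)) {
      repl <- vapply(chars[flip], function(ch)
        sample(setdiff(letters, ch), 1), character(1))
      chars[flip] <- repl
    }
    out$noise <- paste(chars, collapse = "")

    out$resample <- if (!is.null(templates) && length(templates) > 0) {
      if (length(templates) == 1) templates else sample(templates, 1)
    } else text

    out
  })
}
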