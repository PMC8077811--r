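# Token representations: embedding provider contract, rule-feature
# encoding, and concatenation into the tagger input. Providers are frozen
# once trained; the tagger never updates them.

#' Embed a token sequence
#'
#' Provider contract: given one sentence's tokens, return one numeric
#' vector of the provider's dimension per token (matching order and
#' length). Static and subword providers look tokens up independently;
#' the contextual provider encodes the whole sentence, so the same token
#' can receive different vectors in different contexts.
#'
#' @param provider An embedding provider.
#' @param tokens Character vector of token texts (one sentence).
#' @return Numeric matrix, `length(tokens)` rows.
#' @export
embed_tokens <- function(provider, tokens) {
  UseMethod("embed_tokens")
}

word_ngrams <- function(word, nmin = 3L, nmax = 6L) {
  s <- paste0("<", word, ">")
  n <- nchar(s)
  out <- character()
  for (len in seq(nmin, min(nmax, n))) {
    out <- c(out, substring(s, 1:(n - len + 1L), len:n))
  }
  unique(c(out, s))
}

# shared skip-gram/negative-sampling trainer; `compose` abstracts whether
# the input vector is a word row (static) or a mean of n-gram rows (subword)
sgns_train <- function(sent_ids, V, dimension, window, epochs, negative,
                       lr, probs, get_vec, add_grad, C) {
  for (ep in seq_len(epochs)) {
    for (s in sent_ids) {
      n <- length(s)
      if (n < 2L) next
      for (pos in seq_len(n)) {
        lo <- max(1L, pos - window); hi <- min(n, pos + window)
        ctx <- s[setdiff(lo:hi, pos)]
        K <- length(ctx)
        if (K == 0L) next
        neg <- sample.int(V, K * negative, replace = TRUE, prob = probs)
        idx <- c(ctx, neg)
        y <- rep(c(1, 0), c(K, K * negative))
        v <- get_vec(s[pos])
        rows <- C[idx, , drop = FALSE]
        sc <- as.vector(rows %*% v)
        g <- (sigmoid(sc) - y) * lr
        dv <- as.vector(crossprod(rows, g))
        dC <- rowsum(g %*% t(v), idx)
        ridx <- as.integer(rownames(dC))
        C[ridx, ] <- C[ridx, , drop = FALSE] - dC
        add_grad(s[pos], dv)
      }
    }
  }
  C
}

#' Train a static word embedding on a tokenized corpus
#'
#' Skip-gram with negative sampling; in `"subword"` mode the input vector
#' of a word is the mean of its character n-gram vectors (n-grams of the
#' bracketed word, lengths `ngram[1]` to `ngram[2]`, plus the whole word),
#' so unseen words compose a vector from known n-grams. Out-of-vocabulary
#' tokens with no known n-grams map to a dedicated seed-fixed unknown
#' vector. Training is deterministic for a fixed seed; vectors are frozen
#' afterwards.
#'
#' @param sentences List of character vectors (tokens, case-folded
#'   internally).
#' @param dimension Embedding dimension (default 100).
#' @param window Symmetric context window in tokens.
#' @param epochs Passes over the corpus.
#' @param negative Negative samples per positive pair.
#' @param learning_rate SGD step size.
#' @param min_count Minimum corpus frequency for a vocabulary entry.
#' @param mode `"static"` or `"subword"`.
#' @param ngram Character n-gram length range for subword mode.
#' @param seed Integer seed.
#' @return An embedding provider (class `static_embedding` or
#'   `subword_embedding`).
#' @export
train_static_embedding <- function(sentences, dimension = 100L, window = 5L,
                                   epochs = 3L, negative = 5L,
                                   learning_rate = 0.025, min_count = 1L,
                                   mode = c("static", "subword"),
                                   ngram = c(3L, 6L), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(dimension > 0L)
  sentences <- lapply(sentences, tolower)
  counts <- table(unlist(sentences))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) stop("empty corpus: no vocabulary")
  vocab <- names(counts)
  V <- length(vocab)
  probs <- as.numeric(counts)^0.75
  probs <- probs / sum(probs)
  sent_ids <- lapply(sentences, function(s) {
    i <- match(s, vocab)
    i[!is.na(i)]
  })
  with_seed(seed, {
    r <- 0.5 / dimension
    C <- matrix(0, V, dimension)
    unk <- stats::runif(dimension, -r, r)
    if (mode == "static") {
      W <- matrix(stats::runif(V * dimension, -r, r), V)
      env <- environment()
      C <- sgns_train(sent_ids, V, dimension, window, epochs, negative,
                      learning_rate, probs,
                      get_vec = function(i) W[i, ],
                      add_grad = function(i, dv) {
                        env$W[i, ] <- env$W[i, ] - dv
                      }, C)
      structure(list(mode = "static", dimension = dimension, vocab = vocab,
                     W = env$W, unk = unk),
                class = c("static_embedding", "embedding_provider"))
    } else {
      gram_sets <- lapply(vocab, word_ngrams, nmin = ngram[1], nmax = ngram[2])
      gram_vocab <- unique(unlist(gram_sets))
      gram_ids <- lapply(gram_sets, match, table = gram_vocab)
      G <- matrix(stats::runif(length(gram_vocab) * dimension, -r, r),
                  length(gram_vocab))
      env <- environment()
      C <- sgns_train(sent_ids, V, dimension, window, epochs, negative,
                      learning_rate, probs,
                      get_vec = function(i) {
                        colMeans(G[gram_ids[[i]], , drop = FALSE])
                      },
                      add_grad = function(i, dv) {
                        ids <- gram_ids[[i]]
                        env$G[ids, ] <- env$G[ids, , drop = FALSE] -
                          matrix(dv / length(ids), length(ids), dimension,
                                 byrow = TRUE)
                      }, C)
      structure(list(mode = "subword", dimension = dimension,
                     gram_vocab = gram_vocab, G = env$G, unk = unk,
                     ngram = ngram),
                class = c("subword_embedding", "embedding_provider"))
    }
  })
}

#' @export
embed_tokens.static_embedding <- function(provider, tokens) {
  idx <- match(tolower(tokens), provider$vocab)
  out <- matrix(provider$unk, length(tokens), provider$dimension, byrow = TRUE)
  hit <- !is.na(idx)
  out[hit, ] <- provider$W[idx[hit], , drop = FALSE]
  out
}

#' @export
embed_tokens.subword_embedding <- function(provider, tokens) {
  out <- matrix(provider$unk, length(tokens), provider$dimension, byrow = TRUE)
  for (j in seq_along(tokens)) {
    ids <- match(word_ngrams(tolower(tokens[j]), provider$ngram[1],
                             provider$ngram[2]), provider$gram_vocab)
    ids <- ids[!is.na(ids)]
    if (length(ids)) out[j, ] <- colMeans(provider$G[ids, , drop = FALSE])
  }
  out
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat(sprintf("<embedding_provider: mode %s, dimension %d>\n",
              x$mode, x$dimension))
  invisible(x)
}

# ---- contextual provider (character-aware recurrent language model) -------

char_onehot <- function(ids, V) {
  X <- array(0, c(1, length(ids), V))
  ok <- !is.na(ids)
  X[cbind(1, which(ok), ids[ok])] <- 1
  X
}

train_char_lm_dir <- function(seqs, V, hidden, epochs, lr) {
  params <- list(lstm = lstm_init(V, hidden),
                 W = matrix(stats::runif(hidden * V, -0.05, 0.05), hidden),
                 b = rep(0, V))
  st <- adam_state(params)
  for (ep in seq_len(epochs)) {
    for (s in seqs) {
      L <- length(s)
      if (L < 3L) next
      X <- char_onehot(s[-L], V)
      tgt <- s[-1]
      fw <- lstm_forward(params$lstm, X)
      Hm <- matrix(fw$H[1, , ], L - 1L, hidden)
      logits <- Hm %*% params$W + matrix(params$b, L - 1L, V, byrow = TRUE)
      p <- exp(logits - apply(logits, 1, max))
      p <- p / rowSums(p)
      dlog <- p
      dlog[cbind(seq_len(L - 1L), tgt)] <- dlog[cbind(seq_len(L - 1L), tgt)] - 1
      dlog <- dlog / (L - 1L)
      dH <- array(dlog %*% t(params$W), c(1, L - 1L, hidden))
      gl <- lstm_backward(params$lstm, fw$cache, dH)
      grads <- list(lstm = gl, W = crossprod(Hm, dlog), b = colSums(dlog))
      upd <- adam_update(params, grads, st, lr)
      params <- upd$params
      st <- upd$state
    }
  }
  params
}

#' Train a contextual embedding provider
#'
#' A small character-aware recurrent language model: one forward and one
#' backward character LSTM trained on the corpus text (next/previous
#' character prediction). A token's vector concatenates the forward hidden
#' state at its last character and the backward hidden state at its first
#' character, so the representation depends on the whole sentence.
#' The provider has dimension `2 * hidden` and is frozen after training.
#'
#' @param sentences List of character vectors (tokens).
#' @param hidden Hidden size per direction.
#' @param epochs Training passes.
#' @param learning_rate Adam step size.
#' @param seed Integer seed.
#' @return A provider of class `contextual_embedding`.
#' @export
train_contextual_embedding <- function(sentences, hidden = 32L, epochs = 2L,
                                       learning_rate = 0.005, seed = 1L) {
  texts <- vapply(sentences, function(s) tolower(paste(s, collapse = " ")), "")
  if (length(texts) == 0L || all(!nzchar(texts))) stop("empty corpus")
  chars <- strsplit(texts, "")
  vocab <- sort(unique(unlist(chars)))
  V <- length(vocab)
  seqs <- lapply(chars, match, table = vocab)
  with_seed(seed, {
    fwd <- train_char_lm_dir(seqs, V, hidden, epochs, learning_rate)
    bwd <- train_char_lm_dir(lapply(seqs, rev), V, hidden, epochs,
                             learning_rate)
    structure(list(mode = "contextual", dimension = 2L * hidden,
                   vocab = vocab, hidden = hidden, fwd = fwd, bwd = bwd),
              class = c("contextual_embedding", "embedding_provider"))
  })
}

#' @export
embed_tokens.contextual_embedding <- function(provider, tokens) {
  n <- length(tokens)
  out <- matrix(0, n, provider$dimension)
  if (n == 0L) return(out)
  text <- tolower(paste(tokens, collapse = " "))
  ids <- match(strsplit(text, "")[[1]], provider$vocab)
  L <- length(ids)
  X <- char_onehot(ids, length(provider$vocab))
  Hf <- lstm_forward(provider$fwd$lstm, X, keep_cache = FALSE)$H
  Xr <- char_onehot(rev(ids), length(provider$vocab))
  Hb <- lstm_forward(provider$bwd$lstm, Xr, keep_cache = FALSE)$H
  ends <- cumsum(nchar(tokens) + 1L) - 1L  # position of last char, 1-based
  starts <- ends - nchar(tokens) + 1L
  for (j in seq_len(n)) {
    out[j, ] <- c(Hf[1, ends[j], ], Hb[1, L - starts[j] + 1L, ])
  }
  out
}

# ---- rule features and fusion ---------------------------------------------

#' One-hot encoding of rule-layer IOB tags
#'
#' Positions follow the fixed tag order of [med_tags()] (`O` first, then
#' `B-c`/`I-c` per category), dimension 15.
#'
#' @param tags IOB tag vector.
#' @return Binary matrix, one unit row per tag.
#' @export
encode_rule_features <- function(tags) {
  idx <- tag_index(tags)
  m <- matrix(0, length(tags), length(med_tags()))
  m[cbind(seq_along(tags), idx)] <- 1
  m
}

#' Build the tagger input matrix for one sentence
#'
#' Concatenates the embedding block (first) with the one-hot rule-feature
#' block (last); with `rule_tags = NULL` (ablation) the input is the
#' embedding alone.
#'
#' @param tokens Character vector of token texts.
#' @param provider An embedding provider.
#' @param rule_tags Optional rule-layer IOB tags aligned to `tokens`.
#' @return Numeric matrix with `provider$dimension` (+ 15) columns.
#' @export
build_inputs <- function(tokens, provider, rule_tags = NULL) {
  E <- embed_tokens(provider, tokens)
  if (is.null(rule_tags)) return(E)
  if (length(rule_tags) != length(tokens)) {
    stop("rule tags and tokens are misaligned")
  }
  cbind(E, encode_rule_features(rule_tags))
}
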