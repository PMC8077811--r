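# Bidirectional LSTM sequence tagger with a dense-softmax or linear-chain
# CRF output layer, Adam training with early stopping and learning-rate
# reduction on plateau, and random hyperparameter search.

hidden_grid <- c(128L, 256L, 512L)
batch_grid <- c(64L, 128L)
dropout_grid <- c(0, 0.1, 0.2, 0.3, 0.5, 0.6, 0.7)

#' Tagger configuration
#'
#' Values must lie on the supported grids: hidden size 128/256/512, batch
#' size 64/128, dropouts in {0, 0.1, 0.2, 0.3, 0.5, 0.6, 0.7}. The
#' training schedule is Adam at `learning_rate`, early stopping on
#' development loss with `patience`, and multiplication of the learning
#' rate by `plateau_factor` after `plateau_patience` epochs without a
#' development-loss improvement larger than `plateau_min_delta`.
#'
#' @param hidden_size LSTM units per direction.
#' @param batch_size Sentences per training batch.
#' @param dropout_before,dropout_after Input / pre-output dropout rates.
#' @param recurrent_dropout Variational dropout on the recurrent state.
#' @param use_crf Use a CRF output layer instead of dense softmax.
#' @param learning_rate Adam step size.
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param plateau_factor Learning-rate multiplier on plateau.
#' @param plateau_patience,plateau_min_delta Plateau trigger definition.
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A `tagger_config` list.
#' @export
tagger_config <- function(hidden_size = 128L, batch_size = 64L,
                          dropout_before = 0, dropout_after = 0,
                          recurrent_dropout = 0, use_crf = FALSE,
                          learning_rate = 0.001, max_epochs = 50L,
                          patience = 8L, plateau_factor = 0.1,
                          plateau_patience = 3L, plateau_min_delta = 1e-4,
                          seed = 1L) {
  if (!hidden_size %in% hidden_grid) {
    stop("hidden_size must be one of ", paste(hidden_grid, collapse = ", "))
  }
  if (!batch_size %in% batch_grid) {
    stop("batch_size must be one of ", paste(batch_grid, collapse = ", "))
  }
  for (nm in c("dropout_before", "dropout_after", "recurrent_dropout")) {
    v <- get(nm)
    if (!isTRUE(any(abs(v - dropout_grid) < 1e-12))) {
      stop(nm, " must be one of ", paste(dropout_grid, collapse = ", "))
    }
  }
  stopifnot(learning_rate > 0, max_epochs >= 1L, patience >= 1L,
            plateau_factor > 0, plateau_factor <= 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 batch_size = as.integer(batch_size),
                 dropout_before = dropout_before,
                 dropout_after = dropout_after,
                 recurrent_dropout = recurrent_dropout,
                 use_crf = isTRUE(use_crf), learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_min_delta = plateau_min_delta,
                 seed = as.integer(seed)),
            class = "tagger_config")
}

init_tagger_params <- function(input_dim, hidden, n_tags, use_crf) {
  r <- sqrt(6 / (2 * hidden + n_tags))
  p <- list(fwd = lstm_init(input_dim, hidden),
            bwd = lstm_init(input_dim, hidden),
            W_out = matrix(stats::runif(2 * hidden * n_tags, -r, r), 2 * hidden),
            b_out = rep(0, n_tags))
  if (use_crf) p$trans <- matrix(0, n_tags, n_tags)
  p
}

#' Build a bidirectional LSTM tagger
#'
#' Two directional LSTM encoders whose per-token outputs are concatenated
#' (never summed) feed a 15-way output layer: dense softmax, or emissions
#' plus a 15 x 15 transition table when `use_crf`. Initialization is
#' deterministic for the config seed.
#'
#' @param config A [tagger_config()].
#' @param input_dim Per-token input dimension (embedding + rule features).
#' @return A `tagger_model`.
#' @export
build_tagger <- function(config, input_dim) {
  stopifnot(inherits(config, "tagger_config"), input_dim >= 1L)
  n_tags <- length(med_tags())
  params <- with_seed(config$seed,
                      init_tagger_params(input_dim, config$hidden_size,
                                         n_tags, config$use_crf))
  structure(list(config = config, input_dim = as.integer(input_dim),
                 n_tags = n_tags, params = params),
            class = "tagger_model")
}

#' @export
print.tagger_model <- function(x, ...) {
  cat(sprintf("<tagger_model: input %d, hidden %d x2, %s output>\n",
              x$input_dim, x$config$hidden_size,
              if (x$config$use_crf) "CRF" else "dense softmax"))
  invisible(x)
}

# pad a list of examples into dense batch arrays
pad_batch <- function(examples, input_dim) {
  B <- length(examples)
  lens <- vapply(examples, function(e) nrow(e$x), integer(1))
  Tn <- max(lens)
  X <- array(0, c(B, Tn, input_dim))
  Y <- matrix(0L, B, Tn)
  for (b in seq_len(B)) {
    X[b, seq_len(lens[b]), ] <- examples[[b]]$x
    if (!is.null(examples[[b]]$y)) Y[b, seq_len(lens[b])] <- examples[[b]]$y
  }
  list(X = X, Y = Y, lens = lens, B = B, Tn = Tn)
}

drop_mask <- function(dims, p) {
  if (p <= 0) return(NULL)
  array((stats::runif(prod(dims)) >= p) / (1 - p), dims)
}

# forward (and optionally backward) pass over one padded batch.
# Returns loss and, when `grads`, the parameter gradients.
tagger_batch_pass <- function(params, batch, config, train = FALSE,
                              grads = FALSE) {
  X <- batch$X; Y <- batch$Y; lens <- batch$lens
  B <- batch$B; Tn <- batch$Tn
  H <- config$hidden_size
  K <- ncol(params$W_out)
  m_in <- if (train) drop_mask(dim(X), config$dropout_before) else NULL
  if (!is.null(m_in)) X <- X * m_in
  rm_f <- rm_b <- NULL
  if (train && config$recurrent_dropout > 0) {
    rm_f <- matrix((stats::runif(B * H) >= config$recurrent_dropout) /
                     (1 - config$recurrent_dropout), B, H)
    rm_b <- matrix((stats::runif(B * H) >= config$recurrent_dropout) /
                     (1 - config$recurrent_dropout), B, H)
  }
  fw <- lstm_forward(params$fwd, X, rmask = rm_f, keep_cache = grads)
  Xr <- reverse_sequences(X, lens)
  bw <- lstm_forward(params$bwd, Xr, rmask = rm_b, keep_cache = grads)
  HH <- array(0, c(B, Tn, 2 * H))
  HH[, , 1:H] <- fw$H
  HH[, , H + 1:H] <- reverse_sequences(bw$H, lens)
  m_out <- if (train) drop_mask(dim(HH), config$dropout_after) else NULL
  if (!is.null(m_out)) HH <- HH * m_out
  Hmat <- array(HH, c(B * Tn, 2 * H))
  logits <- Hmat %*% params$W_out +
    matrix(params$b_out, B * Tn, K, byrow = TRUE)
  real <- as.vector(matrix(rep(seq_len(Tn), each = B), B) <=
                      matrix(lens, B, Tn))
  yvec <- as.vector(Y)
  N <- sum(lens)

  if (config$use_crf) {
    emis <- array(logits, c(B, Tn, K))
    res <- crf_nll(emis, params$trans, Y, lens)
    loss <- res$loss
    if (!grads) return(list(loss = loss))
    dlog <- array(res$demis, c(B * Tn, K))
    dtrans <- res$dtrans
  } else {
    mx <- apply(logits, 1, max)
    P <- exp(logits - mx)
    P <- P / rowSums(P)
    rows <- which(real)
    loss <- -sum(log(pmax(P[cbind(rows, yvec[rows])], 1e-300))) / N
    if (!grads) return(list(loss = loss))
    dlog <- P
    dlog[cbind(rows, yvec[rows])] <- dlog[cbind(rows, yvec[rows])] - 1
    dlog[!real, ] <- 0
    dlog <- dlog / N
    dtrans <- NULL
  }

  dW_out <- crossprod(Hmat, dlog)
  db_out <- colSums(dlog)
  dHH <- array(dlog %*% t(params$W_out), c(B, Tn, 2 * H))
  if (!is.null(m_out)) dHH <- dHH * m_out
  dH1 <- array(dHH[, , 1:H, drop = FALSE], c(B, Tn, H))
  dH2 <- reverse_sequences(array(dHH[, , H + 1:H, drop = FALSE], c(B, Tn, H)),
                           lens)
  g <- list(fwd = lstm_backward(params$fwd, fw$cache, dH1, rmask = rm_f),
            bwd = lstm_backward(params$bwd, bw$cache, dH2, rmask = rm_b),
            W_out = dW_out, b_out = db_out)
  if (config$use_crf) g$trans <- dtrans
  list(loss = loss, grads = g)
}

#' Generic training schedule with early stopping and LR plateau
#'
#' Drives any per-epoch training step under the schedule shared by all
#' taggers: the step function is called once per epoch with the current
#' learning rate and must return `train_loss`, `dev_loss` and optionally
#' `dev_f` and `state` (an opaque parameter snapshot). The best
#' development-loss state is retained; training stops once `patience`
#' epochs pass without improvement; the learning rate is multiplied by
#' `plateau_factor` after `plateau_patience` epochs without an improvement
#' larger than `plateau_min_delta`.
#'
#' @param epoch_fn `function(epoch, lr)` returning a list as above.
#' @param config A [tagger_config()] (schedule fields are used).
#' @return List with `history` (data frame: epoch, train_loss, dev_loss,
#'   dev_f, lr), `best_epoch`, `best_state`, `stopped_epoch`.
#' @export
training_schedule <- function(epoch_fn, config) {
  lr <- config$learning_rate
  best_loss <- Inf; best_epoch <- 0L; best_state <- NULL
  plateau_count <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     dev_loss = numeric(), dev_f = numeric(), lr = numeric())
  last <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    res <- epoch_fn(epoch, lr)
    hist[nrow(hist) + 1L, ] <- list(epoch, res$train_loss, res$dev_loss,
                                    if (is.null(res$dev_f)) NA_real_ else res$dev_f,
                                    lr)
    if (res$dev_loss < best_loss) {
      if (best_loss - res$dev_loss > config$plateau_min_delta) {
        plateau_count <- 0L
      } else {
        plateau_count <- plateau_count + 1L
      }
      best_loss <- res$dev_loss
      best_epoch <- epoch
      best_state <- res$state
    } else {
      plateau_count <- plateau_count + 1L
    }
    last <- epoch
    if (epoch - best_epoch >= config$patience) break
    if (plateau_count >= config$plateau_patience) {
      lr <- lr * config$plateau_factor
      plateau_count <- 0L
    }
  }
  list(history = hist, best_epoch = best_epoch, best_state = best_state,
       stopped_epoch = last)
}

as_example <- function(e) {
  y <- e$y
  tags <- e$tags
  if (is.null(y) && !is.null(tags)) y <- tag_index(tags)
  list(x = e$x, y = y, tags = tags)
}

#' Train a tagger
#'
#' Adam optimization of the token cross-entropy (dense mode) or CRF
#' negative log-likelihood at the configured learning rate, with
#' sentence-level batches (padded and loss-masked), per-epoch shuffling,
#' early stopping on development loss and learning-rate reduction on
#' plateau. The returned model carries the parameters of the best
#' development-loss epoch. Fully deterministic for a fixed config seed.
#'
#' @param model A [build_tagger()] model.
#' @param train,dev Lists of examples: each `list(x = input matrix, y =
#'   tag indices or tags = IOB tags)`.
#' @param config Training configuration (defaults to the model's).
#' @return List with `model` (best checkpoint) and `history`.
#' @export
train_tagger <- function(model, train, dev, config = model$config) {
  if (length(train) == 0L) stop("empty training set")
  train <- lapply(train, as_example)
  dev <- lapply(dev, as_example)
  dev_batches <- lapply(chunk_list(dev, config$batch_size),
                        pad_batch, input_dim = model$input_dim)
  params <- model$params
  seeds <- derive_seeds(config$seed, config$max_epochs)
  st <- adam_state(params)
  opt_env <- environment()

  epoch_fn <- function(epoch, lr) {
    with_seed(seeds[epoch], {
      perm <- sample.int(length(train))
      batches <- lapply(chunk_list(train[perm], config$batch_size),
                        pad_batch, input_dim = model$input_dim)
      tl <- 0; ntok <- 0
      for (ba in batches) {
        out <- tagger_batch_pass(opt_env$params, ba, config,
                                 train = TRUE, grads = TRUE)
        upd <- adam_update(opt_env$params, out$grads, opt_env$st, lr)
        opt_env$params <- upd$params
        opt_env$st <- upd$state
        tl <- tl + out$loss * sum(ba$lens)
        ntok <- ntok + sum(ba$lens)
      }
      dl <- 0; dn <- 0
      for (ba in dev_batches) {
        dl <- dl + tagger_batch_pass(opt_env$params, ba, config)$loss *
          sum(ba$lens)
        dn <- dn + sum(ba$lens)
      }
      dev_loss <- if (dn > 0) dl / dn else tl / max(ntok, 1)
      m2 <- model; m2$params <- opt_env$params
      dev_f <- if (length(dev)) {
        pred <- predict_tagger(m2, lapply(dev, `[[`, "x"))
        gold <- lapply(dev, function(e) med_tags()[e$y])
        micro_prf(token_confusion_all(gold, pred))$f[8]
      } else NA_real_
      list(train_loss = tl / max(ntok, 1), dev_loss = dev_loss,
           dev_f = dev_f, state = opt_env$params)
    })
  }
  sched <- training_schedule(epoch_fn, config)
  best <- model
  best$params <- if (is.null(sched$best_state)) params else sched$best_state
  list(model = best, history = sched$history,
       best_epoch = sched$best_epoch, stopped_epoch = sched$stopped_epoch)
}

chunk_list <- function(x, size) {
  if (length(x) == 0L) return(list())
  split(x, ceiling(seq_along(x) / size))
}

#' Predict IOB tags
#'
#' Dense mode decodes by per-token argmax; CRF mode by argmax of the
#' forward-backward posterior marginals (default) or joint Viterbi.
#' Inference is deterministic (no dropout).
#'
#' @param model A trained `tagger_model`.
#' @param xs List of input matrices (one per sentence).
#' @param decode `"marginal"` or `"viterbi"` (CRF mode only).
#' @return List of IOB tag vectors.
#' @export
predict_tagger <- function(model, xs, decode = c("marginal", "viterbi")) {
  decode <- match.arg(decode)
  out <- vector("list", length(xs))
  if (length(xs) == 0L) return(out)
  for (x in xs) {
    if (ncol(x) != model$input_dim) {
      stop("input dimension ", ncol(x), " does not match model (",
           model$input_dim, ")")
    }
  }
  tags <- med_tags()
  idx_chunks <- chunk_list(seq_along(xs), 64L)
  for (ch in idx_chunks) {
    ba <- pad_batch(lapply(xs[ch], function(x) list(x = x, y = NULL)),
                    model$input_dim)
    p <- model$params
    fw <- lstm_forward(p$fwd, ba$X, keep_cache = FALSE)
    bw <- lstm_forward(p$bwd, reverse_sequences(ba$X, ba$lens),
                       keep_cache = FALSE)
    H <- model$config$hidden_size
    HH <- array(0, c(ba$B, ba$Tn, 2 * H))
    HH[, , 1:H] <- fw$H
    HH[, , H + 1:H] <- reverse_sequences(bw$H, ba$lens)
    K <- model$n_tags
    logits <- array(array(HH, c(ba$B * ba$Tn, 2 * H)) %*% p$W_out +
                      matrix(p$b_out, ba$B * ba$Tn, K, byrow = TRUE),
                    c(ba$B, ba$Tn, K))
    if (model$config$use_crf) {
      if (decode == "marginal") {
        marg <- crf_marginals(logits, p$trans, ba$lens)
        for (j in seq_along(ch)) {
          L <- ba$lens[j]
          out[[ch[j]]] <- tags[apply(matrix(marg[j, seq_len(L), ], L, K),
                                     1, which.max)]
        }
      } else {
        for (j in seq_along(ch)) {
          L <- ba$lens[j]
          out[[ch[j]]] <- tags[viterbi_decode(
            matrix(logits[j, seq_len(L), ], L, K), p$trans)]
        }
      }
    } else {
      for (j in seq_along(ch)) {
        L <- ba$lens[j]
        out[[ch[j]]] <- tags[apply(matrix(logits[j, seq_len(L), ], L, K),
                                   1, which.max)]
      }
    }
  }
  out
}

#' Build tagger examples from annotated documents
#'
#' Runs the rule engine over each document, converts the rule layer to
#' IOB, embeds the tokens and concatenates the rule features (unless
#' ablated), pairing each sentence input with its gold tags.
#'
#' @param docs List of `med_document`s carrying gold spans.
#' @param provider An embedding provider.
#' @param lexicon A `drug_lexicon`.
#' @param ruleset A `rule_set`.
#' @param use_rule_features Concatenate the rule one-hot block.
#' @param window Rule-engine token window.
#' @return List of examples (`x`, `y`, `tags`, plus `doc_id`, `sentence`).
#' @export
tagger_dataset <- function(docs, provider, lexicon,
                           ruleset = default_ruleset(),
                           use_rule_features = TRUE, window = 10L) {
  out <- list()
  for (doc in docs) {
    doc <- annotate_document(doc, lexicon, ruleset, window)
    rtags <- rule_iob(doc)
    gtags <- doc_iob(doc, "gold", warn = FALSE)
    for (k in seq_len(nrow(doc$sentences))) {
      toks <- doc$tokens$text[doc$tokens$sentence == k]
      if (length(toks) == 0L) next
      x <- build_inputs(toks, provider,
                        if (use_rule_features) rtags[[k]] else NULL)
      out[[length(out) + 1L]] <- list(x = x, y = tag_index(gtags[[k]]),
                                      tags = gtags[[k]], doc_id = doc$doc_id,
                                      sentence = k)
    }
  }
  out
}

#' Random hyperparameter search
#'
#' Samples `n_iter` configurations uniformly from a finite grid space,
#' scores each with `eval_fn` (higher is better; typically development
#' micro-F after training) and returns the argmax trial with the full
#' trial log. Seed-reproducible.
#'
#' @param space Named list of candidate value vectors for
#'   [tagger_config()] fields.
#' @param n_iter Number of sampled configurations.
#' @param eval_fn `function(config)` returning a numeric score.
#' @param seed Integer seed.
#' @param ... Fixed arguments passed to every [tagger_config()].
#' @return List with `best_config`, `best_score` and `trials` (data frame
#'   of sampled values and scores).
#' @export
random_search <- function(space, n_iter = 15L, eval_fn, seed = 1L, ...) {
  if (n_iter < 1L) stop("n_iter must be at least 1")
  stopifnot(length(space) > 0L, !is.null(names(space)))
  fixed <- list(...)
  draws <- with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      lapply(space, function(v) v[[sample.int(length(v), 1L)]])
    })
  })
  scores <- numeric(n_iter)
  configs <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    configs[[i]] <- do.call(tagger_config, c(draws[[i]], fixed))
    scores[i] <- eval_fn(configs[[i]])
  }
  trials <- cbind(do.call(rbind, lapply(draws, function(d) {
    as.data.frame(d, stringsAsFactors = FALSE)
  })), score = scores)
  best <- which.max(scores)
  list(best_config = configs[[best]], best_score = scores[best],
       trials = trials)
}
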