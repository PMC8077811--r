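# Minimal LSTM layer with manual backpropagation through time, shared by
# the sequence tagger and the character-level contextual embedding model.
# Batches are dense arrays (batch, time, feature); sequences are padded at
# the end, so untouched trailing states never reach the loss and need no
# explicit masking inside the recurrence.

# slice timestep t of a (B, T, D) array as a (B, D) matrix
slice_t <- function(X, t) {
  d <- dim(X)
  array(X[, t, , drop = FALSE], dim = c(d[1], d[3]))
}

# uniform Glorot-style init; forget-gate bias starts at 1
lstm_init <- function(input_dim, hidden) {
  r <- sqrt(6 / (input_dim + 4 * hidden))
  Wx <- matrix(stats::runif(input_dim * 4 * hidden, -r, r), input_dim)
  rh <- sqrt(6 / (hidden + 4 * hidden))
  Wh <- matrix(stats::runif(hidden * 4 * hidden, -rh, rh), hidden)
  b <- rep(0, 4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1
  list(Wx = Wx, Wh = Wh, b = b)
}

# forward pass; rmask is an optional (B, H) variational recurrent-dropout
# mask applied to the previous hidden state at every step
lstm_forward <- function(p, X, rmask = NULL, keep_cache = TRUE) {
  d <- dim(X); B <- d[1]; Tn <- d[2]
  H <- nrow(p$Wh)
  gi <- 1:H; gf <- H + gi; go <- 2 * H + gi; gg <- 3 * H + gi
  bmat <- matrix(p$b, B, 4 * H, byrow = TRUE)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hout <- array(0, c(B, Tn, H))
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    x <- slice_t(X, t)
    hu <- if (is.null(rmask)) h else h * rmask
    z <- x %*% p$Wx + hu %*% p$Wh + bmat
    i <- sigmoid(z[, gi, drop = FALSE])
    f <- sigmoid(z[, gf, drop = FALSE])
    o <- sigmoid(z[, go, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    hn <- o * tc
    if (keep_cache) {
      cache[[t]] <- list(x = x, hu = hu, i = i, f = f, o = o, g = g,
                         c_prev = cc, tc = tc)
    }
    h <- hn; cc <- c_new
    Hout[, t, ] <- h
  }
  list(H = Hout, cache = cache)
}

# backward pass; dH is (B, T, H). Returns parameter gradients only (inputs
# are frozen embeddings or one-hot characters; no dX needed).
lstm_backward <- function(p, cache, dH, rmask = NULL) {
  Tn <- length(cache)
  H <- nrow(p$Wh)
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- rep(0, 4 * H)
  dh_next <- NULL; dc_next <- NULL
  for (t in rev(seq_len(Tn))) {
    ca <- cache[[t]]
    dh <- slice_t(dH, t)
    if (!is.null(dh_next)) dh <- dh + dh_next
    dc <- dh * ca$o * (1 - ca$tc^2)
    if (!is.null(dc_next)) dc <- dc + dc_next
    do_ <- dh * ca$tc
    di <- dc * ca$g
    dg <- dc * ca$i
    df <- dc * ca$c_prev
    dc_next <- dc * ca$f
    dz <- cbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                do_ * ca$o * (1 - ca$o),
                dg * (1 - ca$g^2))
    dWx <- dWx + crossprod(ca$x, dz)
    dWh <- dWh + crossprod(ca$hu, dz)
    db <- db + colSums(dz)
    dh_next <- dz %*% t(p$Wh)
    if (!is.null(rmask)) dh_next <- dh_next * rmask
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# reverse each sequence within its true length, pads staying at the end
reverse_sequences <- function(X, lens) {
  out <- X
  for (b in seq_along(lens)) {
    L <- lens[b]
    if (L > 1L) out[b, 1:L, ] <- X[b, L:1, ]
  }
  out
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(step, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  out <- Map(step, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}
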