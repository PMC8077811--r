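# Linear-chain CRF output layer. Training minimizes the sequence-level
# categorical cross-entropy (the CRF negative log-likelihood); its gradient
# is exactly the forward-backward per-token (and pairwise) marginals minus
# the gold indicators, i.e. marginal-based optimization. Decoding is
# per-token marginal argmax by default, joint Viterbi behind a flag.

# alpha/beta recursions in log space, vectorized over the batch.
# emis: (B, T, K); trans: (K, K); lens: integer(B).
crf_forward_backward <- function(emis, trans, lens) {
  d <- dim(emis); B <- d[1]; Tn <- d[2]; K <- d[3]
  etrans <- exp(trans)
  alpha <- array(-Inf, c(B, Tn, K))
  alpha[, 1, ] <- slice_t(emis, 1)
  if (Tn > 1) {
    for (t in 2:Tn) {
      prev <- slice_t(alpha, t - 1)
      m <- apply(prev, 1, max)
      S <- exp(prev - m) %*% etrans
      new <- log(S) + m + slice_t(emis, t)
      upd <- t <= lens
      cur <- prev
      cur[upd, ] <- new[upd, , drop = FALSE]
      alpha[, t, ] <- cur
    }
  }
  last <- matrix(0, B, K)
  for (b in seq_len(B)) last[b, ] <- alpha[b, lens[b], ]
  logZ <- logsumexp_rows(last)

  beta <- array(0, c(B, Tn, K))
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      nxt <- slice_t(beta, t + 1) + slice_t(emis, t + 1)
      m <- apply(nxt, 1, max)
      m[!is.finite(m)] <- 0
      S <- exp(nxt - m) %*% t(etrans)
      new <- log(S) + m
      upd <- t < lens
      cur <- slice_t(beta, t + 1)
      cur[upd, ] <- new[upd, , drop = FALSE]
      # states at and beyond the last step keep beta = 0
      cur[t >= lens, ] <- 0
      beta[, t, ] <- cur
    }
  }
  list(alpha = alpha, beta = beta, logZ = logZ)
}

# token posterior marginals P(y_t = k | x); zero at padded positions
crf_marginals <- function(emis, trans, lens, fb = NULL) {
  if (is.null(fb)) fb <- crf_forward_backward(emis, trans, lens)
  d <- dim(emis); B <- d[1]; Tn <- d[2]; K <- d[3]
  marg <- array(0, c(B, Tn, K))
  for (t in seq_len(Tn)) {
    v <- exp(slice_t(fb$alpha, t) + slice_t(fb$beta, t) - fb$logZ)
    v[t > lens, ] <- 0
    marg[, t, ] <- v
  }
  marg
}

# negative log-likelihood (per-token mean) and gradients for emissions and
# transitions. y: (B, T) integer matrix of gold tag indices, 0 at pads.
crf_nll <- function(emis, trans, y, lens) {
  d <- dim(emis); B <- d[1]; Tn <- d[2]; K <- d[3]
  N <- sum(lens)
  fb <- crf_forward_backward(emis, trans, lens)
  marg <- crf_marginals(emis, trans, lens, fb)

  score <- numeric(B)
  for (b in seq_len(B)) {
    idx <- seq_len(lens[b])
    score[b] <- sum(emis[cbind(b, idx, y[b, idx])])
    if (lens[b] > 1) {
      score[b] <- score[b] +
        sum(trans[cbind(y[b, idx[-lens[b]]], y[b, idx[-1]])])
    }
  }
  loss <- sum(fb$logZ - score) / N

  demis <- marg
  for (b in seq_len(B)) {
    idx <- seq_len(lens[b])
    demis[cbind(b, idx, y[b, idx])] <- demis[cbind(b, idx, y[b, idx])] - 1
  }
  demis <- demis / N

  dtrans <- matrix(0, K, K)
  if (Tn > 1) {
    tshift <- max(trans)
    et <- exp(trans - tshift)
    for (t in 2:Tn) {
      act <- which(t <= lens)
      if (length(act) == 0L) next
      ap <- slice_t(fb$alpha, t - 1)[act, , drop = FALSE]
      eb <- slice_t(fb$beta, t)[act, , drop = FALSE] +
        slice_t(emis, t)[act, , drop = FALSE]
      c1 <- apply(ap, 1, max)
      c2 <- apply(eb, 1, max)
      s <- exp(c1 + c2 + tshift - fb$logZ[act])
      E1 <- exp(ap - c1) * s
      E2 <- exp(eb - c2)
      dtrans <- dtrans + crossprod(E1, E2) * et
      yp <- y[act, t - 1]; yc <- y[act, t]
      for (j in seq_along(act)) {
        dtrans[yp[j], yc[j]] <- dtrans[yp[j], yc[j]] - 1
      }
    }
  }
  dtrans <- dtrans / N

  list(loss = loss, demis = demis, dtrans = dtrans, marginals = marg)
}

# joint Viterbi decoding for one sequence; emis: (T, K)
viterbi_decode <- function(emis, trans) {
  Tn <- nrow(emis); K <- ncol(emis)
  delta <- emis[1, ]
  back <- matrix(0L, Tn, K)
  if (Tn > 1) {
    for (t in 2:Tn) {
      m <- delta + trans  # K x K: prev state rows
      back[t, ] <- apply(m, 2, which.max)
      delta <- m[cbind(back[t, ], seq_len(K))] + emis[t, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) {
    for (t in Tn:2) path[t - 1] <- back[t, path[t]]
  }
  path
}
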