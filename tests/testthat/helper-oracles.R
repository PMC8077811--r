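# Independent brute-force oracles. These re-derive expected results by
# direct enumeration, without using the package's own algorithms.

# IOB tags by per-token character-overlap check
oracle_iob <- function(tokens, spans) {
  tags <- rep("O", nrow(tokens))
  if (nrow(spans) == 0L) return(tags)
  spans <- spans[order(spans$start), , drop = FALSE]
  for (i in seq_len(nrow(spans))) {
    first <- TRUE
    for (t in seq_len(nrow(tokens))) {
      ov <- min(tokens$end[t], spans$end[i]) - max(tokens$start[t], spans$start[i])
      if (ov > 0) {
        tags[t] <- paste0(if (first) "B-" else "I-", spans$label[i])
        first <- FALSE
      }
    }
  }
  tags
}

# all-substring dictionary scan + longest-leftmost selection
oracle_match <- function(token_texts, surfaces) {
  folded <- tolower(token_texts)
  cands <- list()
  for (i in seq_along(folded)) {
    for (j in i:length(folded)) {
      key <- paste(folded[i:j], collapse = " ")
      if (key %in% surfaces) cands[[length(cands) + 1L]] <- c(i, j)
    }
  }
  picked <- list()
  taken <- rep(FALSE, length(folded))
  # leftmost start, then longest
  ord <- order(vapply(cands, `[`, 0, 1), -vapply(cands, function(c) c[2] - c[1], 0))
  for (c in cands[ord]) {
    if (!any(taken[c[1]:c[2]])) {
      picked[[length(picked) + 1L]] <- c
      taken[c[1]:c[2]] <- TRUE
    }
  }
  picked
}

# per-token confusion tally by explicit loop
oracle_confusion <- function(gold, pred) {
  strip <- function(x) sub("^[BI]-", "", x)
  labs <- med_labels()
  out <- data.frame(label = labs, tp = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (t in seq_along(gold)) {
    g <- strip(gold[t]); p <- strip(pred[t])
    if (g != "O" && p == g) out$tp[out$label == g] <- out$tp[out$label == g] + 1L
    if (p != "O" && p != g) out$fp[out$label == p] <- out$fp[out$label == p] + 1L
    if (g != "O" && p != g) out$fn[out$label == g] <- out$fn[out$label == g] + 1L
  }
  out
}

# slot extraction by explicit scan (lenient)
oracle_slots <- function(tags) {
  strip <- function(x) sub("^[BI]-", "", x)
  pre <- ifelse(tags == "O", "O", substr(tags, 1, 1))
  cls <- strip(tags)
  slots <- list()
  cur <- NULL
  for (i in seq_along(tags)) {
    starts_new <- pre[i] == "B" ||
      (pre[i] == "I" && (is.null(cur) || cur$label != cls[i]))
    if (pre[i] == "O" || starts_new) {
      if (!is.null(cur)) { slots[[length(slots) + 1L]] <- cur; cur <- NULL }
    }
    if (pre[i] != "O" && (starts_new)) cur <- list(label = cls[i], first = i, last = i)
    else if (pre[i] != "O") cur$last <- i
  }
  if (!is.null(cur)) slots[[length(slots) + 1L]] <- cur
  slots
}

# enumerate every matching of two slot lists (positive overlap required),
# select by the total order (score desc, pairs desc, lexicographic pairs),
# return SER error counts
oracle_ser_counts <- function(gold_tags, pred_tags) {
  gs <- oracle_slots(gold_tags)
  ps <- oracle_slots(pred_tags)
  overlap <- function(g, p) max(0L, min(g$last, p$last) - max(g$first, p$first) + 1L)
  score1 <- function(g, p) {
    ov <- overlap(g, p)
    if (ov == 0L) return(0)
    4 * ov + 2 * (g$label == p$label) +
      1 * (g$first == p$first && g$last == p$last)
  }
  all_matchings <- list()
  recurse <- function(i, used_p, pairs) {
    if (i > length(gs)) {
      all_matchings[[length(all_matchings) + 1L]] <<- pairs
      return(invisible())
    }
    recurse(i + 1L, used_p, pairs)  # gold i unmatched
    for (j in seq_along(ps)) {
      if (!j %in% used_p && overlap(gs[[i]], ps[[j]]) > 0L) {
        recurse(i + 1L, c(used_p, j), c(pairs, list(c(i, j))))
      }
    }
  }
  recurse(1L, integer(), list())
  best <- NULL; best_key <- NULL
  for (m in all_matchings) {
    sc <- sum(vapply(m, function(pr) score1(gs[[pr[1]]], ps[[pr[2]]]), 0))
    key <- list(score = sc, n = length(m), flat = unlist(m))
    better <- is.null(best_key) || sc > best_key$score ||
      (sc == best_key$score && key$n > best_key$n)
    if (!better && !is.null(best_key) && sc == best_key$score &&
        key$n == best_key$n && key$n > 0) {
      d <- which(key$flat != best_key$flat)
      if (length(d) && key$flat[d[1]] < best_key$flat[d[1]]) better <- TRUE
    }
    if (better) { best <- m; best_key <- key }
  }
  D <- length(gs) - length(best)
  I <- length(ps) - length(best)
  Ty <- 0L; Fr <- 0L
  for (pr in best) {
    g <- gs[[pr[1]]]; p <- ps[[pr[2]]]
    if (g$label != p$label) Ty <- Ty + 1L
    if (g$first != p$first || g$last != p$last) Fr <- Fr + 1L
  }
  list(deletion = D, insertion = I, type = Ty, frontier = Fr,
       ref_slots = length(gs))
}

# random valid IOB sequence with roughly `density` entity mass
random_iob <- function(n, density = 0.5) {
  labs <- med_labels()
  tags <- character(n)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < density) {
      lab <- sample(labs, 1)
      len <- sample.int(3L, 1L)
      len <- min(len, n - i + 1L)
      tags[i:(i + len - 1L)] <- c(paste0("B-", lab),
                                  rep(paste0("I-", lab), len - 1L))
      i <- i + len
    } else {
      tags[i] <- "O"
      i <- i + 1L
    }
  }
  tags
}

# random corruption of a gold sequence (for alignment tests)
corrupt_iob <- function(tags, p_flip = 0.2) {
  labs <- med_labels()
  out <- tags
  for (i in seq_along(out)) {
    if (stats::runif(1) < p_flip) {
      out[i] <- sample(c("O", paste0(sample(c("B-", "I-"), 1), sample(labs, 1))), 1)
    }
  }
  out
}
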