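# Token-level micro-averaged metrics and slot error rate.
#
# Token scoring compares classes only (the B/I prefix is ignored: a gold
# B-dosage predicted I-dosage is a true positive); prefix mistakes surface
# at slot level as frontier errors. The slot error rate aggregates
# deletions D, insertions I, type errors T and frontier errors Fr as
#   SER = (D + I + 0.5 * (T + Fr)) / R
# with R the number of reference slots; a matched slot that is wrong in
# both class and boundary counts once (0.5 + 0.5).

#' Token-level confusion counts
#'
#' A token is a true positive of class `c` when gold and prediction agree
#' on `c`; a prediction of class `c` where gold says otherwise is a false
#' positive of `c` (and a false negative of the gold class when the gold
#' token is an entity); an entity token predicted `O` is a false negative.
#'
#' @param gold,pred Aligned IOB tag vectors (equal length).
#' @return Data frame with one row per category: `label`, `tp`, `fp`, `fn`.
#' @export
token_confusion <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and predicted sequences have different lengths")
  }
  validate_iob(gold); validate_iob(pred)
  g <- tag_class(gold); p <- tag_class(pred)
  labs <- med_labels()
  tp <- fp <- fn <- integer(length(labs))
  for (i in seq_along(labs)) {
    c <- labs[i]
    tp[i] <- sum(g == c & p == c)
    fp[i] <- sum(p == c & g != c)
    fn[i] <- sum(g == c & p != c)
  }
  data.frame(label = labs, tp = tp, fp = fp, fn = fn, stringsAsFactors = FALSE)
}

# sum confusion tables
add_confusion <- function(a, b) {
  a$tp <- a$tp + b$tp; a$fp <- a$fp + b$fp; a$fn <- a$fn + b$fn
  a
}

#' Confusion counts over lists of sequences
#'
#' @param gold_list,pred_list Lists of aligned IOB tag vectors.
#' @return Pooled confusion data frame as from [token_confusion()].
#' @export
token_confusion_all <- function(gold_list, pred_list) {
  stopifnot(length(gold_list) == length(pred_list))
  out <- data.frame(label = med_labels(), tp = 0L, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(gold_list)) {
    out <- add_confusion(out, token_confusion(gold_list[[i]], pred_list[[i]]))
  }
  out
}

#' Micro-averaged precision, recall and F-measure
#'
#' Per-class rows plus an `overall` row pooling counts across classes
#' (micro-averaging). Values are on the percent scale. A zero denominator
#' yields 0 and sets the `flagged` column.
#'
#' @param counts Confusion data frame from [token_confusion()].
#' @return Data frame `label`, `precision`, `recall`, `f`, `flagged`.
#' @export
micro_prf <- function(counts) {
  rows <- rbind(counts,
                data.frame(label = "overall", tp = sum(counts$tp),
                           fp = sum(counts$fp), fn = sum(counts$fn),
                           stringsAsFactors = FALSE))
  prf <- function(tp, fp, fn) {
    flagged <- (tp + fp == 0L) || (tp + fn == 0L)
    p <- if (tp + fp > 0L) tp / (tp + fp) else 0
    r <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(100 * p, 100 * r, 100 * f, flagged)
  }
  m <- t(mapply(prf, rows$tp, rows$fp, rows$fn))
  data.frame(label = rows$label, precision = m[, 1], recall = m[, 2],
             f = m[, 3], flagged = as.logical(m[, 4]),
             stringsAsFactors = FALSE)
}

#' Extract slots from an IOB sequence
#'
#' A slot is a maximal run of `B`/`I` tags of one class (lenient decoding:
#' an orphan `I-` opens a slot).
#'
#' @param tags IOB tag vector.
#' @return Data frame `label`, `first`, `last` (1-based token indices,
#'   inclusive).
#' @export
slots_from_tags <- function(tags) {
  validate_iob(tags)
  cls <- tag_class(tags); pre <- tag_prefix(tags)
  lab <- character(); first <- integer(); last <- integer()
  open <- NA_character_; start <- NA_integer_
  for (i in seq_along(tags)) {
    opens <- pre[i] == "B" || (pre[i] == "I" && (is.na(open) || open != cls[i]))
    if (pre[i] == "O" || opens) {
      if (!is.na(open)) {
        lab <- c(lab, open); first <- c(first, start); last <- c(last, i - 1L)
        open <- NA_character_
      }
    }
    if (pre[i] != "O" && (opens || pre[i] == "B")) {
      open <- cls[i]; start <- i
    }
  }
  if (!is.na(open)) {
    lab <- c(lab, open); first <- c(first, start); last <- c(last, length(tags))
  }
  data.frame(label = lab, first = first, last = last, stringsAsFactors = FALSE)
}

# pair score for slot alignment: token overlap dominates, then matching
# class, then exact boundaries; > 0 required for a pair to be matched.
slot_pair_score <- function(g, p) {
  ov <- max(0L, min(g$last, p$last) - max(g$first, p$first) + 1L)
  if (ov == 0L) return(0)
  4 * ov + 2 * (g$label == p$label) +
    1 * (g$first == p$first && g$last == p$last)
}

# exact optimal alignment of two ordered slot lists. Positive-overlap
# pairs cannot cross (slots are disjoint and ordered), so the DP over
# (gold suffix, pred suffix) enumerates every feasible matching. Total
# order on solutions: maximize score, then number of pairs, then the
# lexicographically earliest pair list -- making the optimum unique.
align_slot_tables <- function(gs, ps) {
  ng <- nrow(gs); np <- nrow(ps)
  memo <- vector("list", (ng + 1L) * (np + 1L))
  key <- function(i, j) (i - 1L) * (np + 1L) + j
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$score != b$score) return(a$score > b$score)
    if (length(a$pairs) != length(b$pairs)) {
      return(length(a$pairs) > length(b$pairs))
    }
    av <- unlist(a$pairs); bv <- unlist(b$pairs)
    d <- which(av != bv)
    if (length(d) == 0L) return(FALSE)
    av[d[1]] < bv[d[1]]
  }
  rec <- function(i, j) {
    k <- key(i, j)
    if (!is.null(memo[[k]])) return(memo[[k]])
    if (i > ng && j > np) {
      res <- list(score = 0, pairs = list())
    } else {
      best <- NULL
      if (i <= ng && j <= np) {
        s <- slot_pair_score(gs[i, ], ps[j, ])
        if (s > 0) {
          sub <- rec(i + 1L, j + 1L)
          cand <- list(score = s + sub$score,
                       pairs = c(list(c(i, j)), sub$pairs))
          if (better(cand, best)) best <- cand
        }
      }
      if (i <= ng) {
        sub <- rec(i + 1L, j)
        if (better(sub, best)) best <- sub
      }
      if (j <= np) {
        sub <- rec(i, j + 1L)
        if (better(sub, best)) best <- sub
      }
      res <- best
    }
    memo[[k]] <<- res
    res
  }
  rec(1L, 1L)
}

# error counts for one aligned pair of tag sequences
slot_error_counts <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and predicted sequences have different lengths")
  }
  gs <- slots_from_tags(gold)
  ps <- slots_from_tags(pred)
  aln <- align_slot_tables(gs, ps)
  matched_g <- vapply(aln$pairs, `[`, integer(1), 1L)
  matched_p <- vapply(aln$pairs, `[`, integer(1), 2L)
  D <- nrow(gs) - length(matched_g)
  I <- nrow(ps) - length(matched_p)
  Ty <- 0L; Fr <- 0L; correct <- 0L
  for (pr in aln$pairs) {
    g <- gs[pr[1], ]; p <- ps[pr[2], ]
    same_class <- g$label == p$label
    same_bounds <- g$first == p$first && g$last == p$last
    if (same_class && same_bounds) correct <- correct + 1L
    if (!same_class) Ty <- Ty + 1L
    if (!same_bounds) Fr <- Fr + 1L
  }
  list(deletion = D, insertion = I, type = Ty, frontier = Fr,
       correct = correct, ref_slots = nrow(gs))
}

#' Slot error rate report
#'
#' Aligns gold and predicted slots per sequence with an exact optimal
#' matching, classifies each matched pair (correct; type error: same
#' boundaries, different class; frontier error: same class, overlapping
#' but different boundaries; both wrong: one type plus one frontier error)
#' and counts unmatched gold slots as deletions and unmatched predicted
#' slots as insertions. Rates are counts divided by the reference slot
#' count and the aggregate is `SER = (D + I + 0.5*(T + Fr)) / R`.
#'
#' @param gold,pred Aligned IOB tag vectors, or lists thereof (counts are
#'   pooled across sequences).
#' @return An object of class `ser_report`: list with `counts`, `rates`,
#'   `ref_slots` and `ser`.
#' @export
ser_report <- function(gold, pred) {
  if (!is.list(gold)) gold <- list(gold)
  if (!is.list(pred)) pred <- list(pred)
  stopifnot(length(gold) == length(pred))
  tot <- list(deletion = 0L, insertion = 0L, type = 0L, frontier = 0L,
              correct = 0L, ref_slots = 0L)
  for (i in seq_along(gold)) {
    c1 <- slot_error_counts(gold[[i]], pred[[i]])
    tot <- Map(`+`, tot, c1)
  }
  R <- tot$ref_slots
  rates <- if (R > 0) {
    lapply(tot[c("deletion", "insertion", "type", "frontier")],
           function(x) x / R)
  } else {
    list(deletion = 0, insertion = 0, type = 0, frontier = 0)
  }
  ser <- if (R > 0) {
    (tot$deletion + tot$insertion + 0.5 * (tot$type + tot$frontier)) / R
  } else 0
  structure(list(counts = tot, rates = rates, ref_slots = R, ser = ser),
            class = "ser_report")
}

#' @export
print.ser_report <- function(x, digits = 2, ...) {
  cat(sprintf("Slot error rate: %.*f  (R = %d reference slots)\n",
              digits, x$ser, x$ref_slots))
  cat(sprintf("  deletions %d (%.*f)  insertions %d (%.*f)  type %d (%.*f)  frontier %d (%.*f)\n",
              x$counts$deletion, digits, x$rates$deletion,
              x$counts$insertion, digits, x$rates$insertion,
              x$counts$type, digits, x$rates$type,
              x$counts$frontier, digits, x$rates$frontier))
  invisible(x)
}

#' Aggregate SER from printed component rates
#'
#' Combines already-normalized insertion, deletion, type and frontier
#' error rates into the aggregate slot error rate under the half-weight
#' substitution convention, `SER = D + I + 0.5 * (T + Fr)`.
#'
#' @param insertion,deletion,type,frontier Component error rates.
#' @param digits Rounding of the result (2, matching published tables);
#'   `NA` for no rounding.
#' @return The aggregate slot error rate.
#' @export
#' @examples
#' ser_from_rates(insertion = 0.03, deletion = 0.23,
#'                type = 0.02, frontier = 0.04)  # 0.29
ser_from_rates <- function(insertion, deletion, type, frontier, digits = 2) {
  ser <- deletion + insertion + 0.5 * (type + frontier)
  if (is.na(digits)) ser else round(ser, digits)
}

#' Evaluate a CoNLL-style file pair of tag columns
#'
#' Convenience wrapper: computes micro P/R/F and the SER report between
#' two tag layers of a [read_conll()] frame.
#'
#' @param conll Data frame from [read_conll()].
#' @param gold_col,pred_col Column names holding the gold and system tags.
#' @return List with `metrics` (from [micro_prf()]) and `ser`.
#' @export
evaluate_conll <- function(conll, gold_col = "gold_tag", pred_col = "rule_tag") {
  gold <- split(conll[[gold_col]], conll$sentence)
  pred <- split(conll[[pred_col]], conll$sentence)
  counts <- token_confusion_all(gold, pred)
  list(metrics = micro_prf(counts), ser = ser_report(gold, pred))
}
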