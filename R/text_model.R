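# Span/IOB data model and standoff / CoNLL readers and writers.

#' Build an entity span table
#'
#' @param label Category names (see [med_labels()]).
#' @param start,end 0-based half-open character offsets into the normalized
#'   document text.
#' @param source Annotation layer: `"gold"`, `"rule"` or `"model"`.
#' @param text Optional surface strings.
#' @return Data frame with the canonical span columns.
#' @export
entity_spans <- function(label = character(), start = integer(),
                         end = integer(), source = "gold", text = NA_character_) {
  if (length(label) == 0L) return(empty_spans())
  check_labels(label)
  stopifnot(all(start >= 0L), all(end > start))
  data.frame(label = as.character(label), start = as.integer(start),
             end = as.integer(end),
             source = rep_len(as.character(source), length(label)),
             text = rep_len(as.character(text), length(label)),
             stringsAsFactors = FALSE)
}

#' Resolve overlapping spans within one annotation layer
#'
#' Longer spans win; ties go to the earlier start. Spans from different
#' sources are never resolved against each other.
#'
#' @param spans Span data frame.
#' @return Non-overlapping subset (per source), original order restored.
#' @export
resolve_spans <- function(spans) {
  if (nrow(spans) <= 1L) return(spans)
  keep_rows <- logical(nrow(spans))
  for (src in unique(spans$source)) {
    idx <- which(spans$source == src)
    ord <- idx[order(-(spans$end[idx] - spans$start[idx]), spans$start[idx])]
    taken <- logical(0)
    iv <- matrix(numeric(0), ncol = 2)
    for (i in ord) {
      s <- spans$start[i]; e <- spans$end[i]
      if (nrow(iv) == 0L || all(e <= iv[, 1] | s >= iv[, 2])) {
        keep_rows[i] <- TRUE
        iv <- rbind(iv, c(s, e))
      }
    }
  }
  out <- spans[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert character spans to an IOB tag sequence
#'
#' A token receives the span's tag if any of its characters overlap the
#' span (any-overlap rule): the first overlapped token gets `B-label`,
#' subsequent ones `I-label`, everything else `O`. Overlaps within the
#' input are resolved first with [resolve_spans()]. Spans overlapping no
#' token are dropped with a warning; the count is attached as attribute
#' `"dropped"`.
#'
#' @param tokens Token data frame for one sentence (columns `text`,
#'   `start`, `end`).
#' @param spans Span data frame (offsets in the same text).
#' @param warn Warn on dropped spans (default `TRUE`).
#' @return Character vector of tags, one per token.
#' @export
spans_to_iob <- function(tokens, spans, warn = TRUE) {
  tags <- rep("O", nrow(tokens))
  spans <- resolve_spans(spans)
  dropped <- 0L
  if (nrow(spans)) {
    spans <- spans[order(spans$start), , drop = FALSE]
    for (i in seq_len(nrow(spans))) {
      hit <- which(tokens$start < spans$end[i] & tokens$end > spans$start[i])
      if (length(hit) == 0L) {
        dropped <- dropped + 1L
        next
      }
      tags[hit] <- paste0("I-", spans$label[i])
      tags[hit[1]] <- paste0("B-", spans$label[i])
    }
  }
  if (dropped > 0L && warn) {
    warning(sprintf("%d span(s) overlapped no token and were dropped", dropped))
  }
  attr(tags, "dropped") <- dropped
  tags
}

#' Decode an IOB tag sequence into character spans
#'
#' Maximal runs of `B`/`I` tags of one class become spans from the first
#' token's start to the last token's end. Decoding is lenient by default:
#' an `I-` tag without a same-class predecessor opens a new span (neural
#' taggers emit such sequences). With `strict = TRUE` orphan `I-` tags are
#' treated as `O`.
#'
#' @param tokens Token data frame aligned with `tags`.
#' @param tags IOB tag vector.
#' @param source Source recorded on the produced spans.
#' @param strict Drop orphan `I-` tags instead of opening spans.
#' @return Span data frame.
#' @export
iob_to_spans <- function(tokens, tags, source = "model", strict = FALSE) {
  stopifnot(nrow(tokens) == length(tags))
  validate_iob(tags)
  cls <- tag_class(tags)
  pre <- tag_prefix(tags)
  out <- empty_spans()
  open_cls <- NULL
  open_first <- NA_integer_
  close_span <- function(last) {
    out[nrow(out) + 1L, ] <<- list(open_cls, tokens$start[open_first],
                                   tokens$end[last], source, NA_character_)
  }
  for (i in seq_along(tags)) {
    if (pre[i] == "O") {
      if (!is.null(open_cls)) { close_span(i - 1L); open_cls <- NULL }
    } else if (pre[i] == "B") {
      if (!is.null(open_cls)) close_span(i - 1L)
      open_cls <- cls[i]; open_first <- i
    } else {  # I
      continues <- !is.null(open_cls) && open_cls == cls[i]
      if (!continues) {
        if (!is.null(open_cls)) close_span(i - 1L)
        if (strict) {
          open_cls <- NULL
        } else {
          open_cls <- cls[i]; open_first <- i
        }
      }
    }
  }
  if (!is.null(open_cls)) close_span(length(tags))
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  rownames(out) <- NULL
  out
}

#' Per-sentence IOB tags for a whole document
#'
#' @param doc A `med_document`.
#' @param source Which span layer to convert (`"gold"`, `"rule"`, `"model"`).
#' @param warn Warn on spans overlapping no token.
#' @return List of tag vectors, one per sentence.
#' @export
doc_iob <- function(doc, source = "gold", warn = TRUE) {
  spans <- doc$spans[doc$spans$source == source, , drop = FALSE]
  n_sent <- nrow(doc$sentences)
  out <- vector("list", n_sent)
  for (k in seq_len(n_sent)) {
    toks <- doc$tokens[doc$tokens$sentence == k, , drop = FALSE]
    sel <- spans[spans$start < doc$sentences$end[k] &
                   spans$end > doc$sentences$start[k], , drop = FALSE]
    out[[k]] <- spans_to_iob(toks, sel, warn = warn)
  }
  out
}

#' Document-level spans from per-sentence predicted tags
#'
#' @param doc A `med_document`.
#' @param tag_list List of tag vectors, one per sentence.
#' @inheritParams iob_to_spans
#' @return Span data frame with document-absolute offsets.
#' @export
doc_spans_from_iob <- function(doc, tag_list, source = "model", strict = FALSE) {
  stopifnot(length(tag_list) == nrow(doc$sentences))
  parts <- lapply(seq_along(tag_list), function(k) {
    toks <- doc$tokens[doc$tokens$sentence == k, , drop = FALSE]
    iob_to_spans(toks, tag_list[[k]], source = source, strict = strict)
  })
  out <- do.call(rbind, c(parts, list(empty_spans())))
  rownames(out) <- NULL
  out
}

# ---- BRAT standoff ---------------------------------------------------------

read_text_file <- function(path) {
  txt <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  # normalize platform line endings; trailing newline is not document text
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  sub("\n$", "", txt)
}

#' Read a document with BRAT standoff annotations
#'
#' Parses `T` lines of the form
#' `T<id><TAB><LABEL> <start> <end><TAB><surface>` (offsets 0-based,
#' half-open, into the text file). Each surface string is verified against
#' the text slice; offsets are then mapped into the normalized text and the
#' spans stored with `source = "gold"`.
#'
#' @param text_path Path to the `.txt` file.
#' @param ann_path Path to the `.ann` file.
#' @param doc_id Document id (defaults to the text file name).
#' @param continuation Sentence-boundary blocking words.
#' @return A `med_document` with gold spans.
#' @export
read_standoff <- function(text_path, ann_path, doc_id = basename(text_path),
                          continuation = default_continuation()) {
  raw <- read_text_file(text_path)
  doc <- preprocess_document(raw, doc_id = doc_id, continuation = continuation)
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[startsWith(lines, "T")]
  if (length(lines) == 0L) return(doc)
  m <- regmatches(lines,
                  regexec("^T[0-9]+\t([^\t ]+) ([0-9]+) ([0-9]+)\t(.*)$", lines))
  spans <- empty_spans()
  for (i in seq_along(lines)) {
    f <- m[[i]]
    if (length(f) == 0L) stop("malformed annotation line: ", lines[i])
    label <- f[2]
    if (!label %in% med_labels()) stop("unknown label: ", label)
    s <- as.integer(f[3]); e <- as.integer(f[4])
    if (is.na(s) || is.na(e) || s < 0L || e > nchar(raw) || s >= e) {
      stop("malformed annotation: offsets ", f[3], " ", f[4],
           " outside text of length ", nchar(raw))
    }
    surface <- f[5]
    if (substr0(raw, s, e) != surface) {
      stop(sprintf("malformed annotation: surface '%s' != text slice '%s'",
                   surface, substr0(raw, s, e)))
    }
    idx <- which(doc$offset_map >= s & doc$offset_map <= e - 1L)
    if (length(idx) == 0L) stop("annotation lost by normalization: ", lines[i])
    spans <- rbind(spans, entity_spans(label, min(idx) - 1L, max(idx),
                                       source = "gold", text = surface))
  }
  doc$spans <- rbind(doc$spans, spans)
  rownames(doc$spans) <- NULL
  doc
}

#' Write a span layer as BRAT standoff
#'
#' Writes `<prefix>.txt` (the normalized text) and `<prefix>.ann` with
#' offsets into it, so the pair round-trips through [read_standoff()].
#'
#' @param doc A `med_document`.
#' @param prefix Output path prefix.
#' @param source Which span layer to write.
#' @return Invisibly, the `.ann` path.
#' @export
write_standoff <- function(doc, prefix, source = "rule") {
  spans <- doc$spans[doc$spans$source == source, , drop = FALSE]
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  writeLines(doc$text, paste0(prefix, ".txt"), useBytes = TRUE)
  lines <- character(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    lines[i] <- sprintf("T%d\t%s %d %d\t%s", i, spans$label[i],
                        spans$start[i], spans$end[i],
                        substr0(doc$text, spans$start[i], spans$end[i]))
  }
  writeLines(lines, paste0(prefix, ".ann"), useBytes = TRUE)
  invisible(paste0(prefix, ".ann"))
}

# ---- CoNLL-style columns ---------------------------------------------------

#' Write a document in CoNLL-style columns
#'
#' One token per line, `token<TAB>rule_tag<TAB>gold_tag`, with a blank line
#' after each sentence. Tags are computed from the document's span layers.
#'
#' @param doc A `med_document` with gold and/or rule spans.
#' @param path Output file path.
#' @param rule_tags,gold_tags Optional precomputed per-sentence tag lists;
#'   by default derived from the `rule` and `gold` span layers.
#' @return Invisibly, `path`.
#' @export
write_conll <- function(doc, path,
                        rule_tags = doc_iob(doc, "rule", warn = FALSE),
                        gold_tags = doc_iob(doc, "gold", warn = FALSE)) {
  n_sent <- nrow(doc$sentences)
  stopifnot(length(rule_tags) == n_sent, length(gold_tags) == n_sent)
  out <- character()
  for (k in seq_len(n_sent)) {
    toks <- doc$tokens$text[doc$tokens$sentence == k]
    if (length(toks) != length(rule_tags[[k]]) ||
        length(toks) != length(gold_tags[[k]])) {
      stop("tag/token alignment error in sentence ", k)
    }
    out <- c(out, paste(toks, rule_tags[[k]], gold_tags[[k]], sep = "\t"), "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a CoNLL-style column file
#'
#' @param path File written by [write_conll()].
#' @return Data frame with columns `sentence`, `token`, `rule_tag`,
#'   `gold_tag`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  empty <- data.frame(sentence = integer(), token = character(),
                      rule_tag = character(), gold_tag = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  blank <- !nzchar(lines)
  sent_id <- cumsum(blank) + 1L
  tok_lines <- lines[!blank]
  if (length(tok_lines) == 0L) return(empty)
  parts <- strsplit(tok_lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("malformed CoNLL line: ", tok_lines[which(lengths(parts) != 3L)[1]])
  }
  mat <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  data.frame(sentence = sent_id[!blank], token = mat[, 1],
             rule_tag = mat[, 2], gold_tag = mat[, 3],
             stringsAsFactors = FALSE)
}

#' CoNLL view of a document, as returned by [read_conll()]
#'
#' @inheritParams write_conll
#' @return Data frame with columns `sentence`, `token`, `rule_tag`,
#'   `gold_tag`; useful for round-trip checks and downstream tools.
#' @export
conll_frame <- function(doc,
                        rule_tags = doc_iob(doc, "rule", warn = FALSE),
                        gold_tags = doc_iob(doc, "gold", warn = FALSE)) {
  n_sent <- nrow(doc$sentences)
  parts <- lapply(seq_len(n_sent), function(k) {
    toks <- doc$tokens$text[doc$tokens$sentence == k]
    data.frame(sentence = rep(k, length(toks)), token = toks,
               rule_tag = as.vector(rule_tags[[k]]),
               gold_tag = as.vector(gold_tags[[k]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(parts, list(
    data.frame(sentence = integer(), token = character(),
               rule_tag = character(), gold_tag = character(),
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}
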