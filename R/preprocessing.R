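# Text normalization, sentence splitting and tokenization for French
# clinical text. All offsets in this package are 0-based, half-open, and
# refer to the *normalized* text; the offset map converts back to raw text.

# Accented characters handled by normalization. Closed table (rather than a
# transliteration library) so that every output character carries an exact
# source index; oe/ae ligatures expand to two characters sharing one index.
accent_map <- local({
  m <- c(
    "à" = "a", "â" = "a", "ä" = "a", "á" = "a",
    "é" = "e", "è" = "e", "ê" = "e", "ë" = "e",
    "î" = "i", "ï" = "i", "í" = "i",
    "ô" = "o", "ö" = "o", "ó" = "o",
    "ù" = "u", "û" = "u", "ü" = "u", "ú" = "u",
    "ç" = "c", "ÿ" = "y", "ñ" = "n",
    "œ" = "oe", "æ" = "ae"
  )
  up <- toupper(m)
  names(up) <- toupper(names(m))
  c(m, up)
})

apostrophe_chars <- c("'", "’", "ʼ", "`", "´")

is_upper_ascii <- function(ch) ch %in% LETTERS
is_letter_ascii <- function(ch) ch %in% c(LETTERS, letters)
is_digit_chr <- function(ch) ch %in% as.character(0:9)
is_lower_letter <- function(ch) {
  ch %in% letters || (ch %in% names(accent_map) && ch == tolower(ch))
}

#' Normalize raw clinical text
#'
#' Applies, in order: carriage-return cleanup; removal of acronym-internal
#' periods (periods chained between single uppercase letters, so `"I.V."`
#' becomes `"IV"`) and replacement of decimal points between digits by
#' commas; removal of line breaks that are document-conversion wrap
#' artifacts (line not ending with a period and next line starting
#' lowercase), replaced by spaces; accent stripping to ASCII base letters;
#' and replacement of apostrophes by spaces. Case is preserved. The
#' function is total and idempotent.
#'
#' @param raw Character scalar, the raw document text (UTF-8).
#' @return A list with `text` (the normalized string) and `offset_map`, an
#'   integer vector with one 0-based raw-text index per normalized
#'   character (monotone non-decreasing).
#' @export
#' @examples
#' normalize_text("2.5 mg d'aspirine")$text   # "2,5 mg d aspirine"
#' normalize_text("à jeûn")$text    # "a jeun"
normalize_text <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw) || nchar(raw) == 0L) {
    return(list(text = "", offset_map = integer()))
  }
  chars <- strsplit(raw, "", fixed = FALSE)[[1]]
  map <- seq_along(chars) - 1L

  # carriage returns: \r\n -> \n, lone \r -> \n
  cr <- chars == "\r"
  if (any(cr)) {
    nxt <- c(chars[-1], "")
    drop <- cr & nxt == "\n"
    chars[cr & !drop] <- "\n"
    chars <- chars[!drop]
    map <- map[!drop]
  }

  n <- length(chars)
  keep <- rep(TRUE, n)
  acro_dropped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (chars[i] != ".") next
    p1 <- if (i > 1L) chars[i - 1L] else ""
    p2 <- if (i > 2L) chars[i - 2L] else ""
    nx <- if (i < n) chars[i + 1L] else ""
    n2 <- if (i + 1L < n) chars[i + 2L] else ""
    if (is_digit_chr(p1) && is_digit_chr(nx)) {
      chars[i] <- ","  # decimal point
      next
    }
    between <- is_upper_ascii(p1) && !is_letter_ascii(p2) &&
      is_upper_ascii(nx) && (!is_letter_ascii(n2) || n2 == ".")
    chained <- is_upper_ascii(p1) && p2 == "." && i > 2L && acro_dropped[i - 2L]
    if (between || chained) {
      keep[i] <- FALSE
      acro_dropped[i] <- TRUE
    }
  }
  chars <- chars[keep]
  map <- map[keep]

  # wrap-artifact line breaks -> spaces; real breaks kept for splitting
  nl <- which(chars == "\n")
  for (i in nl) {
    before <- chars[seq_len(i - 1L)]
    before <- before[before != " " & before != "\t"]
    prev <- if (length(before)) before[length(before)] else ""
    after <- if (i < length(chars)) chars[(i + 1L):length(chars)] else character()
    after <- after[!(after %in% c(" ", "\t"))]
    after <- if (length(after)) after[1L] else ""
    if (prev != "" && prev != "." && prev != "\n" && is_lower_letter(after)) {
      chars[i] <- " "
    }
  }

  # accents (may expand ligatures), then apostrophes
  hit <- chars %in% names(accent_map)
  if (any(hit)) {
    repl <- accent_map[chars[hit]]
    wide <- nchar(repl) > 1L
    if (any(wide)) {
      out_chars <- vector("list", length(chars))
      out_map <- vector("list", length(chars))
      for (j in seq_along(chars)) {
        r <- if (hit[j]) accent_map[[chars[j]]] else chars[j]
        out_chars[[j]] <- strsplit(r, "")[[1]]
        out_map[[j]] <- rep(map[j], nchar(r))
      }
      chars <- unlist(out_chars, use.names = FALSE)
      map <- unlist(out_map, use.names = FALSE)
    } else {
      chars[hit] <- unname(repl)
    }
  }
  chars[chars %in% apostrophe_chars] <- " "

  list(text = paste(chars, collapse = ""), offset_map = as.integer(map))
}

continuation_cache <- new.env(parent = emptyenv())

#' Default French continuation-word list
#'
#' Words (prepositions, coordinating and common subordinating conjunctions)
#' that block a sentence boundary when adjacent to a candidate period or
#' line break, shipped as a plain-text config file (one word per line,
#' lines starting with `#` ignored).
#'
#' @param path Optional path to an alternative list file.
#' @return Character vector of lowercase words.
#' @export
default_continuation <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(continuation_cache$words)) return(continuation_cache$words)
    path <- system.file("extdata", "continuation_fr.txt", package = "medextract")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- tolower(trimws(lines))
  words <- words[nzchar(words) & !startsWith(words, "#")]
  continuation_cache$words <- words
  words
}

#' Split normalized text into sentences
#'
#' Boundaries are the periods and line breaks remaining after
#' [normalize_text()], except where the word immediately before or after
#' the candidate boundary belongs to the continuation list (so a line
#' break followed by e.g. `"et"` does not split). The terminating period
#' stays inside its sentence; line breaks and surrounding whitespace are
#' trimmed away.
#'
#' @param text Normalized text.
#' @param continuation Character vector of boundary-blocking words.
#' @return Data frame with columns `start`, `end` (0-based, half-open) and
#'   `text`, one row per non-empty sentence.
#' @export
split_sentences <- function(text, continuation = default_continuation()) {
  empty <- data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || nchar(text) == 0L) return(empty)
  chars <- strsplit(text, "")[[1]]
  cand <- which(chars == "." | chars == "\n")

  wml <- gregexpr("[[:alnum:]]+", text)
  wm <- wml[[1]]
  wstart <- as.integer(wm)
  wlen <- attr(wm, "match.length")
  has_words <- wstart[1] != -1L
  is_boundary <- rep(TRUE, length(cand))
  if (has_words && length(cand)) {
    wend <- wstart + wlen - 1L
    words <- tolower(regmatches(text, wml)[[1]])
    for (k in seq_along(cand)) {
      pos <- cand[k]
      iprev <- findInterval(pos - 1L, wstart)
      prev_ok <- iprev >= 1L && wend[iprev] < pos
      prev_w <- if (prev_ok) words[iprev] else ""
      inext <- findInterval(pos, wstart) + 1L
      next_w <- if (inext <= length(words)) words[inext] else ""
      if (prev_w %in% continuation || next_w %in% continuation) {
        is_boundary[k] <- FALSE
      }
    }
  }
  cuts <- cand[is_boundary]
  seg_start <- c(1L, cuts + 1L)
  seg_end <- c(cuts, length(chars))  # boundary char belongs to left segment
  out <- empty
  for (k in seq_along(seg_start)) {
    s <- seg_start[k]; e <- seg_end[k]
    if (s > e) next
    seg <- chars[s:e]
    ws <- seg %in% c(" ", "\t", "\n")
    if (all(ws)) next
    first <- s + which(!ws)[1] - 1L
    last <- s + max(which(!ws)) - 1L
    out <- rbind(out, data.frame(
      start = first - 1L, end = last, text = substr(text, first, last),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Tokenize a normalized sentence
#'
#' Tokens are maximal runs of alphanumeric characters, or maximal runs of
#' a single repeated non-alphanumeric non-space character (`"!!!"` is one
#' token, `"?!"` is two). Whitespace separates tokens and is discarded.
#'
#' @param text Normalized text.
#' @param start,end 0-based half-open window to tokenize (defaults to the
#'   whole string). Returned offsets are absolute within `text`.
#' @return Data frame with columns `text`, `start`, `end`.
#' @export
#' @examples
#' tokenize("doliprane 1g matin")$text  # "doliprane" "1g" "matin"
#' tokenize("3x/jour !!!")$text         # "3x" "/" "jour" "!!!"
tokenize <- function(text, start = 0L, end = nchar(text)) {
  seg <- substr0(text, start, end)
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(seg) == 0L) return(empty)
  ml <- gregexpr("[[:alnum:]]+|([^[:alnum:][:space:]])\\1*", seg, perl = TRUE)
  m <- ml[[1]]
  if (m[1] == -1L) return(empty)
  starts <- start + as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(text = regmatches(seg, ml)[[1]],
             start = starts, end = starts + lens,
             stringsAsFactors = FALSE)
}

#' Preprocess a raw document
#'
#' Runs normalization, sentence splitting and tokenization, producing the
#' annotated-document container used by the rule engine, the tagger and
#' the evaluation layer. Entity spans (gold, rule or model) are stored in
#' `$spans` with 0-based half-open offsets into `$text`.
#'
#' @param raw Raw document text.
#' @param doc_id Document identifier.
#' @param continuation Sentence-boundary blocking words.
#' @return An object of class `med_document`: a list with `doc_id`,
#'   `raw_text`, `text`, `offset_map`, `sentences` (data frame), `tokens`
#'   (data frame with a `sentence` index column) and `spans`.
#' @export
preprocess_document <- function(raw, doc_id = "doc",
                                continuation = default_continuation()) {
  norm <- normalize_text(raw)
  sents <- split_sentences(norm$text, continuation)
  tok_list <- vector("list", nrow(sents))
  for (k in seq_len(nrow(sents))) {
    tk <- tokenize(norm$text, sents$start[k], sents$end[k])
    if (nrow(tk)) tk$sentence <- k
    tok_list[[k]] <- tk
  }
  tokens <- if (length(tok_list)) do.call(rbind, tok_list) else
    data.frame(text = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  if (is.null(tokens$sentence)) tokens$sentence <- integer()
  rownames(tokens) <- NULL
  structure(list(doc_id = doc_id, raw_text = raw, text = norm$text,
                 offset_map = norm$offset_map, sentences = sents,
                 tokens = tokens, spans = empty_spans()),
            class = "med_document")
}

#' @export
print.med_document <- function(x, ...) {
  cat(sprintf("<med_document '%s': %d sentences, %d tokens, %d spans>\n",
              x$doc_id, nrow(x$sentences), nrow(x$tokens), nrow(x$spans)))
  invisible(x)
}
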