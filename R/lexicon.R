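# Unified drug dictionary and exact-match anchor detection.
#
# Surfaces are normalized with the preprocessing module, tokenized, and
# case-folded; matching is exact at the token-sequence level (no stemming,
# no edit distance) to keep anchor precision maximal.

atc_pattern <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

surface_key <- function(text) {
  norm <- normalize_text(tolower(text))$text
  toks <- tokenize(norm)
  if (nrow(toks) == 0L) return(NA_character_)
  paste(toks$text, collapse = " ")
}

#' Build the unified drug lexicon
#'
#' Takes one or more drug tables (as from the public national drug
#' databases, possibly one per year), normalizes and case-folds each
#' surface form with the package tokenizer, and deduplicates across
#' tables. Rows with an empty name are skipped and counted; malformed ATC
#' codes are kept with a warning and the code set to `"unknown"`. A
#' surface listed both as a medication name and as a class resolves to
#' `medication_name` (logged via `message`).
#'
#' @param tables A data frame, or list of data frames, with columns
#'   `name`, `atc`, `type` (`type` being `"medication_name"` or
#'   `"medication_class"`).
#' @return An object of class `drug_lexicon`: list with `entries` (data
#'   frame `surface`, `n_tokens`, `normalized_name`, `atc_code`,
#'   `entry_type`), `index` (environment keyed by surface), `max_len`,
#'   and attribute `n_skipped`.
#' @export
build_lexicon <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(t) {
    stopifnot(all(c("name", "atc", "type") %in% names(t)))
    data.frame(name = as.character(t$name), atc = as.character(t$atc),
               type = as.character(t$type), stringsAsFactors = FALSE)
  }))
  n_skipped <- 0L
  entries <- data.frame(surface = character(), n_tokens = integer(),
                        normalized_name = character(), atc_code = character(),
                        entry_type = character(), stringsAsFactors = FALSE)
  seen <- character()
  for (i in seq_len(nrow(rows))) {
    nm <- trimws(rows$name[i])
    if (is.na(nm) || !nzchar(nm)) { n_skipped <- n_skipped + 1L; next }
    type <- rows$type[i]
    if (!type %in% c("medication_name", "medication_class")) {
      stop("entry_type must be medication_name or medication_class, got: ", type)
    }
    key <- surface_key(nm)
    if (is.na(key)) { n_skipped <- n_skipped + 1L; next }
    pair <- paste(key, type)
    if (pair %in% seen) next
    seen <- c(seen, pair)
    atc <- toupper(trimws(rows$atc[i]))
    if (is.na(atc) || !grepl(atc_pattern, atc)) {
      warning("malformed ATC code '", rows$atc[i], "' for '", nm,
              "'; setting to unknown")
      atc <- "unknown"
    }
    entries[nrow(entries) + 1L, ] <- list(
      key, nrow(tokenize(key)), tolower(nm), atc, type)
  }
  # ambiguous name/class surfaces resolve to medication_name
  dup <- entries$surface[duplicated(entries$surface)]
  for (s in unique(dup)) {
    message("surface '", s, "' listed as both name and class; keeping medication_name")
    drop <- which(entries$surface == s & entries$entry_type == "medication_class")
    entries <- entries[-drop, , drop = FALSE]
  }
  rownames(entries) <- NULL
  index <- new.env(parent = emptyenv(), size = max(16L, nrow(entries)))
  for (i in seq_len(nrow(entries))) assign(entries$surface[i], i, envir = index)
  structure(list(entries = entries, index = index,
                 max_len = if (nrow(entries)) max(entries$n_tokens) else 0L),
            class = "drug_lexicon", n_skipped = n_skipped)
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat(sprintf("<drug_lexicon: %d entries (%d names, %d classes), max %d tokens>\n",
              nrow(x$entries),
              sum(x$entries$entry_type == "medication_name"),
              sum(x$entries$entry_type == "medication_class"),
              x$max_len))
  invisible(x)
}

#' Read / write a lexicon CSV
#'
#' Column layout `surface,normalized_name,atc_code,entry_type` with header.
#'
#' @param lexicon A `drug_lexicon`.
#' @param path CSV path.
#' @return [write_lexicon()] returns `path` invisibly; [read_lexicon()] a
#'   `drug_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.csv(lexicon$entries[, c("surface", "normalized_name",
                                       "atc_code", "entry_type")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  build_lexicon(data.frame(name = df$surface, atc = df$atc_code,
                           type = df$entry_type, stringsAsFactors = FALSE))
}

#' Exact dictionary matching of drug mentions
#'
#' Scans a sentence's tokens for contiguous case-folded token subsequences
#' present in the lexicon. Disambiguation is longest-leftmost: at each
#' position the longest matching surface wins and scanning resumes after
#' it, so matches never overlap.
#'
#' @param tokens Token data frame (one sentence).
#' @param lexicon A `drug_lexicon`.
#' @return Span data frame (`source = "rule"`), labels taken from the
#'   entry type (`medication_name` or `medication_class`).
#' @export
match_exact <- function(tokens, lexicon) {
  n <- nrow(tokens)
  out <- empty_spans()
  if (n == 0L || lexicon$max_len == 0L) return(out)
  folded <- tolower(tokens$text)
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in seq(min(lexicon$max_len, n - i + 1L), 1L)) {
      key <- paste(folded[i:(i + len - 1L)], collapse = " ")
      idx <- get0(key, envir = lexicon$index, inherits = FALSE)
      if (!is.null(idx)) {
        out <- rbind(out, entity_spans(
          lexicon$entries$entry_type[idx],
          tokens$start[i], tokens$end[i + len - 1L],
          source = "rule", text = key))
        hit_len <- len
        break
      }
    }
    i <- i + max(hit_len, 1L)
  }
  rownames(out) <- NULL
  out
}
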