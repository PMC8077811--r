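# Anchor-centered attribute extraction. A drug or drug-class mention found
# by exact dictionary matching serves as the anchor; handcrafted regular
# expressions search the surrounding token window for the five attributes.
# Extraction is anchor-gated: a sentence with no anchor yields no spans.

attribute_order <- c("dosage", "frequency", "duration", "route", "condition")

#' Construct a rule set
#'
#' @param rules Data frame with columns `attribute`, `pattern` and
#'   optionally `window` (token distance from the anchor, `NA` = engine
#'   default) and `direction` (`"both"`, `"left"`, `"right"`). Priority is
#'   the attribute order `dosage > frequency > duration > route >
#'   condition`, then list order within an attribute.
#' @return A `rule_set` data frame with `priority` filled in.
#' @export
rule_set <- function(rules) {
  stopifnot(all(c("attribute", "pattern") %in% names(rules)))
  bad <- setdiff(rules$attribute, attribute_order)
  if (length(bad)) stop("not an attribute category: ", paste(bad, collapse = ", "))
  for (p in rules$pattern) {
    ok <- tryCatch({ suppressWarnings(regexpr(p, "", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("pattern does not compile: ", p)
  }
  if (is.null(rules$window)) rules$window <- NA_integer_
  if (is.null(rules$direction)) rules$direction <- "both"
  rules$priority <- match(rules$attribute, attribute_order) * 1000L +
    stats::ave(seq_len(nrow(rules)), rules$attribute, FUN = seq_along)
  class(rules) <- c("rule_set", "data.frame")
  rules
}

#' Default French attribute rule set
#'
#' Patterns are matched case-folded against normalized text (accents
#' stripped, apostrophes replaced by spaces — hence `"jusqu a"`). The
#' inventory covers the common prescription phrasings: numeric doses with
#' units or galenic forms, `"X fois par jour"`-style frequencies, day and
#' week durations, administration routes, and `"si ..."` / `"en cas de
#' ..."` intake conditions.
#'
#' @return A `rule_set`.
#' @export
default_ruleset <- function() {
  rule_set(data.frame(
    attribute = c(
      rep("dosage", 3),
      rep("frequency", 5),
      rep("duration", 3),
      rep("route", 3),
      rep("condition", 2)
    ),
    pattern = c(
      # dosage
      "(?<![0-9,])[0-9]+(,[0-9]+)? ?(mg|g|ml|ui|mcg)\\b",
      "(?<![0-9,])[0-9]+ (comprimes?|gelules?|gouttes?|sachets?|ampoules?|cp)\\b",
      "\\b(un|une|deux|trois) (comprimes?|gelules?|sachets?)\\b",
      # frequency
      "(?<![0-9,])[0-9]+ fois par (jour|semaine|mois)\\b",
      "\\btoutes les [0-9]+ heures\\b",
      "\\bmatin(,? midi)? et soir\\b",
      "\\bchaque (matin|soir|jour)\\b",
      "\\bau coucher\\b",
      # duration
      "\\bpendant [0-9]+ (jours?|semaines?|mois)\\b",
      "\\bpour une duree de [0-9]+ (jours?|semaines?|mois)\\b",
      "\\bjusqu a nouvel ordre\\b",
      # route
      "\\b(par )?voie (orale|intraveineuse|intramusculaire|sous cutanee|cutanee|rectale|inhalee)\\b",
      "\\bper os\\b",
      "\\ben (intraveineux|intramusculaire|sous cutane|iv|im)\\b",
      # condition
      "\\bsi (douleurs?|fievre|besoin|infection|nausees|insomnie|crises?)\\b",
      "\\ben cas de (douleurs?|fievre|nausees|crises?|vomissements)\\b"
    ),
    stringsAsFactors = FALSE
  ))
}

#' Read / write a rule set as YAML
#'
#' One record per rule with fields `attribute`, `pattern`, and optional
#' `window`, `direction`.
#'
#' @param path YAML file path.
#' @param rules A `rule_set`.
#' @return [read_ruleset()] returns a `rule_set`; [write_ruleset()] the
#'   path, invisibly.
#' @export
read_ruleset <- function(path) {
  recs <- yaml::read_yaml(path)
  rule_set(data.frame(
    attribute = vapply(recs, `[[`, "", "attribute"),
    pattern = vapply(recs, `[[`, "", "pattern"),
    window = vapply(recs, function(r) {
      if (is.null(r$window)) NA_integer_ else as.integer(r$window)
    }, integer(1)),
    direction = vapply(recs, function(r) {
      if (is.null(r$direction)) "both" else r$direction
    }, character(1)),
    stringsAsFactors = FALSE
  ))
}

#' @rdname read_ruleset
#' @export
write_ruleset <- function(rules, path) {
  recs <- lapply(seq_len(nrow(rules)), function(i) {
    r <- list(attribute = rules$attribute[i], pattern = rules$pattern[i])
    if (!is.na(rules$window[i])) r$window <- rules$window[i]
    if (!identical(rules$direction[i], "both")) r$direction <- rules$direction[i]
    r
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Find attribute mentions around one anchor
#'
#' Applies every rule within its token window around the anchor (same
#' sentence, both directions by default) and returns all raw candidate
#' spans, annotated with rule priority and token distance to the anchor.
#' Overlap resolution happens in [annotate_document()].
#'
#' @param text Normalized document text.
#' @param tokens Token data frame of the sentence containing the anchor.
#' @param anchor One-row span data frame (a drug mention).
#' @param ruleset A `rule_set`.
#' @param window Default token window for rules without their own.
#' @return Span data frame with extra columns `priority` and `dist`.
#' @export
find_attributes <- function(text, tokens, anchor, ruleset = default_ruleset(),
                            window = 10L) {
  out <- empty_spans()
  out$priority <- integer()
  out$dist <- integer()
  n <- nrow(tokens)
  if (n == 0L) return(out)
  a_idx <- which(tokens$start < anchor$end & tokens$end > anchor$start)
  if (length(a_idx) == 0L) return(out)
  a_first <- min(a_idx); a_last <- max(a_idx)
  for (r in seq_len(nrow(ruleset))) {
    w <- ruleset$window[r]
    if (is.na(w)) w <- window
    dirn <- ruleset$direction[r]
    lo <- if (dirn == "right") a_first else max(1L, a_first - w)
    hi <- if (dirn == "left") a_last else min(n, a_last + w)
    region_start <- tokens$start[lo]
    region <- tolower(substr0(text, region_start, tokens$end[hi]))
    m <- gregexpr(ruleset$pattern[r], region, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- region_start + as.integer(m) - 1L
    ends <- starts + attr(m, "match.length")
    for (j in seq_along(starts)) {
      if (starts[j] < anchor$end && ends[j] > anchor$start) next  # keep anchor
      t_idx <- which(tokens$start < ends[j] & tokens$end > starts[j])
      if (length(t_idx) == 0L) next
      dist <- if (max(t_idx) < a_first) a_first - max(t_idx)
              else if (min(t_idx) > a_last) min(t_idx) - a_last else 0L
      if (dist > w) next
      row <- entity_spans(ruleset$attribute[r], starts[j], ends[j],
                          source = "rule",
                          text = substr0(text, starts[j], ends[j]))
      row$priority <- ruleset$priority[r]
      row$dist <- dist
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

# priority (asc), then longest, then earliest; greedy non-overlapping
resolve_rule_spans <- function(cands, blocked = empty_spans()) {
  if (nrow(cands) == 0L) return(cands[, names(empty_spans())])
  ord <- order(cands$priority, -(cands$end - cands$start), cands$start)
  iv <- cbind(blocked$start, blocked$end)
  keep <- integer()
  for (i in ord) {
    s <- cands$start[i]; e <- cands$end[i]
    if (nrow(iv) == 0L || all(e <= iv[, 1] | s >= iv[, 2])) {
      keep <- c(keep, i)
      iv <- rbind(iv, c(s, e))
    }
  }
  out <- cands[sort(keep), names(empty_spans()), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rule-based annotation of a whole document
#'
#' For every sentence: exact dictionary matching yields the anchors, then
#' each anchor's neighbourhood is searched with the attribute rules.
#' Candidate attribute spans found from several anchors are deduplicated
#' (kept once, attributed to the nearest anchor) and overlaps are resolved
#' by rule priority, then match length. All spans are stored
#' document-absolute with `source = "rule"`; output is deterministic.
#'
#' @param doc A `med_document`.
#' @param lexicon A `drug_lexicon`.
#' @param ruleset A `rule_set`.
#' @param window Default token window around the anchor.
#' @return The document with its `rule` span layer replaced.
#' @export
annotate_document <- function(doc, lexicon, ruleset = default_ruleset(),
                              window = 10L) {
  all_spans <- empty_spans()
  for (k in seq_len(nrow(doc$sentences))) {
    toks <- doc$tokens[doc$tokens$sentence == k, , drop = FALSE]
    anchors <- match_exact(toks, lexicon)
    if (nrow(anchors) == 0L) next
    cands <- empty_spans(); cands$priority <- integer(); cands$dist <- integer()
    for (a in seq_len(nrow(anchors))) {
      cands <- rbind(cands, find_attributes(doc$text, toks,
                                            anchors[a, , drop = FALSE],
                                            ruleset, window))
    }
    if (nrow(cands)) {
      # same span reachable from several anchors: keep the nearest
      key <- paste(cands$label, cands$start, cands$end)
      cands <- cands[order(key, cands$dist), , drop = FALSE]
      cands <- cands[!duplicated(paste(cands$label, cands$start, cands$end)), ,
                     drop = FALSE]
    }
    attrs <- resolve_rule_spans(cands, blocked = anchors)
    all_spans <- rbind(all_spans, anchors, attrs)
  }
  all_spans <- all_spans[order(all_spans$start, all_spans$end), , drop = FALSE]
  rownames(all_spans) <- NULL
  doc$spans <- rbind(doc$spans[doc$spans$source != "rule", , drop = FALSE],
                     all_spans)
  rownames(doc$spans) <- NULL
  doc
}

#' Rule-layer IOB tags for a document
#'
#' The rule annotation converted to IOB: used both as the pre-annotation
#' output and as the tagger's extra input features.
#'
#' @param doc A `med_document` annotated by [annotate_document()].
#' @return List of tag vectors, one per sentence.
#' @export
rule_iob <- function(doc) {
  doc_iob(doc, "rule", warn = FALSE)
}
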