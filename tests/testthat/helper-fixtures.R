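# Shared fixtures and pipeline helpers, all built in code.

toy_lexicon <- function() {
  build_lexicon(data.frame(
    name = c("doliprane", "paracetamol", "paracetamol codeine", "kardegic",
             "acide acetylsalicylique", "antibiotiques"),
    atc = c("N02BE01", "N02BE01", "N02AJ06", "B01AC06", "B01AC06", "J01"),
    type = c(rep("medication_name", 5), "medication_class"),
    stringsAsFactors = FALSE))
}

# token-level micro metrics and SER of the rule layer over a corpus
rule_layer_eval <- function(corpus, window = 10L) {
  gold <- list(); pred <- list()
  for (doc in corpus$documents) {
    doc <- annotate_document(doc, corpus$lexicon, window = window)
    gold <- c(gold, doc_iob(doc, "gold", warn = FALSE))
    pred <- c(pred, rule_iob(doc))
  }
  list(metrics = micro_prf(token_confusion_all(gold, pred)),
       ser = ser_report(gold, pred), gold = gold, pred = pred)
}

# sentences of token texts for embedding training
corpus_sentences <- function(docs) {
  out <- list()
  for (doc in docs) {
    for (k in seq_len(nrow(doc$sentences))) {
      out[[length(out) + 1L]] <- doc$tokens$text[doc$tokens$sentence == k]
    }
  }
  out
}
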