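# Synthetic French prescription corpus with exact gold annotations.
#
# Sentences follow a slot grammar "<prefix> <drug> <attributes...>" with
# surface inventories chosen so that, at zero noise, every drug mention is
# lexicon-covered and every attribute phrase matches a default rule
# pattern. Noise kinds each target one failure mode of the rule layer:
# alias substitution (drug absent from the lexicon), paraphrase (attribute
# wording outside the rule inventory), character typos. Distractor
# sentences carry no entities and exercise the O class. Generated text is
# already in normalized form (ASCII, no apostrophes), so preprocessing is
# offset-stable on it.

#' Default surface inventories for the corpus generator
#'
#' @return List with the drug table (`drugs`), unseen drug aliases
#'   (`aliases`), per-attribute clean and paraphrase phrase inventories,
#'   sentence prefixes and entity-free distractor sentences.
#' @export
default_inventories <- function() {
  drugs <- data.frame(
    name = c("doliprane", "paracetamol", "paracetamol codeine", "efferalgan",
             "dafalgan", "aspirine", "kardegic", "acide acetylsalicylique",
             "augmentin", "amoxicilline", "levothyrox", "ibuprofene",
             "tramadol", "morphine", "furosemide", "ramipril", "amlodipine",
             "atorvastatine", "simvastatine", "metformine", "insuline",
             "prednisone", "esomeprazole", "omeprazole", "ventoline",
             "salbutamol", "spasfon", "lovenox", "enoxaparine", "bisoprolol",
             "antibiotiques", "antalgiques", "anticoagulants", "betabloquants",
             "statines", "corticoides", "diuretiques", "antihypertenseurs"),
    atc = c("N02BE01", "N02BE01", "N02AJ06", "N02BE01",
            "N02BE01", "N02BE01", "B01AC06", "B01AC06",
            "J01CR02", "J01CA04", "H03AA01", "M01AE01",
            "N02AX02", "N02AA01", "C03CA01", "C09AA05", "C08CA01",
            "C10AA05", "C10AA01", "A10BA02", "A10AB01",
            "H02AB07", "A02BC05", "A02BC01", "R03AC02",
            "R03AC02", "A03AX12", "B01AB05", "B01AB05", "C07AB07",
            "J01", "N02", "B01", "C07",
            "C10", "H02", "C03", "C09"),
    type = c(rep("medication_name", 30), rep("medication_class", 8)),
    stringsAsFactors = FALSE
  )
  list(
    drugs = drugs,
    aliases = c("algodol", "dolfen", "paracetamed", "cardiprin", "febrilix",
                "gastrozol", "tensiomed", "lipidex", "glucofor", "dormicalm",
                "broncholib", "coagulix"),
    dosage = c("5 mg", "10 mg", "20 mg", "50 mg", "100 mg", "200 mg",
               "250 mg", "500 mg", "1000 mg", "2,5 mg", "7,5 mg", "1 g",
               "2 g", "5 ml", "10 ml", "1 comprime", "2 comprimes",
               "3 comprimes", "1 gelule", "2 gelules", "10 gouttes",
               "20 gouttes", "1 sachet", "2 sachets", "2 ampoules"),
    frequency = c("1 fois par jour", "2 fois par jour", "3 fois par jour",
                  "4 fois par jour", "1 fois par semaine",
                  "toutes les 4 heures", "toutes les 6 heures",
                  "toutes les 8 heures", "toutes les 12 heures",
                  "matin et soir", "matin midi et soir", "chaque matin",
                  "chaque soir", "chaque jour", "au coucher"),
    duration = c("pendant 3 jours", "pendant 5 jours", "pendant 7 jours",
                 "pendant 10 jours", "pendant 15 jours", "pendant 2 semaines",
                 "pendant 3 semaines", "pendant 1 mois", "pendant 6 mois",
                 "pour une duree de 7 jours", "pour une duree de 10 jours",
                 "jusqu a nouvel ordre"),
    route = c("par voie orale", "voie orale", "voie intraveineuse",
              "voie intramusculaire", "voie sous cutanee", "per os",
              "en intraveineux", "en sous cutane", "en iv"),
    condition = c("si douleur", "si douleurs", "si fievre", "si besoin",
                  "si infection", "si nausees", "si insomnie",
                  "en cas de douleur", "en cas de fievre", "en cas de nausees",
                  "en cas de crise", "en cas de vomissements"),
    paraphrase = list(
      dosage = c("un demi cachet", "une cuillere a cafe",
                 "deux cuilleres a soupe", "trois cachets", "une faible dose"),
      frequency = c("deux prises quotidiennes", "a chaque repas",
                    "plusieurs fois dans la journee", "une prise le soir"),
      duration = c("quelques jours", "sur une courte periode",
                   "une quinzaine de jours", "pour le mois a venir"),
      route = c("a avaler", "en injection", "par la bouche", "en piqure"),
      condition = c("quand cela est necessaire",
                    "lorsque la douleur revient", "au moment des crises")
    ),
    prefixes = c("prendre", "poursuivre", "debuter", "traitement par",
                 "prescription de", "mise sous", "introduction de"),
    distractors = c("le patient va bien", "examen clinique sans particularite",
                    "retour a domicile prevu", "suivi en consultation prochainement",
                    "etat general conserve", "la plaie est propre et seche",
                    "poursuite de la surveillance habituelle",
                    "bonne tolerance du traitement en cours")
  )
}

#' Generator configuration
#'
#' Defaults are the package's standard study conditions: 320 documents of
#' 3-6 sentences, alias and paraphrase noise at 30%, light typo noise, a
#' quarter of sentences entity-free. Attribute presence probabilities
#' emulate a prescription corpus profile dominated by medication names,
#' dosages and frequencies, with class mentions moderate and condition,
#' duration and route rare.
#'
#' @param n_documents Number of documents.
#' @param sentences_per_document Integer range `c(min, max)`.
#' @param alias_rate Probability that a drug-name mention is replaced by an
#'   out-of-lexicon alias (gold label unchanged).
#' @param paraphrase_rate Probability, per attribute occurrence, of a
#'   phrasing outside the rule inventory.
#' @param typo_rate Probability, per entity, of one character substitution.
#' @param distractor_rate Probability that a sentence carries no entity.
#' @param class_rate Probability that the anchor is a class mention rather
#'   than a drug name.
#' @param attr_probs Named presence probabilities for the five attributes.
#' @param seed Integer seed fixing all randomness.
#' @param inventories Surface inventories, see [default_inventories()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_documents = 320L,
                             sentences_per_document = c(3L, 6L),
                             alias_rate = 0.3, paraphrase_rate = 0.3,
                             typo_rate = 0.02, distractor_rate = 0.25,
                             class_rate = 0.18,
                             attr_probs = c(dosage = 0.75, frequency = 0.7,
                                            duration = 0.12, route = 0.08,
                                            condition = 0.16),
                             seed = 42L,
                             inventories = default_inventories()) {
  rates <- c(alias_rate, paraphrase_rate, typo_rate, distractor_rate,
             class_rate, attr_probs)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(n_documents >= 1L, length(sentences_per_document) == 2L,
            sentences_per_document[1] >= 1L,
            sentences_per_document[2] >= sentences_per_document[1],
            setequal(names(attr_probs), attribute_order))
  for (nm in c("drugs", "aliases", "dosage", "frequency", "duration",
               "route", "condition", "prefixes", "distractors")) {
    if (NROW(inventories[[nm]]) == 0L) stop("empty inventory: ", nm)
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 alias_rate = alias_rate, paraphrase_rate = paraphrase_rate,
                 typo_rate = typo_rate, distractor_rate = distractor_rate,
                 class_rate = class_rate, attr_probs = attr_probs,
                 seed = as.integer(seed), inventories = inventories),
            class = "generator_config")
}

n_tokens_of <- function(surface) nrow(tokenize(surface))

apply_typo <- function(surface) {
  chars <- strsplit(surface, "")[[1]]
  pos <- which(chars %in% letters)
  if (length(pos) == 0L) return(surface)
  i <- pos[sample.int(length(pos), 1L)]
  repl <- sample(setdiff(letters, chars[i]), 1L)
  chars[i] <- repl
  paste(chars, collapse = "")
}

# one entity sentence; returns list(text, spans relative to sentence start)
build_entity_sentence <- function(cfg) {
  inv <- cfg$inventories
  names_tab <- inv$drugs[inv$drugs$type == "medication_name", , drop = FALSE]
  class_tab <- inv$drugs[inv$drugs$type == "medication_class", , drop = FALSE]
  use_class <- stats::runif(1) < cfg$class_rate
  if (use_class) {
    drug <- class_tab$name[sample.int(nrow(class_tab), 1L)]
    drug_label <- "medication_class"
  } else {
    drug_label <- "medication_name"
    if (stats::runif(1) < cfg$alias_rate) {
      drug <- inv$aliases[sample.int(length(inv$aliases), 1L)]
    } else {
      drug <- names_tab$name[sample.int(nrow(names_tab), 1L)]
    }
  }
  present <- attribute_order[stats::runif(length(attribute_order)) <
                               cfg$attr_probs[attribute_order]]
  pieces <- list(list(text = inv$prefixes[sample.int(length(inv$prefixes), 1L)],
                      label = NA_character_))
  surfaces <- list()
  for (att in attribute_order) {
    if (!att %in% present) next
    para <- stats::runif(1) < cfg$paraphrase_rate
    pool <- if (para) inv$paraphrase[[att]] else inv[[att]]
    surfaces[[att]] <- pool[sample.int(length(pool), 1L)]
  }
  # attributes sit inside the default rule window: drop rare attributes
  # (reverse priority) until the attribute block is at most 10 tokens
  while (length(surfaces) &&
         sum(vapply(surfaces, n_tokens_of, integer(1))) > 10L) {
    drop <- rev(intersect(attribute_order, names(surfaces)))[1]
    surfaces[[drop]] <- NULL
  }
  entity_pieces <- c(list(list(text = drug, label = drug_label)),
                     lapply(intersect(attribute_order, names(surfaces)),
                            function(a) list(text = surfaces[[a]], label = a)))
  for (p in entity_pieces) {
    if (stats::runif(1) < cfg$typo_rate) p$text <- apply_typo(p$text)
    pieces[[length(pieces) + 1L]] <- p
  }
  texts <- vapply(pieces, `[[`, "", "text")
  starts <- cumsum(c(0L, nchar(texts) + 1L))[seq_along(texts)]
  lab <- vapply(pieces, `[[`, "", "label")
  keep <- !is.na(lab)
  list(text = paste(texts, collapse = " "),
       spans = data.frame(label = lab[keep], start = starts[keep],
                          end = starts[keep] + nchar(texts[keep]),
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic prescription corpus
#'
#' @param config A [generator_config()].
#' @return An object of class `med_corpus`: list with `documents` (list of
#'   `med_document` objects carrying gold spans), `lexicon` (the toy
#'   [build_lexicon()] dictionary covering exactly the non-noise drug
#'   surfaces) and `config`. Deterministic for a fixed seed.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  inv <- config$inventories
  lexicon <- build_lexicon(inv$drugs)
  docs <- with_seed(config$seed, {
    lapply(seq_len(config$n_documents), function(d) {
      rng <- config$sentences_per_document
      n_sent <- sample(seq(rng[1], rng[2]), 1L)
      sent_texts <- character(n_sent)
      spans <- empty_spans()
      cursor <- 0L
      for (k in seq_len(n_sent)) {
        if (stats::runif(1) < config$distractor_rate) {
          st <- inv$distractors[sample.int(length(inv$distractors), 1L)]
          sent <- list(text = st,
                       spans = data.frame(label = character(),
                                          start = integer(), end = integer(),
                                          stringsAsFactors = FALSE))
        } else {
          sent <- build_entity_sentence(config)
        }
        if (nrow(sent$spans)) {
          spans <- rbind(spans, entity_spans(
            sent$spans$label, cursor + sent$spans$start,
            cursor + sent$spans$end, source = "gold"))
        }
        sent_texts[k] <- paste0(sent$text, ".")
        cursor <- cursor + nchar(sent_texts[k]) + 1L  # joining space
      }
      text <- paste(sent_texts, collapse = " ")
      doc <- preprocess_document(text, doc_id = sprintf("doc_%03d", d))
      stopifnot(doc$text == text)  # generated text is normalization-stable
      spans$text <- if (nrow(spans)) substr0(text, spans$start, spans$end)
                    else character()
      doc$spans <- spans
      doc
    })
  })
  structure(list(documents = docs, lexicon = lexicon, config = config),
            class = "med_corpus")
}

#' @export
print.med_corpus <- function(x, ...) {
  n_spans <- sum(vapply(x$documents, function(d) nrow(d$spans), integer(1)))
  cat(sprintf("<med_corpus: %d documents, %d gold spans, seed %d>\n",
              length(x$documents), n_spans, x$config$seed))
  invisible(x)
}

#' Split a corpus into train/development/test partitions
#'
#' Document-level, disjoint, exhaustive and seed-deterministic. The
#' default fractions reproduce a 216/24/80 split of 320 documents.
#'
#' @param corpus A `med_corpus` (or plain list of documents).
#' @param fractions Numeric vector of three fractions summing to 1.
#' @param seed Integer seed for the shuffle.
#' @return Named list `train`, `dev`, `test` of document lists.
#' @export
split_corpus <- function(corpus, fractions = c(train = 0.675, dev = 0.075,
                                               test = 0.25),
                         seed = 1L) {
  docs <- if (inherits(corpus, "med_corpus")) corpus$documents else corpus
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  n <- length(docs)
  if (n < 3L) stop("fewer documents than splits")
  sizes <- diff(c(0L, round(cumsum(fractions) * n)))
  perm <- with_seed(seed, sample.int(n))
  idx <- split(perm, rep(1:3, times = sizes))
  list(train = docs[sort(idx[[1]])], dev = docs[sort(idx[[2]])],
       test = docs[sort(idx[[3]])])
}

#' Write a corpus to disk
#'
#' One `.txt`/`.ann` standoff pair per document plus `lexicon.csv`.
#'
#' @param corpus A `med_corpus`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in corpus$documents) {
    write_standoff(doc, file.path(dir, doc$doc_id), source = "gold")
  }
  write_lexicon(corpus$lexicon, file.path(dir, "lexicon.csv"))
  invisible(dir)
}
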