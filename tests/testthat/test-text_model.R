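test_that("standoff reader parses T lines and validates them", {
  txt <- withr::local_tempfile(fileext = ".txt")
  ann <- withr::local_tempfile(fileext = ".ann")
  writeLines("doliprane 1 g", txt)
  writeLines("T1\tmedication_name 0 9\tdoliprane", ann)
  doc <- read_standoff(txt, ann)
  expect_equal(doc$spans$label, "medication_name")
  expect_equal(doc$spans$start, 0L)
  expect_equal(doc$spans$end, 9L)
  expect_equal(doc$spans$source, "gold")

  writeLines(character(), ann)
  expect_equal(nrow(read_standoff(txt, ann)$spans), 0L)

  writeLines("T1\tmedication_name 0 9\tkardegic", ann)
  expect_error(read_standoff(txt, ann), "surface")
  writeLines("T1\tmedication_name 0 99\tdoliprane", ann)
  expect_error(read_standoff(txt, ann), "malformed")
  writeLines("T1\tdrug 0 9\tdoliprane", ann)
  expect_error(read_standoff(txt, ann), "unknown label")
})

test_that("spans_to_iob follows the IOB convention and any-overlap rule", {
  doc <- preprocess_document("pendant 3 semaines")
  toks <- doc$tokens
  tags <- spans_to_iob(toks, entity_spans("duration", 0L, 18L))
  expect_equal(as.vector(tags), c("B-duration", "I-duration", "I-duration"))

  # adjacent spans of different classes on consecutive tokens
  doc2 <- preprocess_document("500mg matin")
  tags2 <- spans_to_iob(doc2$tokens,
                        entity_spans(c("dosage", "frequency"),
                                     c(0L, 6L), c(5L, 11L)))
  expect_equal(as.vector(tags2), c("B-dosage", "B-frequency"))

  # span covering half of one token still labels it (any overlap)
  tags3 <- spans_to_iob(doc2$tokens, entity_spans("dosage", 0L, 3L))
  expect_equal(as.vector(tags3), c("B-dosage", "O"))

  # span overlapping no token is dropped with a warning
  doc3 <- preprocess_document("a b")
  expect_warning(
    tags4 <- spans_to_iob(doc3$tokens[1:2, ],
                          entity_spans("route", 200L, 210L)),
    "dropped")
  expect_equal(attr(tags4, "dropped"), 1L)
})

test_that("spans_to_iob matches the character-overlap oracle on random docs", {
  set.seed(21)
  for (i in 1:60) {
    words <- replicate(sample(3:10, 1),
                       paste(sample(letters, sample(2:6, 1), TRUE), collapse = ""))
    doc <- preprocess_document(paste(words, collapse = " "))
    toks <- doc$tokens
    n <- nchar(doc$text)
    k <- sample(0:3, 1)
    if (k == 0) next
    starts <- sort(sample(0:(n - 1), k))
    ends <- pmin(n, starts + sample(1:6, k, TRUE))
    ok <- ends > starts
    spans <- entity_spans(sample(med_labels(), sum(ok), TRUE),
                          starts[ok], ends[ok])
    spans <- resolve_spans(spans)
    got <- suppressWarnings(spans_to_iob(toks, spans))
    expect_equal(as.vector(got), oracle_iob(toks, spans))
  }
})

test_that("iob_to_spans decodes runs, leniently by default", {
  doc <- preprocess_document("500 mg demain")
  toks <- doc$tokens
  sp <- iob_to_spans(toks, c("B-dosage", "I-dosage", "O"))
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$start, toks$start[1])
  expect_equal(sp$end, toks$end[2])

  one <- preprocess_document("os")$tokens
  expect_equal(iob_to_spans(one, "I-route")$label, "route")      # lenient
  expect_equal(nrow(iob_to_spans(one, "I-route", strict = TRUE)), 0L)
})

test_that("spans_to_iob then iob_to_spans is the identity for aligned spans", {
  set.seed(31)
  for (i in 1:40) {
    words <- replicate(sample(4:12, 1),
                       paste(sample(letters, sample(2:5, 1), TRUE), collapse = ""))
    doc <- preprocess_document(paste(words, collapse = " "))
    toks <- doc$tokens
    # token-aligned non-adjacent same-class spans
    n <- nrow(toks)
    picks <- sort(sample(seq_len(n), sample(1:min(3, n), 1)))
    spans <- empty <- entity_spans()
    last_end <- -1L
    for (p in picks) {
      len <- sample(1:2, 1)
      last <- min(n, p + len - 1L)
      if (toks$start[p] <= last_end) next
      spans <- rbind(spans, entity_spans(sample(med_labels(), 1),
                                         toks$start[p], toks$end[last]))
      last_end <- toks$end[last]
    }
    spans <- resolve_spans(spans)
    # adjacent same-class spans would merge under IOB without B boundaries;
    # resolve_spans already guarantees disjoint, order by start
    spans <- spans[order(spans$start), ]
    tags <- spans_to_iob(toks, spans)
    back <- iob_to_spans(toks, tags, source = "gold")
    expect_equal(back$label, spans$label)
    expect_equal(back$start, spans$start)
    expect_equal(back$end, spans$end)
  }
})

test_that("CoNLL writer emits one line per token and round-trips", {
  doc <- preprocess_document("Prendre doliprane 1 g. Arreter kardegic.")
  doc$spans <- entity_spans(c("medication_name", "dosage", "medication_name"),
                            c(8L, 18L, 31L), c(17L, 21L, 39L), source = "gold")
  doc <- annotate_document(doc, toy_lexicon())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_conll(doc, path)
  lines <- readLines(path)
  n_tok <- nrow(doc$tokens)
  expect_equal(length(lines), n_tok + 2L)  # one blank per sentence
  expect_equal(read_conll(path), conll_frame(doc))

  empty <- preprocess_document("")
  p2 <- withr::local_tempfile()
  write_conll(empty, p2)
  expect_equal(length(readLines(p2)), 0L)
  expect_error(write_conll(doc, path, rule_tags = list(c("O"), c("O"))),
               "alignment")
})

test_that("standoff writer round-trips through the reader", {
  doc <- preprocess_document("Prendre doliprane 500 mg si douleur.")
  doc$spans <- entity_spans(c("medication_name", "dosage", "condition"),
                            c(8L, 18L, 25L), c(17L, 24L, 35L), source = "gold")
  prefix <- file.path(withr::local_tempdir(), "doc1")
  write_standoff(doc, prefix, source = "gold")
  back <- read_standoff(paste0(prefix, ".txt"), paste0(prefix, ".ann"))
  expect_equal(back$spans$label, doc$spans$label)
  expect_equal(back$spans$start, doc$spans$start)
  expect_equal(back$spans$end, doc$spans$end)
})
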