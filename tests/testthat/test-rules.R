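test_that("attribute extraction recovers the expected spans around an anchor", {
  lex <- toy_lexicon()
  doc <- preprocess_document("doliprane 1 g 3 fois par jour si douleur")
  doc <- annotate_document(doc, lex)
  sp <- doc$spans
  get1 <- function(lab) sp$text[sp$label == lab]
  expect_equal(get1("medication_name"), "doliprane")
  expect_equal(get1("dosage"), "1 g")
  expect_equal(get1("frequency"), "3 fois par jour")
  expect_equal(get1("condition"), "si douleur")

  doc2 <- preprocess_document("kardegic par voie intraveineuse")
  doc2 <- annotate_document(doc2, lex)
  expect_equal(doc2$spans$text[doc2$spans$label == "route"],
               "par voie intraveineuse")
})

test_that("extraction is anchor-gated", {
  lex <- toy_lexicon()
  # attribute-like text but no drug mention -> nothing at all
  doc <- preprocess_document("prendre 1 g 3 fois par jour si douleur")
  doc <- annotate_document(doc, lex)
  expect_equal(nrow(doc$spans), 0L)

  # removing all lexicon entries yields zero spans of any category
  empty_lex <- build_lexicon(data.frame(name = "zzzz", atc = "A01AA01",
                                        type = "medication_name",
                                        stringsAsFactors = FALSE))
  doc2 <- preprocess_document("doliprane 1 g 3 fois par jour")
  doc2 <- annotate_document(doc2, empty_lex)
  expect_equal(nrow(doc2$spans), 0L)
})

test_that("window limits the attribute search around the anchor", {
  lex <- toy_lexicon()
  filler <- paste(rep("mot", 12), collapse = " ")
  doc <- preprocess_document(paste("doliprane", filler, "si douleur"))
  near <- annotate_document(doc, lex, window = 20L)
  expect_true("condition" %in% near$spans$label)
  far <- annotate_document(doc, lex, window = 5L)
  expect_false("condition" %in% far$spans$label)
})

test_that("document annotation is deterministic and handles degenerate input", {
  lex <- toy_lexicon()
  text <- paste("Prendre doliprane 500 mg matin et soir si douleur.",
                "Kardegic 100 mg pendant 7 jours par voie orale.")
  doc <- preprocess_document(text)
  d1 <- annotate_document(doc, lex)
  d2 <- annotate_document(doc, lex)
  expect_identical(d1$spans, d2$spans)
  # both anchors annotated, attributes attached within their sentences
  expect_equal(sum(d1$spans$label == "medication_name"), 2L)
  expect_true(all(c("dosage", "frequency", "duration", "route", "condition")
                  %in% d1$spans$label))
  out1 <- withr::local_tempfile(); out2 <- withr::local_tempfile()
  write_standoff(d1, out1); write_standoff(d2, out2)
  expect_identical(readLines(paste0(out1, ".ann")),
                   readLines(paste0(out2, ".ann")))

  punct <- annotate_document(preprocess_document("!!! ... ///"), lex)
  expect_equal(nrow(punct$spans), 0L)
  empty <- annotate_document(preprocess_document(""), lex)
  expect_equal(nrow(empty$spans), 0L)
})

test_that("rule_iob delegates to the IOB converter", {
  lex <- toy_lexicon()
  doc <- annotate_document(
    preprocess_document("doliprane 1 g. rien ici. kardegic si douleur."), lex)
  tags <- rule_iob(doc)
  expect_length(tags, 3L)
  expect_equal(as.vector(tags[[1]]),
               c("B-medication_name", "B-dosage", "I-dosage", "O"))
  expect_true(all(tags[[2]] == "O"))
  expect_equal(sum(tags[[3]] != "O"), 3L)  # kardegic + si douleur
  # every emitted sequence parses under the tag grammar
  for (t in tags) expect_true(validate_iob(t))
})

test_that("rule sets validate, prioritize, and round-trip through YAML", {
  expect_error(rule_set(data.frame(attribute = "dosage", pattern = "([a-",
                                   stringsAsFactors = FALSE)),
               "compile")
  expect_error(rule_set(data.frame(attribute = "medication_name",
                                   pattern = "x", stringsAsFactors = FALSE)),
               "attribute")
  rs <- default_ruleset()
  expect_true(all(table(rs$attribute) >= 2))
  expect_true(max(rs$priority[rs$attribute == "dosage"]) <
                min(rs$priority[rs$attribute == "condition"]))
  path <- withr::local_tempfile(fileext = ".yml")
  write_ruleset(rs, path)
  back <- read_ruleset(path)
  expect_equal(back$pattern, rs$pattern)
  expect_equal(back$attribute, rs$attribute)

  # a token claimed by two attributes goes to the higher-priority rule
  lex <- toy_lexicon()
  clash <- rule_set(data.frame(
    attribute = c("dosage", "frequency"),
    pattern = c("500 mg", "mg matin"), stringsAsFactors = FALSE))
  doc <- annotate_document(preprocess_document("doliprane 500 mg matin"),
                           lex, ruleset = clash)
  expect_equal(doc$spans$label[doc$spans$text == "500 mg"], "dosage")
  expect_false("frequency" %in% doc$spans$label)
})
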