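Package: medextract
Title: Hybrid Rule-Based and Recurrent Neural Extraction of Medication
    Information from French Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts drug mentions and their attributes (dosage, frequency,
    duration, route, condition of intake) from French clinical free text.
    Combines a high-precision rule layer (exact dictionary matching of drug
    names anchored to handcrafted regular-expression attribute rules) with a
    bidirectional LSTM sequence tagger (optional linear-chain CRF output)
    that consumes frozen word embeddings concatenated with the rule layer's
    IOB tags as extra features. Includes the full preprocessing pipeline
    (accent and apostrophe normalization, sentence splitting, tokenization),
    BRAT standoff and CoNLL-style IO, token-level micro-averaged metrics,
    slot error rate with insertion/deletion/type/frontier decomposition, and
    a synthetic French prescription corpus generator with gold annotations
    for end-to-end testing without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
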