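test_that("rule-feature encoding is one-hot in the fixed tag order", {
  m <- encode_rule_features(c("O", "B-dosage", "I-dosage"))
  expect_equal(dim(m), c(3L, 15L))
  expect_equal(rowSums(m), c(1, 1, 1))
  expect_equal(which(m[1, ] == 1), 1L)  # O is index 1
  expect_equal(which(m[2, ] == 1), match("B-dosage", med_tags()))
  expect_false(all(m[2, ] == m[3, ]))
  expect_error(encode_rule_features("B-banana"), "unknown")
})

test_that("input fusion concatenates embedding block first, rules last", {
  sents <- list(c("prendre", "doliprane", "matin"),
                c("kardegic", "le", "soir"))
  prov <- train_static_embedding(sents, dimension = 8, epochs = 1, seed = 1)
  toks <- c("prendre", "doliprane")
  rt <- c("O", "B-medication_name")
  x <- build_inputs(toks, prov, rt)
  expect_equal(dim(x), c(2L, 8L + 15L))
  x0 <- build_inputs(toks, prov)
  expect_equal(dim(x0), c(2L, 8L))
  # zeroing the rule block reproduces the no-rules input
  x_zero <- x; x_zero[, 9:23] <- 0
  expect_equal(x_zero[, 1:8], x0)
  expect_error(build_inputs(toks, prov, c("O")), "misaligned")
})

test_that("static embedding training is deterministic with correct shapes", {
  sents <- lapply(1:20, function(i) c("un", "deux", "trois", "quatre")[
    sample.int(4, 4)])
  p1 <- train_static_embedding(sents, dimension = 12, epochs = 2, seed = 9)
  p2 <- train_static_embedding(sents, dimension = 12, epochs = 2, seed = 9)
  expect_identical(p1$W, p2$W)
  expect_equal(p1$dimension, 12L)
  expect_equal(ncol(embed_tokens(p1, c("un", "inconnu"))), 12L)
  # OOV maps to the dedicated unknown vector
  expect_equal(embed_tokens(p1, "inconnu")[1, ], unname(p1$unk))
  expect_error(train_static_embedding(list(), dimension = 4), "empty corpus")
})

test_that("tokens sharing contexts become closer than a random token", {
  # 'alpha' and 'beta' always appear in identical contexts; 'omega' never does
  set.seed(2)
  sents <- list()
  for (i in 1:120) {
    ctx <- sample(c("gauche", "droite", "centre"), 2)
    sents[[length(sents) + 1L]] <- c(ctx[1], "alpha", ctx[2])
    sents[[length(sents) + 1L]] <- c(ctx[1], "beta", ctx[2])
    sents[[length(sents) + 1L]] <- c("omega", "fond", "omega")
  }
  prov <- train_static_embedding(sents, dimension = 16, epochs = 5, seed = 33)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  E <- embed_tokens(prov, c("alpha", "beta", "omega"))
  expect_gt(cos(E[1, ], E[2, ]), cos(E[1, ], E[3, ]))
})

test_that("subword provider composes vectors for unseen words", {
  sents <- lapply(1:30, function(i) c("doliprane", "dosage", "matin"))
  prov <- train_static_embedding(sents, dimension = 10, epochs = 2,
                                 mode = "subword", seed = 5)
  v <- embed_tokens(prov, "dolipran")  # unseen, shares n-grams
  expect_false(isTRUE(all.equal(v[1, ], unname(prov$unk))))
  # a word with entirely unknown n-grams falls back to the unknown vector
  v2 <- embed_tokens(prov, "zzzzzzzz")
  expect_equal(v2[1, ], unname(prov$unk))
})

test_that("contextual provider gives context-dependent, deterministic vectors", {
  sents <- lapply(1:15, function(i)
    list(c("prendre", "doliprane", "matin"),
         c("arreter", "doliprane", "soir"))[[1 + i %% 2]])
  prov <- train_contextual_embedding(sents, hidden = 8, epochs = 1, seed = 3)
  expect_equal(prov$dimension, 16L)
  a <- embed_tokens(prov, c("prendre", "doliprane", "matin"))
  b <- embed_tokens(prov, c("arreter", "doliprane", "soir"))
  expect_equal(dim(a), c(3L, 16L))
  # same token, different sentence context -> different vector
  expect_false(isTRUE(all.equal(a[2, ], b[2, ])))
  a2 <- embed_tokens(prov, c("prendre", "doliprane", "matin"))
  expect_identical(a, a2)
})

test_that("providers stay frozen through tagger training", {
  sents <- lapply(1:10, function(i) c("prendre", "doliprane", "matin"))
  prov <- train_static_embedding(sents, dimension = 6, epochs = 1, seed = 2)
  before <- serialize(prov, NULL)
  exs <- lapply(1:6, function(i) {
    toks <- c("prendre", "doliprane", "matin")
    list(x = build_inputs(toks, prov),
         tags = c("O", "B-medication_name", "B-frequency"))
  })
  cfg <- tagger_config(max_epochs = 2L, seed = 1L)
  fit <- train_tagger(build_tagger(cfg, 6L), exs, exs)
  expect_identical(serialize(prov, NULL), before)
})
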