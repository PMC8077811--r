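test_that("token confusion follows the per-token definitions", {
  c1 <- token_confusion("B-dosage", "B-dosage")
  expect_equal(c1$tp[c1$label == "dosage"], 1L)
  expect_equal(sum(c1$fp) + sum(c1$fn), 0L)

  c2 <- token_confusion("B-dosage", "B-route")
  expect_equal(c2$fp[c2$label == "route"], 1L)
  expect_equal(c2$fn[c2$label == "dosage"], 1L)
  expect_equal(sum(c2$tp), 0L)

  # prefix mismatch within the same class is still a true positive
  c3 <- token_confusion("B-dosage", "I-dosage")
  expect_equal(c3$tp[c3$label == "dosage"], 1L)

  expect_error(token_confusion(c("O", "O"), "O"), "length")
})

test_that("token confusion matches the exhaustive tally on random pairs", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(1:20, 1)
    gold <- random_iob(n)
    pred <- corrupt_iob(gold, 0.4)
    got <- token_confusion(gold, pred)
    expect_equal(got, oracle_confusion(gold, pred))
    # token identity: TP + FN covers exactly the gold entity tokens
    expect_equal(sum(got$tp) + sum(got$fn), sum(gold != "O"))
  }
})

test_that("micro averaging pools counts and handles degenerate input", {
  counts <- data.frame(label = med_labels(), tp = 0L, fp = 0L, fn = 0L)
  counts$tp[1] <- 9L; counts$fp[1] <- 1L; counts$fn[1] <- 1L
  m <- micro_prf(counts)
  ov <- m[m$label == "overall", ]
  expect_equal(ov$precision, 90)
  expect_equal(ov$recall, 90)
  expect_equal(ov$f, 90)

  # no predictions, nonzero gold
  counts$tp[1] <- 0L; counts$fp[1] <- 0L; counts$fn[1] <- 5L
  m2 <- micro_prf(counts)
  ov2 <- m2[m2$label == "overall", ]
  expect_equal(c(ov2$precision, ov2$recall, ov2$f), c(0, 0, 0))
  expect_true(ov2$flagged)

  # F lies between P and R whenever both are defined
  set.seed(4)
  for (i in 1:30) {
    cc <- data.frame(label = med_labels(),
                     tp = sample(0:20, 7, TRUE), fp = sample(0:10, 7, TRUE),
                     fn = sample(0:10, 7, TRUE))
    mm <- micro_prf(cc)
    ok <- mm$precision + mm$recall > 0
    expect_true(all(mm$f[ok] >= pmin(mm$precision, mm$recall)[ok] - 1e-9))
    expect_true(all(mm$f[ok] <= pmax(mm$precision, mm$recall)[ok] + 1e-9))
  }
})

test_that("identical sequences give a zero slot error rate", {
  tags <- c("B-dosage", "I-dosage", "O", "B-route")
  r <- ser_report(tags, tags)
  expect_equal(r$ser, 0)
  expect_equal(unlist(r$rates), c(deletion = 0, insertion = 0, type = 0,
                                  frontier = 0))
  expect_equal(r$ref_slots, 2L)
})

test_that("SER worked example: miss one, add one, mislabel one, clip one", {
  # 10 reference slots, separated by O tokens
  labs <- rep(c("dosage", "frequency"), 5)
  gold <- unlist(lapply(labs, function(l) c(paste0("B-", l),
                                            paste0("I-", l), "O")))
  pred <- gold
  pred[1:2] <- "O"                       # deletion
  pred[3] <- "B-route"                   # insertion (on an O token)
  pred[4:5] <- c("B-condition", "I-condition")  # type error, same bounds
  pred[8] <- "O"                         # frontier: clipped token
  r <- ser_report(gold, pred)
  expect_equal(r$ref_slots, 10L)
  expect_equal(r$counts$deletion, 1L)
  expect_equal(r$counts$insertion, 1L)
  expect_equal(r$counts$type, 1L)
  expect_equal(r$counts$frontier, 1L)
  expect_equal(r$ser, (1 + 1 + 0.5 + 0.5) / 10)  # 0.30
})

test_that("a slot wrong in both class and boundary counts type + frontier", {
  gold <- c("B-dosage", "I-dosage", "I-dosage", "O")
  pred <- c("O", "B-route", "I-route", "O")
  r <- ser_report(gold, pred)
  expect_equal(r$counts$type, 1L)
  expect_equal(r$counts$frontier, 1L)
  expect_equal(r$ser, 1)  # 0.5 + 0.5 over one reference slot
})

test_that("aggregate SER reproduces printed component arithmetic", {
  expect_equal(ser_from_rates(insertion = 0.03, deletion = 0.23,
                              type = 0.02, frontier = 0.04), 0.29)
  expect_equal(ser_from_rates(0.09, 0.25, 0.07, 0.15), 0.45)
  expect_equal(ser_from_rates(0.07, 0.08, 0.03, 0.09), 0.21)
  expect_equal(ser_from_rates(0.11, 0.26, 0.11, 0.21), 0.53)
})

test_that("slot alignment agrees with brute-force optimal matching", {
  set.seed(23)
  for (i in 1:150) {
    n <- sample(4:24, 1)
    gold <- random_iob(n, density = 0.4)
    pred <- if (i %% 3 == 0) random_iob(n, density = 0.4) else
      corrupt_iob(gold, 0.35)
    got <- medextract:::slot_error_counts(gold, pred)
    want <- oracle_ser_counts(gold, pred)
    expect_equal(got[c("deletion", "insertion", "type", "frontier",
                       "ref_slots")], want)
  }
})

test_that("the SER decomposition identity holds on random pairs", {
  set.seed(29)
  for (i in 1:40) {
    gold <- lapply(1:5, function(k) random_iob(sample(3:15, 1)))
    pred <- lapply(gold, corrupt_iob, p_flip = 0.3)
    r <- ser_report(gold, pred)
    with(r$counts, expect_equal(
      r$ser * r$ref_slots, deletion + insertion + 0.5 * (type + frontier)))
  }
})
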