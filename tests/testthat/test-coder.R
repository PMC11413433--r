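separable_corpus <- function(seed = 1) {
  space <- make_code_space(code_space_config(n_families = 6, n_background = 10,
                                             seed = 2))
  sample_corpus(space, corpus_config(n_train = 500, n_dev = 100, n_test = 150,
                                     trigger_prob = 1, mean_tokens = 15,
                                     noise_vocab = 40, balanced = TRUE,
                                     seed = seed))$corpus
}

test_that("build_vocab is deterministic and honors the frequency floor", {
  cp <- tiny_corpus()
  v1 <- build_vocab(cp, coder_config(min_freq = 1))
  expect_equal(v1[1], "<unk>")
  expect_true(all(c("chest", "pain", "fever", "cough") %in% v1))
  expect_identical(v1, build_vocab(cp, coder_config(min_freq = 1)))
  v2 <- build_vocab(cp, coder_config(min_freq = 2))
  expect_true("fever" %in% v2)     # appears in two training documents
  expect_false("cough" %in% v2)    # singleton maps to unknown
  expect_error(build_vocab(cp[cp$split == "test", ], coder_config()),
               "empty training split")
})

test_that("mean_average_precision matches hand-computed rankings", {
  # single label, positives at ranks 1 and 3 of 4: AP = (1 + 2/3)/2 = 5/6
  scores <- matrix(c(0.9, 0.7, 0.5, 0.3), ncol = 1)
  gold <- matrix(c(TRUE, FALSE, TRUE, FALSE), ncol = 1)
  expect_equal(mean_average_precision(scores, gold), 5 / 6)
  # perfect ranking for all labels
  s2 <- cbind(c(0.9, 0.8, 0.1), c(0.2, 0.95, 0.1))
  g2 <- cbind(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE))
  expect_equal(mean_average_precision(s2, g2), 1)
  expect_error(mean_average_precision(s2, g2 & FALSE), "no label has a positive")
  # random scores: mAP concentrates near label prevalence
  set.seed(8)
  n <- 400
  prev <- 0.3
  reps <- vapply(1:200, function(i) {
    mean_average_precision(matrix(stats::runif(n), ncol = 1),
                           matrix(stats::runif(n) < prev, ncol = 1))
  }, numeric(1))
  expect_lt(abs(mean(reps) - prev), 0.02)
})

test_that("training learns a separable label-conditioned corpus", {
  cp <- separable_corpus(seed = 1)
  co <- train_coder(cp[cp$split == "train", ], cp[cp$split == "dev", ],
                    coder_config(epochs = 20, seed = 11))
  expect_gte(max(co$dev_map), 0.95)
  expect_equal(co$selected_epoch, which.max(co$dev_map))
  # trigger-token documents predict their label on the test split
  te <- cp[cp$split == "test", ]
  pred <- predict(co, te)
  gold <- stats::setNames(te$labels, te$doc_id)
  m <- flat_metrics(gold, pred$labels, co$labels)
  expect_gte(m$micro[["f1"]], 0.8)
})

test_that("training is seed-reproducible and respects the epoch budget", {
  cp <- separable_corpus(seed = 2)
  tr <- cp[cp$split == "train", ][1:120, ]
  dv <- cp[cp$split == "dev", ][1:40, ]
  cfg <- coder_config(epochs = 4, seed = 5)
  a <- train_coder(tr, dv, cfg)
  b <- train_coder(tr, dv, cfg)
  expect_identical(a$dev_map, b$dev_map)
  expect_identical(a$params, b$params)
  one <- train_coder(tr, dv, coder_config(epochs = 1, seed = 5))
  expect_equal(one$selected_epoch, 1)
  expect_length(one$dev_map, 1)
})

test_that("prediction sets are monotone non-increasing in the threshold", {
  cp <- separable_corpus(seed = 3)
  tr <- cp[cp$split == "train", ][1:150, ]
  dv <- cp[cp$split == "dev", ][1:40, ]
  co <- train_coder(tr, dv, coder_config(epochs = 5, seed = 9))
  te <- cp[cp$split == "test", ][1:30, ]
  prev <- NULL
  for (th in c(0.1, 0.3, 0.5, 0.8)) {
    cur <- predict(co, te, threshold = th)$labels
    if (!is.null(prev)) {
      for (id in names(cur)) expect_true(all(cur[[id]] %in% prev[[id]]))
    }
    prev <- cur
  }
  # boundary semantics: threshold 0 predicts everything (score >= 0)
  all0 <- predict(co, te, threshold = 0)$labels
  for (id in names(all0)) expect_setequal(all0[[id]], co$labels)
  # scores never reach 1 exactly, so threshold 1 predicts nothing
  all1 <- predict(co, te, threshold = 1)$labels
  expect_true(all(lengths(all1) == 0))
})

test_that("dev-only labels are excluded from the output space with a warning", {
  tr <- new_corpus(c("a", "b"), c("foo bar", "bar baz"),
                   list("E10.1", "E10.2"), c("train", "train"))
  dv <- new_corpus("c", "foo qux", list(c("E10.1", "Z99.9")), "dev")
  expect_warning(co <- train_coder(tr, dv, coder_config(epochs = 1)),
                 "dev-only")
  expect_setequal(co$labels, c("E10.1", "E10.2"))
})
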