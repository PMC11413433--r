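fam_hier <- function(leaves) code_hierarchy(leaves)

test_that("flat metrics match hand computations", {
  gold <- list(d1 = "A01.1")
  pred <- list(d1 = c("A01.1", "A01.2"))
  m <- flat_metrics(gold, pred, c("A01.1", "A01.2"))
  expect_equal(unname(m$micro), c(0.5, 1, 2 / 3))
  # perfect predictions
  mp <- flat_metrics(gold, gold, "A01.1")
  expect_equal(unname(mp$micro), c(1, 1, 1))
  expect_equal(unname(mp$macro), c(1, 1, 1))
  # macro over per-label F1 {1, 0} averages to 0.5
  g2 <- list(d1 = "A01.1")
  p2 <- list(d1 = c("A01.1", "A01.2"))
  m2 <- flat_metrics(g2, p2, c("A01.1", "A01.2"))
  expect_equal(m2$macro[["f1"]], 0.5)
  expect_error(flat_metrics(gold, list(d2 = "A01.1"), "A01.1"),
               "same documents")
})

test_that("ancestor extension matches its two modes", {
  h <- fam_hier(c("A01.1", "A01.2", "A01.3"))
  counts <- extend_with_ancestors(c("A01.1", "A01.2"), h, "counts")
  expect_equal(counts[["A01.1"]], 1)
  expect_equal(counts[["A01.2"]], 1)
  expect_equal(counts[["A01"]], 2)
  sets <- extend_with_ancestors(c("A01.1", "A01.2"), h, "set")
  expect_equal(sets[["A01"]], 1)
  expect_length(extend_with_ancestors(character(0), h, "set"), 0)
  # extension never removes leaf entries
  expect_true(all(c("A01.1", "A01.2") %in% names(counts)))
  expect_error(extend_with_ancestors("Z99.9", h), "unknown leaf")
})

test_that("hierarchical worked examples match the metric definitions", {
  h <- fam_hier(c("A01.1", "A01.2", "A01.3"))
  gold <- list(d1 = c("A01.1", "A01.2"))
  pred <- list(d1 = c("A01.1", "A01.3"))
  leaf <- hierarchical_metrics(gold, pred, h, "leaf_only")
  expect_equal(leaf$micro[["precision"]], 0.5)
  expect_equal(leaf$micro[["recall"]], 0.5)
  sb <- hierarchical_metrics(gold, pred, h, "set_based")
  expect_equal(sb$micro[["precision"]], 2 / 3)
  expect_equal(sb$micro[["recall"]], 2 / 3)
  cp <- hierarchical_metrics(gold, pred, h, "cophe")
  expect_equal(cp$micro[["precision"]], 3 / 4)
  expect_equal(cp$micro[["recall"]], 3 / 4)

  # over-prediction within the family: CoPHE drops below set-based
  gold2 <- list(d1 = "A01.1")
  pred2 <- list(d1 = c("A01.1", "A01.2"))
  sb2 <- hierarchical_metrics(gold2, pred2, h, "set_based")
  cp2 <- hierarchical_metrics(gold2, pred2, h, "cophe")
  expect_equal(sb2$micro[["precision"]], 2 / 3)
  expect_equal(sb2$micro[["recall"]], 1)
  expect_equal(cp2$micro[["precision"]], 2 / 4)
  expect_equal(cp2$micro[["recall"]], 1)
  expect_lt(cp2$micro[["f1"]], sb2$micro[["f1"]])

  # perfect prediction: every variant returns 1
  for (v in c("leaf_only", "set_based", "cophe")) {
    expect_equal(hierarchical_metrics(gold, gold, h, v)$micro[["f1"]], 1)
  }
})

test_that("sibling confusion preserves CoPHE ancestor credit", {
  # replacing a predicted gold leaf by a sibling keeps the family count
  # intact, so CoPHE >= set-based on count-preserving confusions
  h <- fam_hier(c("A01.1", "A01.2", "A01.3", "B02.1"))
  gold <- list(d1 = c("A01.1", "B02.1"))
  pred <- list(d1 = c("A01.2", "B02.1"))  # A01.1 -> sibling A01.2
  sb <- hierarchical_metrics(gold, pred, h, "set_based")
  cp <- hierarchical_metrics(gold, pred, h, "cophe")
  expect_gte(cp$micro[["f1"]], sb$micro[["f1"]])
  leaf <- hierarchical_metrics(gold, pred, h, "leaf_only")
  expect_lt(leaf$micro[["f1"]], cp$micro[["f1"]])
})

test_that("WHCM classifies the worked example and conserves rates", {
  h <- fam_hier(c("A01.1", "A01.2", "B02.1"))
  gold <- list(d1 = c("A01.1", "B02.1"))
  pred <- list(d1 = "A01.2")
  w <- whcm_rates(gold, pred, c("A01.1", "B02.1"), h)
  expect_equal(w$oof, 50)
  expect_equal(w$if_, 50)
  expect_equal(w$tp, 0)
  # perfect predictions: no errors
  w2 <- whcm_rates(gold, gold, c("A01.1", "B02.1"), h)
  expect_equal(w2$oof, 0)
  expect_equal(w2$if_, 0)
  expect_equal(w2$tp, 100)
  # a false positive alone creates no FN error
  w3 <- whcm_rates(list(d1 = "A01.1"), list(d1 = c("A01.1", "A01.2")),
                   "A01.1", h)
  expect_equal(w3$tp, 100)
  expect_equal(w3$oof + w3$if_, 0)
})

test_that("metrics agree exactly with brute-force oracles on random instances", {
  set.seed(77)
  for (rep in 1:120) {
    inst <- random_instance()
    h <- fam_hier(inst$leaves)
    gold <- inst$gold
    pred <- inst$pred
    # flat
    m <- flat_metrics(gold, pred, inst$leaves)
    o <- oracle_flat(gold, pred, inst$leaves)
    expect_equal(unname(m$micro), o$micro)
    expect_equal(unname(m$macro), unname(o$macro))
    # hierarchical, both variants
    for (v in c("set_based", "cophe")) {
      mode <- if (v == "cophe") "counts" else "set"
      mh <- hierarchical_metrics(gold, pred, h, v)
      oh <- oracle_hier(gold, pred, mode)
      expect_equal(mh$micro, oh)
    }
    # WHCM on a random codeset
    cs <- sample(inst$leaves, max(1, length(inst$leaves) %/% 2))
    has_gold <- any(unlist(lapply(gold, intersect, cs)) %in% cs)
    if (has_gold) {
      mw <- suppressMessages(whcm_rates(gold, pred, cs, h))
      ow <- oracle_whcm(gold, pred, cs)
      expect_equal(mw$oof, ow$oof)
      expect_equal(mw$if_, ow$if_)
      expect_equal(mw$tp, ow$tp)
      expect_equal(mw$n_labels, ow$n_labels)
      # conservation: per label TP% + IF% + OOF% = 100
      expect_true(all(abs(rowSums(mw$per_label) - 100) < 1e-9))
    }
  }
})

test_that("metrics are invariant to document and label order", {
  set.seed(5)
  inst <- random_instance()
  h <- fam_hier(inst$leaves)
  gold <- inst$gold
  pred <- inst$pred
  perm <- sample(names(gold))
  gold2 <- lapply(gold[perm], rev)
  pred2 <- lapply(pred[perm], sample)
  m1 <- flat_metrics(gold, pred, inst$leaves)
  m2 <- flat_metrics(gold2, pred2, inst$leaves)
  expect_equal(m1$micro, m2$micro)
  expect_equal(m1$macro, m2$macro)
  h1 <- hierarchical_metrics(gold, pred, h, "cophe")
  h2 <- hierarchical_metrics(gold2, pred2, h, "cophe")
  expect_equal(h1$micro, h2$micro)
})
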