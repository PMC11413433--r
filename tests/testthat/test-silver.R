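# a small corpus where family A01 has a frequent member (A01.0), two
# few-shot members (A01.1 pop 3, A01.2 pop 4) and a zero-shot member
# (A01.9, test only); B05 is an unrelated background family
silver_fixture <- function(seed = 3) {
  space <- make_code_space(code_space_config(n_families = 3, n_background = 5))
  sc <- sample_corpus(space, corpus_config(n_train = 350, n_dev = 60,
                                           n_test = 120, seed = seed))
  sel <- select_generation_targets(
    label_populations(sc$corpus),
    selection_config(n_families = 2, seed = seed))
  list(corpus = sc$corpus, selection = sel, space = space)
}

test_that("drop_nonrelevant keeps relevant labels and caps drops", {
  set.seed(1)
  # cap at the number of non-relevant labels
  for (i in 1:50) {
    out <- drop_nonrelevant(c("R07.9", "A01.1", "B02.2", "C03.3"), "R07.9")
    expect_true("R07.9" %in% out)
    expect_gte(length(out), 1)
  }
  expect_equal(drop_nonrelevant("R07.9", "R07.9"), "R07.9")
  # uniform-k contract: with 8 non-relevant labels every k in 0..5 occurs,
  # and relevant labels are never dropped
  labels <- c("R07.9", sprintf("B%02d.1", 1:8))
  ks <- integer(0)
  for (i in 1:2000) {
    out <- drop_nonrelevant(labels, "R07.9")
    expect_true("R07.9" %in% out)
    ks <- c(ks, length(labels) - length(out))
  }
  expect_setequal(unique(ks), 0:5)
  # roughly uniform: each k should appear in about a sixth of draws
  expect_true(all(table(ks) > 2000 / 6 * 0.5))
})

test_that("clone_to_population produces the target count with round-robin clones", {
  src <- new_corpus(sprintf("s%d", 1:4),
                    rep("text", 4),
                    replicate(4, c("A01.1", "B02.0", "C03.0"), simplify = FALSE),
                    rep("train", 4))
  set.seed(2)
  recs <- clone_to_population(src, "A01.1", target_pop = 100)
  expect_length(recs, 100)
  expect_equal(sum(vapply(recs, function(r) r$clone_index == 0L, logical(1))), 4)
  # originals keep their full label sets
  for (r in recs[1:4]) expect_setequal(r$labels, c("A01.1", "B02.0", "C03.0"))
  # every record carries the target code
  for (r in recs) expect_true("A01.1" %in% r$labels)
  # round-robin: each source contributes 24 clones
  tab <- table(vapply(recs, `[[`, character(1), "source_doc_id"))
  expect_true(all(tab == 25))
  # 98 sources -> 2 clones
  src98 <- new_corpus(sprintf("t%d", 1:98), rep("x", 98),
                      replicate(98, "A01.1", simplify = FALSE), rep("train", 98))
  expect_length(clone_to_population(src98, "A01.1", target_pop = 100), 100)
  # population already met: sources returned unchanged
  expect_length(clone_to_population(src98, "A01.1", target_pop = 50), 98)
  expect_error(clone_to_population(src98[0, ], "A01.1"), "no source")
})

test_that("substitute_zero_shot swaps exactly one sibling for the zero-shot code", {
  doc <- new_corpus("d1", "t", list(c("S02.1", "S02.5", "K21.9")), "train")
  codeset <- c("S02.1", "S02.5", "S02.63XA", "K21.9")
  set.seed(4)
  seen <- character(0)
  for (i in 1:50) {
    r <- substitute_zero_shot(doc[1, ], "S02.63XA", codeset)
    expect_true(r$is_zero_shot)
    expect_true("S02.63XA" %in% r$labels)
    expect_true("K21.9" %in% r$labels)
    removed <- setdiff(c("S02.1", "S02.5"), r$labels)
    expect_length(removed, 1)
    seen <- union(seen, removed)
  }
  expect_setequal(seen, c("S02.1", "S02.5"))  # both siblings get chosen
  doc2 <- new_corpus("d2", "t", list("G43.0"), "train")
  r2 <- substitute_zero_shot(doc2[1, ], "G43.9", c("G43.0", "G43.9"))
  expect_equal(r2$labels, "G43.9")
  doc3 <- new_corpus("d3", "t", list("K21.9"), "train")
  expect_error(substitute_zero_shot(doc3[1, ], "G43.9", c("G43.0", "K21.9")),
               "no sibling")
})

test_that("build_silver_set meets the per-code population and temperature contracts", {
  fx <- silver_fixture()
  silver <- build_silver_set(fx$corpus, fx$selection, seed = 9)
  recs <- silver$records
  gen <- fx$selection$generation_codes
  few <- gen$code[gen$stratum == "few_shot" & !gen$code %in% silver$skipped]
  # exactly 100 records per few-shot generation code with sources
  for (code in few) {
    n <- sum(vapply(recs, function(r) r$target_code == code && !r$is_zero_shot,
                    logical(1)))
    expect_equal(n, 100)
  }
  # conservation: target code always inside its label set
  for (r in recs) expect_true(r$target_code %in% r$labels)
  # duplicates (and only duplicates) carry temperature 0.1
  keys <- vapply(recs, function(r) paste(r$labels, collapse = "|"), character(1))
  expect_identical(vapply(recs, `[[`, logical(1), "duplicate"),
                   duplicated(keys))
  temps <- vapply(recs, `[[`, numeric(1), "temperature")
  expect_true(all(temps[duplicated(keys)] == 0.1))
  expect_true(all(temps[!duplicated(keys)] == 0))
  # no record drops more than 5 non-relevant labels relative to its source
  src_labels <- stats::setNames(fx$corpus$labels, fx$corpus$doc_id)
  for (r in recs) {
    src <- src_labels[[r$source_doc_id]]
    if (r$is_zero_shot) {
      expect_length(setdiff(src, r$labels), 1)  # exactly one former sibling
    } else {
      expect_lte(length(setdiff(src, r$labels)), 5)
    }
  }
  # seed-reproducible, order-stable
  silver2 <- build_silver_set(fx$corpus, fx$selection, seed = 9)
  expect_identical(silver$records, silver2$records)
})

test_that("silver arithmetic: clones plus one substitution record per sibling doc", {
  fx <- silver_fixture()
  silver <- build_silver_set(fx$corpus, fx$selection, seed = 9)
  gen <- fx$selection$generation_codes
  few <- gen$code[gen$stratum == "few_shot" & !gen$code %in% silver$skipped]
  zero <- gen$code[gen$stratum == "zero_shot"]
  train <- fx$corpus[fx$corpus$split == "train", ]
  all_codes <- unique(unlist(fx$corpus$labels))
  n_expected <- 100 * length(few)
  for (zs in zero) {
    sibs <- siblings_of(zs, all_codes)
    n_expected <- n_expected +
      sum(vapply(train$labels, function(l) length(intersect(l, sibs)) > 0,
                 logical(1)))
  }
  expect_equal(length(silver$records), n_expected)
})

test_that("silver sets serialize as line-delimited records", {
  fx <- silver_fixture()
  silver <- build_silver_set(fx$corpus, fx$selection, seed = 9)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_silver_set(silver, path)
  lines <- readLines(path)
  expect_length(lines, length(silver$records))
  rec <- jsonlite::fromJSON(lines[1])
  expect_setequal(names(rec), c("source_doc_id", "target_code", "labels",
                                "is_zero_shot", "temperature", "clone_index"))
})
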