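# Synthetic stand-ins for the study's data conditions: an ICD-10-like code
# space with family structure, a big-head long-tail coded corpus with
# planted frequent / few-shot / zero-shot strata, label-conditioned
# learnable text, and ordinal rating fixtures for the agreement module.

.qualifiers <- c("Chronic", "Acute", "Recurrent", "Congenital",
                 "Secondary", "Unilateral", "Diffuse", "Transient")
.fam_nouns <- c("stenosis", "neuropathy", "dermatitis", "fibrosis",
                "embolism", "lesion", "myopathy", "colitis", "nephritis",
                "arthropathy", "keratitis", "angiopathy", "cystitis",
                "glossitis", "pleuritis", "phlebitis")
.syllables <- c("ka", "lo", "mi", "ve", "ra", "tu", "se", "ni", "do", "pa")

# Globally unique pseudo-medical word for leaf index i (alphabetic only,
# so it can never collide with the code surface pattern).
unique_word <- function(i) {
  digs <- as.integer(strsplit(sprintf("%03d", i), "")[[1]]) + 1L
  paste0(paste(.syllables[digs], collapse = ""), "in")
}

# Shared background lexicon: the generic clinical working vocabulary that
# both real (simulated) and generated documents draw their non-trigger
# content from. Sharing it matters: a generator writing in a vocabulary
# disjoint from the corpus would let a coder separate synthetic from real
# text instead of learning label-conditioned features.
noise_word <- function(i) paste0("zu", unique_word(i))

#' Code-space configuration
#'
#' @param n_families Number of designated generation-style families, each
#'   holding a frequent, a mid-population, several few-shot, and a
#'   zero-shot leaf.
#' @param leaves_per_family Leaves per designated family (at least 4).
#' @param n_background Number of frequent background codes forming the big
#'   head of the label distribution (one per extra family).
#' @param seed Integer seed.
#' @return A list of class `code_space_config`.
#' @export
code_space_config <- function(n_families = 12, leaves_per_family = 6,
                              n_background = 20, seed = 1L) {
  stopifnot(n_families >= 1, leaves_per_family >= 4, n_background >= 0)
  structure(list(n_families = n_families,
                 leaves_per_family = leaves_per_family,
                 n_background = n_background, seed = as.integer(seed)),
            class = "code_space_config")
}

#' Generate a synthetic code space
#'
#' Builds an ICD-10-like code space: designated families of
#' `leaves_per_family` leaves sharing a 3-character head, plus background
#' codes in their own families. Each leaf's description pairs a qualifier
#' and family noun with a globally unique pseudo-medical word, so that
#' label-conditioned text is learnable; some descriptions carry the
#' keyword "unspecified" and some the umbrella prefix "Other" to exercise
#' the generation constraints. Within each designated family the leaves
#' are designated (in order) one frequent, one mid-population, few-shot
#' leaves, and a final zero-shot leaf.
#'
#' @param cfg A [code_space_config()].
#' @return A list of class `code_space`: `hierarchy`, `code_table` (named
#'   character vector), `strata` (tibble with `code`, `family`,
#'   `designation`), and `trigger_tokens` (named list).
#' @export
make_code_space <- function(cfg = code_space_config()) {
  heads_fam <- sprintf("%s%02d", LETTERS[(seq_len(cfg$n_families) - 1) %% 26 + 1],
                       seq_len(cfg$n_families))
  heads_bg <- if (cfg$n_background > 0) {
    sprintf("%s%02d", letters_to_head(seq_len(cfg$n_background)),
            50 + (seq_len(cfg$n_background) - 1) %% 50)
  } else character(0)
  codes <- character(0); descs <- character(0)
  fams <- character(0); desig <- character(0)
  leaf_no <- 0L
  for (fi in seq_len(cfg$n_families)) {
    noun <- .fam_nouns[(fi - 1) %% length(.fam_nouns) + 1]
    for (li in seq_len(cfg$leaves_per_family)) {
      leaf_no <- leaf_no + 1L
      code <- paste0(heads_fam[fi], ".", li - 1)
      qual <- .qualifiers[(leaf_no - 1) %% length(.qualifiers) + 1]
      d <- paste(qual, unique_word(leaf_no), noun)
      if (li %% 3 == 0) d <- paste0(d, ", unspecified")
      if (li %% 4 == 0) d <- paste("Other", tolower(substr(d, 1, 1)),
                                   substr(d, 2, nchar(d)))
      if (li %% 4 == 0) d <- gsub("^Other ([a-z]) ", "Other \\1", d)
      codes <- c(codes, code); descs <- c(descs, d); fams <- c(fams, heads_fam[fi])
      desig <- c(desig, if (li == 1) "frequent" else if (li == 2) "mid"
                 else if (li == cfg$leaves_per_family) "zero_shot" else "few_shot")
    }
  }
  for (bi in seq_along(heads_bg)) {
    leaf_no <- leaf_no + 1L
    code <- paste0(heads_bg[bi], ".0")
    d <- paste(.qualifiers[(bi - 1) %% length(.qualifiers) + 1],
               unique_word(leaf_no),
               .fam_nouns[(bi - 1) %% length(.fam_nouns) + 1])
    codes <- c(codes, code); descs <- c(descs, d); fams <- c(fams, heads_bg[bi])
    desig <- c(desig, "background")
  }
  triggers <- lapply(descs, function(d) {
    toks <- preprocess_text(d)
    setdiff(toks, c("other", "unspecified"))
  })
  names(triggers) <- codes
  structure(list(
    hierarchy = code_hierarchy(codes),
    code_table = stats::setNames(descs, codes),
    strata = tibble::tibble(code = codes, family = fams, designation = desig),
    trigger_tokens = triggers,
    config = cfg),
    class = "code_space")
}

letters_to_head <- function(i) {
  # distinct letter sequence for background heads, offset from family heads
  LETTERS[(i + 13) %% 26 + 1]
}

#' Corpus simulation configuration
#'
#' Defaults are the package's desk-scale study conditions: a 3000/300/600
#' train/dev/test split, a truncated-Poisson label count per document with
#' mean 5 (a scaled-down analogue of the double-digit label counts of real
#' inpatient coding, identical across splits), power-law label popularity
#' with exponent 1.5 for the big-head long-tail shape, and noisy
#' label-conditioned text in which each label emits its trigger tokens
#' with probability 0.9 amid background noise tokens.
#'
#' @param n_train,n_dev,n_test Documents per split.
#' @param mean_labels Mean labels per document (all splits).
#' @param max_labels Cap on labels per document.
#' @param popularity_exponent Power-law exponent for popularity weights.
#' @param trigger_prob Probability each trigger token of a carried label
#'   appears in the document text.
#' @param noise_vocab Size of the background noise vocabulary.
#' @param mean_tokens Target mean document length in tokens.
#' @param balanced If `TRUE`, the few-shot stratum is planted with a
#'   comfortably learnable training population (20-40) instead of 1-5;
#'   used with `trigger_prob = 1` this is the separable configuration for
#'   checking that label-conditioned text is learnable.
#' @param seed Integer seed.
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(n_train = 3000, n_dev = 300, n_test = 600,
                          mean_labels = 5, max_labels = 12,
                          popularity_exponent = 1.5, trigger_prob = 0.9,
                          noise_vocab = 500, mean_tokens = 30,
                          balanced = FALSE, seed = 1L) {
  stopifnot(n_train > 0, n_dev > 0, n_test > 0, mean_labels >= 1,
            trigger_prob > 0, trigger_prob <= 1)
  structure(list(n_train = n_train, n_dev = n_dev, n_test = n_test,
                 mean_labels = mean_labels, max_labels = max_labels,
                 popularity_exponent = popularity_exponent,
                 trigger_prob = trigger_prob, noise_vocab = noise_vocab,
                 mean_tokens = mean_tokens, balanced = isTRUE(balanced),
                 seed = as.integer(seed)),
            class = "corpus_config")
}

plant_targets <- function(balanced = FALSE) {
  # per-split population target ranges per designation; counts are drawn
  # inside the seeded sampler, one row per code. The balanced profile
  # replaces the few-shot stratum with a comfortably learnable population
  # (used by the separability check of the coder).
  few_train <- if (balanced) c(20, 40) else c(1, 5)
  few_dev <- if (balanced) c(3, 6) else c(1, 2)
  data.frame(
    designation = c("frequent", "mid", "few_shot", "zero_shot", "background"),
    lo_train = c(110, 15, few_train[1], 0, 0),
    hi_train = c(160, 60, few_train[2], 0, 0),
    lo_dev = c(8, 2, few_dev[1], 0, 0), hi_dev = c(15, 6, few_dev[2], 0, 0),
    lo_test = c(15, 4, 2, 3, 0), hi_test = c(30, 12, 5, 8, 0))
}

#' Sample a synthetic coded corpus
#'
#' Generates a corpus with the statistical structure the augmentation study
#' assumes. Strata are planted deterministically before popularity
#' sampling: every designated frequent code receives a training population
#' above 100, every few-shot code a training population in 1..5 plus dev
#' and test presence, and every zero-shot code appears only in the test
#' split. Remaining label slots are filled by power-law popularity sampling
#' over the frequent and background codes, with the same label-count
#' distribution in every split. Document text consists of each carried
#' label's trigger tokens (each emitted with `trigger_prob`) shuffled among
#' background noise tokens.
#'
#' @param space A [make_code_space()] result.
#' @param cfg A [corpus_config()].
#' @return A list of class `synthetic_corpus`: `corpus` (an
#'   [new_corpus()] tibble, provenance `"synthetic"`) and `manifest`
#'   (realized populations joined with strata designations, plus seeds).
#' @export
sample_corpus <- function(space, cfg = corpus_config()) {
  n_split <- c(train = cfg$n_train, dev = cfg$n_dev, test = cfg$n_test)
  strata <- space$strata
  with_seed(substream(cfg$seed, "sample_corpus"), {
    labels <- list(
      train = replicate(cfg$n_train, character(0), simplify = FALSE),
      dev = replicate(cfg$n_dev, character(0), simplify = FALSE),
      test = replicate(cfg$n_test, character(0), simplify = FALSE))
    tgt <- plant_targets(cfg$balanced)
    # deterministic planting of the strata populations
    for (ci in seq_len(nrow(strata))) {
      row <- tgt[tgt$designation == strata$designation[ci], ]
      for (sp in c("train", "dev", "test")) {
        lo <- row[[paste0("lo_", sp)]]; hi <- row[[paste0("hi_", sp)]]
        if (hi == 0) next
        want <- if (lo == hi) lo else sample(lo:hi, 1L)
        if (want == 0) next
        if (want > n_split[[sp]]) {
          stop("infeasible strata: ", want, " plants of ",
               strata$code[ci], " exceed the ", sp, " split size",
               call. = FALSE)
        }
        docs <- sample.int(n_split[[sp]], want)
        for (d in docs) {
          labels[[sp]][[d]] <- union(labels[[sp]][[d]], strata$code[ci])
        }
      }
    }
    # power-law popularity fill over the background codes; the designated
    # strata keep exactly their planted populations
    pool <- strata$code[strata$designation == "background"]
    pool <- sample(pool)  # random popularity ranks
    w <- seq_along(pool)^(-cfg$popularity_exponent)
    for (sp in c("train", "dev", "test")) {
      for (d in seq_len(n_split[[sp]])) {
        n_lab <- min(1L + stats::rpois(1, cfg$mean_labels - 1), cfg$max_labels)
        need <- n_lab - length(labels[[sp]][[d]])
        if (need <= 0) next
        avail <- !(pool %in% labels[[sp]][[d]])
        pick <- sample(pool[avail], min(need, sum(avail)), prob = w[avail])
        labels[[sp]][[d]] <- union(labels[[sp]][[d]], pick)
      }
    }
    # label-conditioned text
    noise_words <- vapply(seq_len(cfg$noise_vocab), noise_word, character(1))
    texts <- list()
    for (sp in c("train", "dev", "test")) {
      texts[[sp]] <- vapply(labels[[sp]], function(labs) {
        trig <- unlist(space$trigger_tokens[labs], use.names = FALSE)
        trig <- trig[stats::runif(length(trig)) < cfg$trigger_prob]
        n_noise <- max(3L, stats::rpois(1, max(1, cfg$mean_tokens - length(trig))))
        toks <- c(trig, sample(noise_words, n_noise, replace = TRUE))
        paste(sample(toks), collapse = " ")
      }, character(1))
    }
    corpus <- new_corpus(
      doc_id = c(sprintf("train-%04d", seq_len(cfg$n_train)),
                 sprintf("dev-%04d", seq_len(cfg$n_dev)),
                 sprintf("test-%04d", seq_len(cfg$n_test))),
      text = c(texts$train, texts$dev, texts$test),
      labels = c(labels$train, labels$dev, labels$test),
      split = rep(c("train", "dev", "test"), times = n_split),
      provenance = "synthetic")
    corpus
  }) -> corpus
  pops <- label_populations(corpus)
  manifest <- dplyr::left_join(strata, pops, by = "code")
  for (col in c("train", "dev", "test")) {
    manifest[[col]][is.na(manifest[[col]])] <- 0L
  }
  structure(list(corpus = corpus, manifest = manifest,
                 seed = cfg$seed, config = cfg),
            class = "synthetic_corpus")
}

#' Generate an ordinal rating fixture
#'
#' Draws a complete raters x items x metrics table of 1..5 scores for the
#' agreement module, under a configurable noise profile: `"zero_noise"`
#' (every rater gives the metric's base score — perfect agreement),
#' `"uniform"` (scores uniform on 1..5 — chance-level agreement), or
#' `"mixed"` (item-level base scores with occasional one-point rater
#' deviations). Half the items are real, half synthetic.
#'
#' @param n_raters Number of raters (at least 2).
#' @param n_items Number of items (half real, half synthetic).
#' @param profile Noise profile.
#' @param seed Integer seed.
#' @return A `rating_table` tibble.
#' @export
rating_fixture <- function(n_raters = 4, n_items = 20,
                           profile = c("mixed", "zero_noise", "uniform"),
                           seed = 1L) {
  stopifnot(n_raters >= 2, n_items >= 2)
  profile <- match.arg(profile)
  metrics <- c("correctness_nonlow", "correctness_low",
               "informativeness_nonlow", "informativeness_low",
               "authenticity_patient", "authenticity_scenario",
               "acceptability")
  with_seed(substream(seed, "rating_fixture"), {
    items <- sprintf("item-%03d", seq_len(n_items))
    cls <- rep(c("real", "synthetic"), length.out = n_items)
    rows <- list()
    for (mi in seq_along(metrics)) {
      base_metric <- ((mi * 2) %% 4) + 2  # base scores 2..5 per metric
      for (ii in seq_len(n_items)) {
        base_item <- switch(profile,
          zero_noise = base_metric,
          uniform = NA_integer_,
          mixed = max(1, min(5, base_metric + sample(-1:1, 1))))
        for (ri in seq_len(n_raters)) {
          s <- switch(profile,
            zero_noise = base_item,
            uniform = sample(1:5, 1),
            mixed = max(1, min(5, base_item +
                                 sample(c(-1, 0, 0, 0, 1), 1))))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            item_id = items[ii], item_class = cls[ii],
            rater_id = sprintf("rater-%02d", ri),
            metric = metrics[mi], score = as.integer(s))
        }
      }
    }
    as_rating_table(dplyr::bind_rows(rows))
  })
}
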