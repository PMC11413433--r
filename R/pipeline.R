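#' Study configuration
#'
#' Bundles the per-stage configurations of the end-to-end augmentation
#' study and a single global seed from which every stage derives its own
#' named substream. The defaults are the package's desk-scale study
#' conditions (see the methods vignette).
#'
#' @param seed Global integer seed.
#' @param space_cfg A [code_space_config()].
#' @param corpus_cfg A [corpus_config()].
#' @param selection_cfg A [selection_config()].
#' @param target_pop Silver-standard per-code target population.
#' @param max_drop Maximum non-relevant labels dropped per clone.
#' @param coder_cfg A [coder_config()].
#' @param arms Which experiment arms to train: `"both"`, `"baseline"`, or
#'   `"augmented"`.
#' @param out_dir Optional output directory for reports.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         space_cfg = code_space_config(),
                         corpus_cfg = corpus_config(),
                         selection_cfg = selection_config(),
                         target_pop = 100, max_drop = 5,
                         coder_cfg = coder_config(),
                         arms = c("both", "baseline", "augmented"),
                         out_dir = NULL) {
  arms <- match.arg(arms)
  structure(list(seed = as.integer(seed), space_cfg = space_cfg,
                 corpus_cfg = corpus_cfg, selection_cfg = selection_cfg,
                 target_pop = target_pop, max_drop = max_drop,
                 coder_cfg = coder_cfg, arms = arms, out_dir = out_dir),
            class = "study_config")
}

#' Build the augmentation training documents from a silver set
#'
#' Generates one document per silver record with the supplied generator,
#' extracts the trailing bracketed codes, scrubs residual code mentions
#' from the body, and returns the synthetic training documents whose labels
#' are the extracted codes.
#'
#' @param silver A `silver_set`.
#' @param code_table Named character vector of code descriptions.
#' @param generator Generator function (default [mock_llm_generate()]).
#' @param seed Integer seed forwarded to the generator.
#' @return An [new_corpus()] tibble of split `"train"` documents with
#'   provenance `"synthetic"`.
#' @export
generate_training_documents <- function(silver, code_table,
                                        generator = mock_llm_generate,
                                        seed = 1L) {
  n <- length(silver$records)
  texts <- character(n); labels <- vector("list", n)
  for (i in seq_len(n)) {
    raw <- generate_document(silver$records[[i]], code_table,
                             generator = generator, seed = seed)
    ex <- extract_assigned_codes(raw)
    texts[[i]] <- scrub_codes(ex$body)
    labels[[i]] <- ex$codes
  }
  new_corpus(doc_id = sprintf("gen-%05d", seq_len(n)),
             text = texts, labels = labels,
             split = rep("train", n), provenance = "synthetic")
}

merge_training_sets <- function(baseline, synthetic_docs) {
  merged <- dplyr::bind_rows(baseline, synthetic_docs)
  structure(merged, provenance = "augmented",
            class = c("icd_corpus", class(tibble::tibble())))
}

evaluate_arm <- function(coder, test, selection, hierarchy, all_codes) {
  pred <- predict(coder, test)$labels
  gold <- gold_labels(test)
  f_codes <- all_codes[family_of(all_codes) %in% selection$chosen_families]
  fgen_codes <- selection$generation_codes$code
  list(
    flat = list(
      overall = flat_metrics(gold, pred, all_codes),
      f = flat_metrics(gold, pred, f_codes),
      fgen = flat_metrics(gold, pred, fgen_codes)),
    hierarchical = list(
      set_based = hierarchical_metrics(gold, pred, hierarchy, "set_based"),
      cophe = hierarchical_metrics(gold, pred, hierarchy, "cophe")),
    whcm = list(
      f = suppressMessages(whcm_rates(gold, pred, f_codes, hierarchy)),
      fgen = suppressMessages(whcm_rates(gold, pred, fgen_codes, hierarchy))),
    coder_meta = list(selected_epoch = coder$selected_epoch,
                      dev_map = coder$dev_map))
}

#' Run the augmentation study end to end
#'
#' Executes the full pipeline on synthetic data: simulate a coded corpus
#' with planted frequent/few-shot/zero-shot strata, select low-resource
#' generation families, build the silver-standard generation requests,
#' generate and scrub synthetic training documents, train baseline and
#' augmented coders on identical dev/test splits, and evaluate flat,
#' hierarchical, and within-/out-of-family metrics on the overall, family
#' (f), and generation (f(gen)) codesets.
#'
#' @param config A [study_config()].
#' @return A list of class `study_summary` with elements `selection`,
#'   `n_silver`, `n_baseline_train`, `n_augmented_train`, `arms` (named
#'   list of per-arm evaluation bundles), and `seed`.
#' @export
run_study <- function(config = study_config()) {
  seed <- config$seed
  config$space_cfg$seed <- substream(seed, "space")
  config$corpus_cfg$seed <- substream(seed, "corpus")
  config$selection_cfg$seed <- substream(seed, "selection")

  space <- make_code_space(config$space_cfg)
  sc <- sample_corpus(space, config$corpus_cfg)
  corpus <- sc$corpus
  pop <- label_populations(corpus)
  selection <- select_generation_targets(pop, config$selection_cfg)
  silver <- build_silver_set(corpus, selection,
                             target_pop = config$target_pop,
                             max_drop = config$max_drop,
                             seed = substream(seed, "silver-stage"))
  syn_docs <- generate_training_documents(silver, space$code_table,
                                          seed = substream(seed, "generate"))
  train <- corpus_split(corpus, "train")
  dev <- corpus_split(corpus, "dev")
  test <- corpus_split(corpus, "test")
  augmented_train <- merge_training_sets(train, syn_docs)
  all_codes <- sort(unique(unlist(corpus$labels, use.names = FALSE)))

  arms <- list()
  if (config$arms %in% c("both", "baseline")) {
    cfgb <- config$coder_cfg; cfgb$seed <- substream(seed, "coder-baseline")
    coder_b <- train_coder(train, dev, cfgb)
    arms$baseline <- evaluate_arm(coder_b, test, selection, space$hierarchy,
                                  all_codes)
  }
  if (config$arms %in% c("both", "augmented")) {
    cfga <- config$coder_cfg; cfga$seed <- substream(seed, "coder-augmented")
    coder_a <- train_coder(augmented_train, dev, cfga)
    arms$augmented <- evaluate_arm(coder_a, test, selection, space$hierarchy,
                                   all_codes)
  }
  summary <- structure(list(
    selection = selection, n_silver = length(silver$records),
    n_baseline_train = nrow(train),
    n_augmented_train = nrow(augmented_train),
    arms = arms, seed = seed),
    class = "study_summary")
  if (!is.null(config$out_dir)) write_study_reports(summary, config$out_dir)
  summary
}

#' @export
print.study_summary <- function(x, ...) {
  cat("<study_summary> seed ", x$seed, ": ", x$n_baseline_train,
      " baseline + ", x$n_silver, " silver = ", x$n_augmented_train,
      " augmented training documents\n", sep = "")
  for (arm in names(x$arms)) {
    fl <- x$arms[[arm]]$flat
    cat(sprintf("  %-9s micro-F1 overall %.4f | macro-F1 f(gen) %.4f | OOF f(gen) %.1f%%\n",
                arm, fl$overall$micro[["f1"]], fl$fgen$macro[["f1"]],
                x$arms[[arm]]$whcm$fgen$oof))
  }
  invisible(x)
}

summary_to_list <- function(x) {
  arm_list <- lapply(x$arms, function(a) {
    list(
      flat = lapply(a$flat, function(m) list(
        micro = as.list(round(m$micro, 6)), macro = as.list(round(m$macro, 6)))),
      hierarchical = lapply(a$hierarchical, function(m)
        list(micro = as.list(round(m$micro, 6)))),
      whcm = lapply(a$whcm, function(w) list(
        oof = round(w$oof, 6), if_ = round(w$if_, 6), tp = round(w$tp, 6))),
      selected_epoch = a$coder_meta$selected_epoch)
  })
  list(seed = x$seed,
       n_silver = x$n_silver,
       n_baseline_train = x$n_baseline_train,
       n_augmented_train = x$n_augmented_train,
       chosen_families = x$selection$chosen_families,
       n_generation_codes = nrow(x$selection$generation_codes),
       arms = arm_list)
}

#' Write study reports
#'
#' Writes a JSON summary and a CSV of flat metrics per arm and codeset
#' under `out_dir`. Output is deterministic for a given summary.
#'
#' @param summary A `study_summary`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_reports <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(summary_to_list(summary),
                       file.path(out_dir, "study_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  rows <- list()
  for (arm in names(summary$arms)) {
    for (cs in names(summary$arms[[arm]]$flat)) {
      m <- summary$arms[[arm]]$flat[[cs]]
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, codeset = cs,
        micro_p = m$micro[["precision"]], micro_r = m$micro[["recall"]],
        micro_f1 = m$micro[["f1"]], macro_p = m$macro[["precision"]],
        macro_r = m$macro[["recall"]], macro_f1 = m$macro[["f1"]])
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "flat_metrics.csv"), row.names = FALSE)
  invisible(out_dir)
}
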