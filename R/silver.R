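#' Randomly drop non-relevant labels
#'
#' To increase the variety of cloned label sets, up to `max_drop` of the
#' labels that are not generation-relevant are removed: a drop count `k` is
#' drawn uniformly from `0..min(max_drop, #nonrelevant)` and `k` of the
#' non-relevant labels are removed uniformly without replacement. Relevant
#' labels are always retained. Draws come from the current RNG state; wrap
#' in a seeded context for reproducibility.
#'
#' @param labels Character vector of codes.
#' @param relevant Character vector of codes that must be kept
#'   (a subset of `labels`).
#' @param max_drop Maximum number of labels to drop.
#' @return Character vector of retained labels (sorted).
#' @export
drop_nonrelevant <- function(labels, relevant, max_drop = 5) {
  labels <- unique(parse_code(labels))
  relevant <- unique(parse_code(relevant))
  stopifnot(all(relevant %in% labels))
  nonrel <- setdiff(labels, relevant)
  cap <- min(max_drop, length(nonrel))
  if (cap == 0L) return(sort(labels))
  k <- sample.int(cap + 1L, 1L) - 1L  # uniform over 0..cap
  dropped <- if (k > 0L) nonrel[sample.int(length(nonrel), k)] else character(0)
  sort(setdiff(labels, dropped))
}

new_silver_record <- function(source_doc_id, target_code, labels,
                              is_zero_shot, clone_index) {
  stopifnot(target_code %in% labels)
  list(source_doc_id = source_doc_id, target_code = target_code,
       labels = sort(unique(labels)), is_zero_shot = is_zero_shot,
       clone_index = as.integer(clone_index), temperature = NA_real_)
}

#' Clone source documents to a target population
#'
#' For a few-shot generation code, produces one silver record per source
#' document (clone index 0, labels unmodified) plus enough clones, cycling
#' round-robin over the sources, to reach `target_pop` records. Each clone's
#' non-relevant labels pass through [drop_nonrelevant()].
#'
#' @param sources Corpus subset (tibble rows) of documents carrying `code`.
#' @param code The generation code being brought up to population.
#' @param relevant Codes never dropped from clones (must include `code`).
#' @param target_pop Target per-code record count.
#' @param max_drop Maximum non-relevant labels dropped per clone.
#' @return List of silver records. When the source population already meets
#'   `target_pop`, the unmodified source records are returned unchanged.
#' @export
clone_to_population <- function(sources, code, relevant = code,
                                target_pop = 100, max_drop = 5) {
  if (nrow(sources) == 0L) stop("no source documents for code ", sQuote(code),
                                call. = FALSE)
  code <- parse_code(code)
  stopifnot(all(vapply(sources$labels, function(l) code %in% l, logical(1))))
  recs <- lapply(seq_len(nrow(sources)), function(i) {
    new_silver_record(sources$doc_id[[i]], code, sources$labels[[i]],
                      is_zero_shot = FALSE, clone_index = 0L)
  })
  n_clones <- target_pop - nrow(sources)
  if (n_clones <= 0L) return(recs)
  src_idx <- rep_len(seq_len(nrow(sources)), n_clones)
  clone_no <- stats::ave(src_idx, src_idx, FUN = seq_along)
  clones <- lapply(seq_len(n_clones), function(j) {
    i <- src_idx[[j]]
    rel <- intersect(union(relevant, code), sources$labels[[i]])
    new_silver_record(sources$doc_id[[i]], code,
                      drop_nonrelevant(sources$labels[[i]], rel, max_drop),
                      is_zero_shot = FALSE, clone_index = clone_no[[j]])
  })
  c(recs, clones)
}

#' Substitute a zero-shot code for a random sibling
#'
#' Builds a silver record for one document: a uniformly chosen sibling of
#' the zero-shot code present in the document's labels is removed and the
#' zero-shot code inserted; all other labels are unchanged.
#'
#' @param doc One corpus row (a list or one-row tibble with `doc_id`,
#'   `labels`).
#' @param zs_code The zero-shot code to plant.
#' @param codeset Character vector of codes defining the sibling pool
#'   (typically all codes observed in the corpus).
#' @return A silver record with `is_zero_shot = TRUE`.
#' @export
substitute_zero_shot <- function(doc, zs_code, codeset) {
  zs_code <- parse_code(zs_code)
  labels <- doc$labels[[1]]
  sibs <- intersect(labels, siblings_of(zs_code, codeset))
  if (length(sibs) == 0L) {
    stop("no sibling of ", sQuote(zs_code), " in document ",
         sQuote(doc$doc_id[[1]]), call. = FALSE)
  }
  victim <- if (length(sibs) == 1L) sibs else sibs[sample.int(length(sibs), 1L)]
  new_silver_record(doc$doc_id[[1]], zs_code,
                    c(setdiff(labels, victim), zs_code),
                    is_zero_shot = TRUE, clone_index = 0L)
}

#' Build the full silver-standard generation set
#'
#' For every few-shot generation code with at least one training source
#' document, clones sources to a population of `target_pop`; for every
#' zero-shot generation code, creates one sibling-substitution record per
#' training document containing a sibling. Records whose final label set
#' exactly equals an earlier record's are flagged as duplicates; duplicates
#' are assigned generation temperature 0.1 (allowing output variation) and
#' unique label sets temperature 0 (deterministic generation).
#'
#' @param corpus An [new_corpus()] tibble.
#' @param selection A `selection_result` from [select_generation_targets()].
#' @param target_pop Per-code target population (default 100).
#' @param max_drop Maximum non-relevant labels dropped per clone.
#' @param seed Integer seed controlling label dropping and sibling choice.
#' @return A list of class `silver_set`: `records` (list of silver records,
#'   each with `temperature` and `duplicate` filled in) and `skipped`
#'   (few-shot codes with zero training sources).
#' @export
build_silver_set <- function(corpus, selection, target_pop = 100,
                             max_drop = 5, seed = 1L) {
  gen <- selection$generation_codes
  few <- gen$code[gen$stratum == "few_shot"]
  zero <- gen$code[gen$stratum == "zero_shot"]
  train <- corpus_split(corpus, "train")
  all_codes <- unique(unlist(corpus$labels, use.names = FALSE))

  with_seed(substream(seed, "silver"), {
    records <- list()
    skipped <- character(0)
    for (code in few) {
      has <- vapply(train$labels, function(l) code %in% l, logical(1))
      if (!any(has)) { skipped <- c(skipped, code); next }
      records <- c(records,
                   clone_to_population(train[has, , drop = FALSE], code,
                                       relevant = gen$code,
                                       target_pop = target_pop,
                                       max_drop = max_drop))
    }
    for (zs in zero) {
      sibs <- siblings_of(zs, all_codes)
      has <- vapply(train$labels, function(l) length(intersect(l, sibs)) > 0,
                    logical(1))
      for (i in which(has)) {
        records <- c(records,
                     list(substitute_zero_shot(train[i, , drop = FALSE],
                                               zs, all_codes)))
      }
    }
    records
  }) -> records

  keys <- vapply(records, function(r) paste(r$labels, collapse = "|"), character(1))
  dup <- duplicated(keys)
  for (i in seq_along(records)) {
    records[[i]]$duplicate <- dup[[i]]
    records[[i]]$temperature <- if (dup[[i]]) 0.1 else 0.0
  }
  structure(list(records = records, skipped = skipped),
            class = "silver_set")
}

#' @export
print.silver_set <- function(x, ...) {
  n <- length(x$records)
  ndup <- sum(vapply(x$records, `[[`, logical(1), "duplicate"))
  cat("<silver_set> ", n, " records (", n - ndup, " unique, ", ndup,
      " duplicated), ", length(x$skipped), " codes skipped (no sources)\n",
      sep = "")
  invisible(x)
}

#' Write a silver set as line-delimited JSON
#'
#' One record per line with fields `source_doc_id`, `target_code`, `labels`,
#' `is_zero_shot`, `temperature`, `clone_index`.
#'
#' @param silver A `silver_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_silver_set <- function(silver, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in silver$records) {
    writeLines(jsonlite::toJSON(list(
      source_doc_id = r$source_doc_id, target_code = r$target_code,
      labels = as.list(r$labels), is_zero_shot = r$is_zero_shot,
      temperature = r$temperature, clone_index = r$clone_index),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}
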