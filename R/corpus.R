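#' Coded document corpora
#'
#' A corpus is a tibble with one row per document and columns `doc_id`
#' (unique string), `text` (string), `labels` (list column of normalized
#' code vectors), and `split` (one of `"train"`, `"dev"`, `"test"`). A
#' `provenance` attribute records whether the corpus is real, synthetic,
#' or augmented.
#'
#' @param doc_id,text,split Character vectors of equal length.
#' @param labels List of character vectors of codes, one per document.
#' @param provenance One of `"real"`, `"synthetic"`, `"augmented"`.
#' @return A tibble of class `icd_corpus`.
#' @export
new_corpus <- function(doc_id, text, labels, split, provenance = "real") {
  stopifnot(length(doc_id) == length(text),
            length(doc_id) == length(labels),
            length(doc_id) == length(split))
  if (anyDuplicated(doc_id)) {
    stop("duplicate doc_id: ",
         paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(split %in% c("train", "dev", "test"))) {
    stop("split must be one of 'train', 'dev', 'test'", call. = FALSE)
  }
  provenance <- match.arg(provenance, c("real", "synthetic", "augmented"))
  labels <- lapply(labels, function(l) sort(unique(parse_code(as.character(l)))))
  out <- tibble::tibble(doc_id = as.character(doc_id),
                        text = as.character(text),
                        labels = labels,
                        split = as.character(split))
  structure(out, provenance = provenance,
            class = c("icd_corpus", class(out)))
}

#' Read a coded corpus from line-delimited JSON
#'
#' One JSON object per line with fields `doc_id`, `text`, `labels`
#' (array of code strings), and `split`.
#'
#' @param path Path to a JSONL file.
#' @param provenance Provenance tag for the corpus.
#' @return An [new_corpus()] tibble.
#' @examples
#' cp <- read_corpus(system.file("extdata", "example_corpus.jsonl",
#'                               package = "icdaug"))
#' label_populations(cp)
#' @export
read_corpus <- function(path, provenance = "real") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) NULL)
    if (is.null(rec) || !all(c("doc_id", "text", "labels", "split") %in% names(rec))) {
      stop("malformed corpus record at line ", i, call. = FALSE)
    }
    recs[[i]] <- rec
  }
  new_corpus(
    doc_id = vapply(recs, function(r) as.character(r$doc_id), character(1)),
    text   = vapply(recs, function(r) as.character(r$text), character(1)),
    labels = lapply(recs, function(r) as.character(unlist(r$labels))),
    split  = vapply(recs, function(r) as.character(r$split), character(1)),
    provenance = provenance)
}

#' Write a coded corpus as line-delimited JSON
#'
#' @param corpus An [new_corpus()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(list(
      doc_id = corpus$doc_id[[i]],
      text = corpus$text[[i]],
      labels = as.list(corpus$labels[[i]]),
      split = corpus$split[[i]]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Tokenize and truncate document text
#'
#' Lowercases, splits on runs of non-alphanumeric characters, and truncates
#' to at most `max_tokens` tokens. The default cap of 4000 words mirrors the
#' common maximum document cutoff in ICD-coding pipelines. Deterministic and
#' idempotent on its own (re-joined) output.
#'
#' @param text A single string.
#' @param max_tokens Maximum number of tokens to retain.
#' @return Character vector of tokens (possibly empty).
#' @export
preprocess_text <- function(text, max_tokens = 4000) {
  stopifnot(length(text) == 1L)
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) > max_tokens) toks <- toks[seq_len(max_tokens)]
  toks
}

#' Per-split label populations
#'
#' Counts, for every code observed in the corpus, the number of documents
#' carrying that code in each split. (A label's population is its document
#' count: each document holds one label set.)
#'
#' @param corpus An [new_corpus()] tibble.
#' @return A tibble with columns `code`, `train`, `dev`, `test`.
#' @export
label_populations <- function(corpus) {
  n <- vapply(corpus$labels, length, integer(1))
  long <- data.frame(code = unlist(corpus$labels, use.names = FALSE),
                     split = rep(corpus$split, n),
                     stringsAsFactors = FALSE)
  codes <- sort(unique(long$code))
  tab <- table(factor(long$code, levels = codes),
               factor(long$split, levels = c("train", "dev", "test")))
  tibble::tibble(code = codes,
                 train = as.integer(tab[, "train"]),
                 dev = as.integer(tab[, "dev"]),
                 test = as.integer(tab[, "test"]))
}

#' Restrict a corpus to one split
#'
#' @param corpus An [new_corpus()] tibble.
#' @param split One of `"train"`, `"dev"`, `"test"`.
#' @return The subset corpus (class and provenance preserved).
#' @export
corpus_split <- function(corpus, split) {
  split <- match.arg(split, c("train", "dev", "test"))
  out <- corpus[corpus$split == split, , drop = FALSE]
  structure(out, provenance = attr(corpus, "provenance"),
            class = class(corpus))
}
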