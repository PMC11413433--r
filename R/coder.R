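#' Coder configuration
#'
#' Hyperparameters of the reference convolutional per-label-attention coder.
#' Defaults are sized for desk-scale corpora: small embedding and
#' convolution widths, 20 training epochs with dev-set model selection by
#' mean average precision, and a 0.5 decision threshold.
#'
#' @param min_freq Minimum training-token frequency to enter the vocabulary.
#' @param emb_dim Word-embedding width.
#' @param conv_dim Convolution output width.
#' @param kernel Convolution kernel size (odd). The default context width
#'   of 1 suits corpora whose token order carries no signal (as in the
#'   bundled simulator); widen it for natural text.
#' @param epochs Number of training epochs.
#' @param threshold Probability threshold for positive predictions.
#' @param lr Adagrad learning rate.
#' @param max_tokens Per-document token cap applied during tokenization.
#' @param seed Integer seed for initialization and epoch shuffling.
#' @return A list of class `coder_config`.
#' @export
coder_config <- function(min_freq = 1, emb_dim = 16, conv_dim = 16,
                         kernel = 1, epochs = 20, threshold = 0.5,
                         lr = 0.15, max_tokens = 4000, seed = 1L) {
  stopifnot(epochs >= 1, threshold > 0, threshold < 1, kernel %% 2 == 1,
            emb_dim >= 1, conv_dim >= 1, lr > 0)
  structure(list(min_freq = min_freq, emb_dim = emb_dim, conv_dim = conv_dim,
                 kernel = kernel, epochs = as.integer(epochs),
                 threshold = threshold, lr = lr,
                 max_tokens = max_tokens, seed = as.integer(seed)),
            class = "coder_config")
}

#' Build a vocabulary from a training corpus
#'
#' Tokens with training frequency at least `min_freq`, in deterministic
#' (sorted) order, preceded by an unknown-token slot.
#'
#' @param corpus An [new_corpus()] tibble (its train split is used).
#' @param cfg A [coder_config()].
#' @return Character vector of vocabulary tokens; element 1 is `"<unk>"`.
#' @export
build_vocab <- function(corpus, cfg = coder_config()) {
  train <- corpus_split(corpus, "train")
  if (nrow(train) == 0L) stop("empty training split", call. = FALSE)
  toks <- unlist(lapply(train$text, preprocess_text,
                        max_tokens = cfg$max_tokens), use.names = FALSE)
  freq <- table(toks)
  keep <- sort(names(freq[freq >= cfg$min_freq]))
  c("<unk>", keep)
}

tokens_to_ids <- function(texts, vocab, max_tokens) {
  lapply(texts, function(tx) {
    toks <- preprocess_text(tx, max_tokens = max_tokens)
    ids <- match(toks, vocab)
    ids[is.na(ids)] <- 1L
    as.integer(ids)
  })
}

labels_to_ids <- function(label_sets, label_index) {
  lapply(label_sets, function(l) {
    ids <- match(l, label_index)
    as.integer(ids[!is.na(ids)])
  })
}

#' Train the reference multi-label coder
#'
#' Trains the convolutional per-label-attention coder for exactly
#' `cfg$epochs` epochs of per-document binary cross-entropy updates,
#' evaluating dev-set mean average precision after every epoch and
#' returning the parameters from the best epoch (earliest epoch wins ties).
#' The label space is indexed from the training split; dev-only labels are
#' ignored with a warning. Fully reproducible from `cfg$seed`.
#'
#' @param train,dev [new_corpus()] tibbles (or splits thereof).
#' @param cfg A [coder_config()].
#' @return An object of class `icd_coder` with elements `vocab`, `labels`,
#'   `params`, `dev_map` (per-epoch), `selected_epoch`, `config`.
#' @export
train_coder <- function(train, dev, cfg = coder_config()) {
  if (nrow(train) == 0L || nrow(dev) == 0L) {
    stop("train and dev splits must be non-empty", call. = FALSE)
  }
  vocab <- build_vocab(structure(train, class = class(train)), cfg)
  label_index <- sort(unique(unlist(train$labels, use.names = FALSE)))
  dev_only <- setdiff(unique(unlist(dev$labels, use.names = FALSE)), label_index)
  if (length(dev_only)) {
    warning(length(dev_only), " dev-only label(s) outside the model's ",
            "output space are ignored during training")
  }
  fit <- caml_fit(
    tokens_to_ids(train$text, vocab, cfg$max_tokens),
    labels_to_ids(train$labels, label_index),
    tokens_to_ids(dev$text, vocab, cfg$max_tokens),
    labels_to_ids(dev$labels, label_index),
    n_vocab = length(vocab), n_labels = length(label_index),
    emb_dim = cfg$emb_dim, conv_dim = cfg$conv_dim, kernel = cfg$kernel,
    epochs = cfg$epochs, lr = cfg$lr, seed = cfg$seed)
  structure(list(vocab = vocab, labels = label_index,
                 params = fit[c("E", "Wc", "bc", "U", "B", "b")],
                 dev_map = as.numeric(fit$dev_map),
                 selected_epoch = as.integer(fit$selected_epoch),
                 config = cfg),
            class = "icd_coder")
}

#' @export
print.icd_coder <- function(x, ...) {
  cat("<icd_coder> ", length(x$labels), " labels, vocab ", length(x$vocab),
      ", selected epoch ", x$selected_epoch, "/", x$config$epochs,
      " (dev mAP ", round(x$dev_map[x$selected_epoch], 4), ")\n", sep = "")
  invisible(x)
}

#' Score documents with a trained coder
#'
#' @param coder An `icd_coder`.
#' @param docs A corpus tibble (any split).
#' @return Numeric matrix of per-label probabilities, one row per document,
#'   columns named by label.
#' @export
score_documents <- function(coder, docs) {
  S <- caml_score(tokens_to_ids(docs$text, coder$vocab,
                                coder$config$max_tokens),
                  coder$params, coder$config$kernel)
  dimnames(S) <- list(docs$doc_id, coder$labels)
  S
}

#' Predict label sets
#'
#' Scores each document and thresholds: a label is predicted when its
#' probability is at least `threshold`. Prediction sets are monotone
#' non-increasing in the threshold.
#'
#' @param object An `icd_coder`.
#' @param docs A corpus tibble.
#' @param threshold Probability threshold; defaults to the trained config's.
#' @param ... Unused.
#' @return A list with `scores` (matrix) and `labels` (named list of
#'   predicted code vectors keyed by `doc_id`).
#' @export
predict.icd_coder <- function(object, docs, threshold = NULL, ...) {
  threshold <- threshold %||% object$config$threshold
  S <- score_documents(object, docs)
  sets <- lapply(seq_len(nrow(S)), function(i) {
    object$labels[S[i, ] >= threshold]
  })
  names(sets) <- docs$doc_id
  list(scores = S, labels = sets)
}

#' Mean average precision over labels
#'
#' Macro average, over labels with at least one gold-positive document, of
#' the average precision of the label's document ranking (documents sorted
#' by decreasing score; ties keep document order).
#'
#' @param scores Numeric matrix, documents x labels.
#' @param gold Logical (or 0/1) matrix of the same shape.
#' @return Mean average precision in `[0, 1]`.
#' @export
mean_average_precision <- function(scores, gold) {
  stopifnot(all(dim(scores) == dim(gold)))
  gold <- gold > 0
  has_pos <- colSums(gold) > 0
  if (!any(has_pos)) stop("mAP undefined: no label has a positive document",
                          call. = FALSE)
  aps <- vapply(which(has_pos), function(l) {
    ord <- order(-scores[, l])  # stable: ties keep document order
    hits <- cumsum(gold[ord, l])
    mean((hits / seq_along(ord))[gold[ord, l]])
  }, numeric(1))
  mean(aps)
}
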