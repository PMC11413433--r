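# Gold and predicted label sets are named lists: doc_id -> character vector
# of codes. All metrics are invariant to document and label order.

align_docs <- function(gold, pred) {
  stopifnot(is.list(gold), is.list(pred),
            !is.null(names(gold)), !is.null(names(pred)))
  if (!setequal(names(gold), names(pred))) {
    stop("gold and pred must cover the same documents", call. = FALSE)
  }
  ids <- names(gold)
  list(gold = gold[ids], pred = pred[ids], ids = ids)
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

label_counts <- function(gold, pred, codeset) {
  tp <- fp <- fn <- stats::setNames(numeric(length(codeset)), codeset)
  for (i in seq_along(gold)) {
    g <- intersect(gold[[i]], codeset)
    p <- intersect(pred[[i]], codeset)
    hit <- intersect(g, p)
    tp[hit] <- tp[hit] + 1
    fp[setdiff(p, g)] <- fp[setdiff(p, g)] + 1
    fn[setdiff(g, p)] <- fn[setdiff(g, p)] + 1
  }
  list(tp = tp, fp = fp, fn = fn)
}

#' Flat (leaf-only) micro and macro precision, recall, F1
#'
#' Counts are restricted to `codeset`. Micro metrics pool true/false
#' positives and false negatives over all labels; macro metrics average
#' per-label scores with equal weight. By the documented convention a
#' label's F1 is 0 when its precision and recall are both 0, and codeset
#' labels with neither gold nor predicted instances contribute zeros to the
#' macro average (set `drop_absent = TRUE` to exclude them).
#'
#' @param gold,pred Named lists: doc_id -> character vector of codes.
#' @param codeset Character vector of codes to evaluate over.
#' @param drop_absent Exclude labels with no gold and no predicted
#'   instances from the macro denominator.
#' @return A list of class `metrics_report`: `variant`, `micro`, `macro`
#'   (each `c(precision, recall, f1)`), and `n_labels`.
#' @export
flat_metrics <- function(gold, pred, codeset, drop_absent = FALSE) {
  stopifnot(length(codeset) >= 1)
  a <- align_docs(gold, pred)
  codeset <- unique(parse_code(codeset))
  cc <- label_counts(a$gold, a$pred, codeset)
  micro <- prf(sum(cc$tp), sum(cc$fp), sum(cc$fn))
  keep <- if (drop_absent) (cc$tp + cc$fp + cc$fn) > 0 else rep(TRUE, length(codeset))
  per_label <- vapply(which(keep), function(j) {
    prf(cc$tp[j], cc$fp[j], cc$fn[j])
  }, c(precision = 0, recall = 0, f1 = 0))
  macro <- if (length(per_label)) rowMeans(per_label) else
    c(precision = 0, recall = 0, f1 = 0)
  structure(list(variant = "leaf-only", micro = micro, macro = macro,
                 n_labels = sum(keep)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", x$variant, "\n", sep = "")
  m <- rbind(micro = x$micro, macro = x$macro)
  print(round(m, 4))
  invisible(x)
}

#' Extend a label set with ancestor nodes
#'
#' In set mode an ancestor is present (count 1) whenever at least one of
#' its descendant leaves is present; in counts mode each ancestor carries
#' the number of its descendant leaves present, so over- and
#' under-prediction within a family remains visible.
#'
#' @param labels Character vector of leaf codes (a set).
#' @param hierarchy An [code_hierarchy()] object.
#' @param mode `"set"` or `"counts"`.
#' @return Named integer vector: node id -> count.
#' @export
extend_with_ancestors <- function(labels, hierarchy, mode = c("set", "counts")) {
  mode <- match.arg(mode)
  labels <- unique(labels)
  if (length(labels) == 0L) return(stats::setNames(integer(0), character(0)))
  counts <- stats::setNames(rep(1L, length(labels)), labels)
  for (leaf in labels) {
    for (anc in ancestors_of(leaf, hierarchy)) {
      counts[anc] <- (if (anc %in% names(counts)) counts[[anc]] else 0L) + 1L
    }
  }
  if (mode == "set") counts[] <- 1L
  counts
}

#' Hierarchical micro metrics (set-based and count-preserving)
#'
#' Extends each document's gold and predicted sets with ancestor nodes
#' ([extend_with_ancestors()]), then per (document, node) takes
#' `TP = min(gold, pred)`, `FP = max(pred - gold, 0)`,
#' `FN = max(gold - pred, 0)` and micro-pools. The count-preserving variant
#' (CoPHE) penalizes over- and under-prediction within code families that
#' the set-based variant forgives; `variant = "leaf_only"` returns the flat
#' micro metrics over the hierarchy's leaves for side-by-side reporting.
#'
#' @param gold,pred Named lists: doc_id -> character vector of codes.
#' @param hierarchy An [code_hierarchy()] object.
#' @param variant `"set_based"`, `"cophe"`, or `"leaf_only"`.
#' @return A `metrics_report` (micro only for hierarchical variants).
#' @export
hierarchical_metrics <- function(gold, pred, hierarchy,
                                 variant = c("set_based", "cophe", "leaf_only")) {
  variant <- match.arg(variant)
  if (variant == "leaf_only") {
    out <- flat_metrics(gold, pred, hierarchy$leaves)
    out$variant <- "leaf_only"
    return(out)
  }
  mode <- if (variant == "cophe") "counts" else "set"
  a <- align_docs(gold, pred)
  tp <- fp <- fn <- 0
  for (i in seq_along(a$ids)) {
    gv <- extend_with_ancestors(a$gold[[i]], hierarchy, mode)
    pv <- extend_with_ancestors(a$pred[[i]], hierarchy, mode)
    nodes <- union(names(gv), names(pv))
    g <- ifelse(nodes %in% names(gv), gv[nodes], 0L)
    p <- ifelse(nodes %in% names(pv), pv[nodes], 0L)
    tp <- tp + sum(pmin(g, p))
    fp <- fp + sum(pmax(p - g, 0))
    fn <- fn + sum(pmax(g - p, 0))
  }
  structure(list(variant = variant, micro = prf(tp, fp, fn),
                 macro = NULL, n_labels = length(hierarchy$leaves)),
            class = "metrics_report")
}

#' Weak hierarchical confusion-matrix error rates
#'
#' Classifies every gold instance of a codeset label as a true positive
#' (the label was predicted), a within-family (IF) error (missed, but the
#' prediction set contains at least one false-positive label from the same
#' family), or an out-of-family (OOF) error (missed with no same-family
#' false positive available to match). Matching is weak: one false positive
#' can license any number of IF errors in its family. Per-label percentages
#' are taken over that label's gold instances and macro-averaged over
#' codeset labels with at least one gold instance.
#'
#' @param gold,pred Named lists: doc_id -> character vector of codes.
#' @param codeset Character vector of codes to analyse.
#' @param hierarchy An [code_hierarchy()] object (family heads are taken
#'   from the codes directly; the hierarchy fixes the leaf universe).
#' @return A list of class `whcm_report`: macro `oof`, `if_` and `tp`
#'   percentages (0-100), the per-label table, and `n_labels` used.
#' @export
whcm_rates <- function(gold, pred, codeset, hierarchy) {
  a <- align_docs(gold, pred)
  codeset <- unique(parse_code(codeset))
  stat <- matrix(0, nrow = length(codeset), ncol = 3,
                 dimnames = list(codeset, c("tp", "if_err", "oof_err")))
  for (i in seq_along(a$ids)) {
    g <- a$gold[[i]]
    p <- a$pred[[i]]
    fp_fams <- unique(family_of(setdiff(p, g)))
    for (lab in intersect(g, codeset)) {
      if (lab %in% p) {
        stat[lab, "tp"] <- stat[lab, "tp"] + 1
      } else if (family_of(lab) %in% fp_fams) {
        stat[lab, "if_err"] <- stat[lab, "if_err"] + 1
      } else {
        stat[lab, "oof_err"] <- stat[lab, "oof_err"] + 1
      }
    }
  }
  n_gold <- rowSums(stat)
  used <- n_gold > 0
  if (!all(used)) {
    message(sum(!used), " codeset label(s) without gold instances excluded ",
            "from the WHCM macro average")
  }
  pct <- stat[used, , drop = FALSE] / n_gold[used] * 100
  macro <- if (nrow(pct)) colMeans(pct) else c(tp = NA, if_err = NA, oof_err = NA)
  structure(list(oof = unname(macro["oof_err"]),
                 if_ = unname(macro["if_err"]),
                 tp = unname(macro["tp"]),
                 per_label = pct, n_labels = sum(used)),
            class = "whcm_report")
}

#' @export
print.whcm_report <- function(x, ...) {
  cat("<whcm_report> macro over ", x$n_labels, " labels: OOF ",
      round(x$oof, 2), "%, IF ", round(x$if_, 2), "%, TP ",
      round(x$tp, 2), "%\n", sep = "")
  invisible(x)
}

#' Predictions of a corpus's gold label sets
#'
#' Convenience accessor: the corpus's label sets as a named list keyed by
#' `doc_id`, the shape the evaluation functions consume.
#'
#' @param corpus An [new_corpus()] tibble.
#' @return Named list: doc_id -> character vector of codes.
#' @export
gold_labels <- function(corpus) {
  stats::setNames(corpus$labels, corpus$doc_id)
}
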