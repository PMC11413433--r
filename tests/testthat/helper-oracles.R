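# Brute-force enumeration oracles, written independently of the package's
# metric implementations: plain nested loops over documents, labels, and
# nodes, with no shared helper code.

oracle_family <- function(code) substr(code, 1, 3)

oracle_flat <- function(gold, pred, codeset) {
  ids <- names(gold)
  per <- list()
  TP <- FP <- FN <- 0
  for (lab in codeset) {
    tp <- fp <- fn <- 0
    for (id in ids) {
      g <- lab %in% gold[[id]]
      p <- lab %in% pred[[id]]
      if (g && p) tp <- tp + 1
      if (!g && p) fp <- fp + 1
      if (g && !p) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per[[lab]] <- c(prec, rec, f1)
    TP <- TP + tp; FP <- FP + fp; FN <- FN + fn
  }
  mp <- if (TP + FP > 0) TP / (TP + FP) else 0
  mr <- if (TP + FN > 0) TP / (TP + FN) else 0
  mf <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  macro <- colMeans(do.call(rbind, per))
  list(micro = c(mp, mr, mf), macro = macro)
}

# multiset extension with family ancestors, as a named count vector
oracle_extend <- function(labels, mode) {
  out <- list()
  for (lab in unique(labels)) out[[lab]] <- 1
  for (fam in unique(oracle_family(unique(labels)))) {
    n <- 0
    for (lab in unique(labels)) if (oracle_family(lab) == fam) n <- n + 1
    out[[fam]] <- if (mode == "set") 1 else n
  }
  unlist(out)
}

oracle_hier <- function(gold, pred, mode) {
  TP <- FP <- FN <- 0
  for (id in names(gold)) {
    g <- oracle_extend(gold[[id]], mode)
    p <- oracle_extend(pred[[id]], mode)
    for (node in union(names(g), names(p))) {
      gc <- if (node %in% names(g)) g[[node]] else 0
      pc <- if (node %in% names(p)) p[[node]] else 0
      TP <- TP + min(gc, pc)
      FP <- FP + max(pc - gc, 0)
      FN <- FN + max(gc - pc, 0)
    }
  }
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  rec <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

oracle_whcm <- function(gold, pred, codeset) {
  stats <- list()
  for (lab in codeset) stats[[lab]] <- c(tp = 0, if_err = 0, oof = 0)
  for (id in names(gold)) {
    fps <- setdiff(pred[[id]], gold[[id]])
    for (lab in intersect(gold[[id]], codeset)) {
      if (lab %in% pred[[id]]) {
        stats[[lab]]["tp"] <- stats[[lab]]["tp"] + 1
      } else {
        same_fam_fp <- FALSE
        for (f in fps) if (oracle_family(f) == oracle_family(lab)) same_fam_fp <- TRUE
        if (same_fam_fp) stats[[lab]]["if_err"] <- stats[[lab]]["if_err"] + 1
        else stats[[lab]]["oof"] <- stats[[lab]]["oof"] + 1
      }
    }
  }
  oofs <- ifs <- tps <- c()
  for (lab in codeset) {
    n <- sum(stats[[lab]])
    if (n == 0) next
    tps <- c(tps, stats[[lab]]["tp"] / n * 100)
    ifs <- c(ifs, stats[[lab]]["if_err"] / n * 100)
    oofs <- c(oofs, stats[[lab]]["oof"] / n * 100)
  }
  list(oof = mean(oofs), if_ = mean(ifs), tp = mean(tps), n_labels = length(oofs))
}

# random metric instance: <= 5 families x <= 4 leaves, <= 20 documents
random_instance <- function() {
  n_fam <- sample(1:5, 1)
  fams <- sprintf("%s%02d", LETTERS[seq_len(n_fam)], seq_len(n_fam))
  leaves <- unlist(lapply(fams, function(f) {
    paste0(f, ".", seq_len(sample(1:4, 1)) - 1)
  }))
  n_doc <- sample(1:20, 1)
  gold <- pred <- list()
  for (i in seq_len(n_doc)) {
    id <- paste0("d", i)
    gold[[id]] <- sample(leaves, sample(0:min(6, length(leaves)), 1))
    pred[[id]] <- sample(leaves, sample(0:min(6, length(leaves)), 1))
  }
  list(leaves = leaves, gold = gold, pred = pred)
}

# small deterministic 6-document corpus used across I/O tests
tiny_corpus <- function() {
  new_corpus(
    doc_id = sprintf("d%d", 1:6),
    text = c("chest pain and fever", "fever with cough",
             "fracture of the orbit", "migraine without aura",
             "anemia and fatigue", "routine follow up"),
    labels = list(c("R07.9", "R50.9"), c("R50.9", "R05"),
                  c("S02.1"), c("G43.0"), c("D64.9"), c("Z00.0")),
    split = c("train", "train", "train", "dev", "test", "test"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
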