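#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement among a fixed number of raters assigning each
#' item to one of a set of categories: `kappa = (Pbar - Pe) / (1 - Pe)`,
#' where `Pbar` is the mean observed pairwise agreement per item and `Pe`
#' the agreement expected from the marginal category proportions. Ordinal
#' scores are treated as nominal categories (the classical formulation);
#' an optional linear-weighted variant credits near-misses.
#'
#' @param assignments Matrix (items x raters) of category values, or a
#'   data frame coercible to one. Every item must have the same number of
#'   raters and no missing cells.
#' @param categories Ordered vector of all possible categories; defaults to
#'   the sorted unique values observed.
#' @param weighted If `TRUE`, use linear disagreement weights over the
#'   ordered categories instead of all-or-nothing agreement.
#' @return Kappa (a real number, at most 1).
#' @export
fleiss_kappa <- function(assignments, categories = NULL, weighted = FALSE) {
  m <- as.matrix(assignments)
  if (anyNA(m)) stop("assignment matrix has missing cells", call. = FALSE)
  n_items <- nrow(m)
  n_raters <- ncol(m)
  if (n_items < 2 || n_raters < 2) {
    stop("need at least 2 items and 2 raters", call. = FALSE)
  }
  categories <- categories %||% sort(unique(as.vector(m)))
  if (!all(as.vector(m) %in% categories)) {
    stop("assignments outside the category set", call. = FALSE)
  }
  # n_ij: raters assigning item i to category j
  nij <- do.call(rbind, lapply(seq_len(n_items), function(i) {
    tabulate(match(m[i, ], categories), nbins = length(categories))
  }))
  pj <- colSums(nij) / (n_items * n_raters)
  if (!weighted) {
    Pi <- (rowSums(nij^2) - n_raters) / (n_raters * (n_raters - 1))
    Pbar <- mean(Pi)
    Pe <- sum(pj^2)
  } else {
    q <- length(categories)
    W <- 1 - abs(outer(seq_len(q), seq_len(q), "-")) / (q - 1)
    Pi <- (rowSums((nij %*% W) * nij) - n_raters) /
      (n_raters * (n_raters - 1))
    Pbar <- mean(Pi)
    Pe <- sum(W * outer(pj, pj))
  }
  if (isTRUE(all.equal(Pe, 1))) {
    stop("degenerate agreement: all raters always use one category",
         call. = FALSE)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Read a rating table
#'
#' CSV with columns `item_id,item_class,rater_id,metric,score`; `item_class`
#' is `"real"` or `"synthetic"`, scores are integers in 1..5.
#'
#' @param path CSV path.
#' @return A tibble of class `rating_table`.
#' @export
read_rating_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_rating_table(df)
}

#' Validate a rating table
#'
#' @param df Data frame with columns `item_id`, `item_class`, `rater_id`,
#'   `metric`, `score`.
#' @return A tibble of class `rating_table`.
#' @export
as_rating_table <- function(df) {
  need <- c("item_id", "item_class", "rater_id", "metric", "score")
  if (!all(need %in% names(df))) {
    stop("rating table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$score %in% 1:5)) stop("scores must be integers in 1..5",
                                    call. = FALSE)
  if (!all(df$item_class %in% c("real", "synthetic"))) {
    stop("item_class must be 'real' or 'synthetic'", call. = FALSE)
  }
  counts <- table(df$metric, df$item_id)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("incomplete rating table: unequal raters per (metric, item)",
         call. = FALSE)
  }
  structure(tibble::as_tibble(df), class = c("rating_table",
                                             class(tibble::tibble())))
}

#' Agreement report: kappa and mean score per metric and item class
#'
#' For each rating metric, separately for real and synthetic items,
#' computes Fleiss' kappa over the five score categories and the grand
#' mean score. A metric whose kappa is degenerate (all raters always in
#' one category) is reported with `kappa = NA` and flagged, without
#' aborting the other metrics.
#'
#' @param table A `rating_table` (see [as_rating_table()]).
#' @param weighted Use the linear-weighted kappa variant.
#' @return A tibble with columns `metric`, `item_class`, `kappa`, `mean`,
#'   `degenerate`.
#' @export
agreement_report <- function(table, weighted = FALSE) {
  table <- as_rating_table(table)
  out <- list()
  for (metric in sort(unique(table$metric))) {
    for (cls in intersect(c("real", "synthetic"), unique(table$item_class))) {
      sub <- table[table$metric == metric & table$item_class == cls, ]
      wide <- stats::xtabs(score ~ item_id + rater_id, data = sub)
      k <- tryCatch(fleiss_kappa(wide, categories = 1:5, weighted = weighted),
                    error = function(e) NA_real_)
      out[[length(out) + 1L]] <- tibble::tibble(
        metric = metric, item_class = cls, kappa = k,
        mean = mean(sub$score), degenerate = is.na(k))
    }
  }
  dplyr::bind_rows(out)
}
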