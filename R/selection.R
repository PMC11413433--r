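#' Selection configuration
#'
#' Parameters for identifying low-resource generation targets. Few-shot
#' candidates are codes appearing up to `few_shot_max` times in training
#' (default 5) and present in all three splits. A family is retained when it
#' has at least one frequent member (training population strictly greater
#' than `frequent_threshold`, default 100) and at least one zero-shot member
#' (absent from training, present in test). `n_families` families are then
#' sampled for generation, and every family member with training population
#' strictly below `generation_pop_cap` becomes a generation code.
#'
#' @param few_shot_max Maximum training population of a few-shot candidate.
#' @param frequent_threshold Training population a frequent member must
#'   strictly exceed.
#' @param n_families Number of families to sample for generation.
#' @param generation_pop_cap Generation codes must have training population
#'   strictly below this cap.
#' @param seed Integer seed for family sampling.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(few_shot_max = 5, frequent_threshold = 100,
                             n_families = 10, generation_pop_cap = 100,
                             seed = 1L) {
  stopifnot(few_shot_max >= 1, frequent_threshold > few_shot_max,
            n_families >= 1, generation_pop_cap >= 1)
  structure(list(few_shot_max = few_shot_max,
                 frequent_threshold = frequent_threshold,
                 n_families = n_families,
                 generation_pop_cap = generation_pop_cap,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Few-shot codes common to all splits
#'
#' Codes with training population between 1 and `cfg$few_shot_max` that also
#' appear at least once in both the dev and test splits.
#'
#' @param pop A [label_populations()] tibble.
#' @param cfg A [selection_config()].
#' @return Character vector of codes (possibly empty).
#' @export
few_shot_common_codes <- function(pop, cfg = selection_config()) {
  keep <- pop$train >= 1 & pop$train <= cfg$few_shot_max &
    pop$dev >= 1 & pop$test >= 1
  sort(pop$code[keep])
}

#' Retain families with a frequent and a zero-shot member
#'
#' Among the families of the candidate codes, keeps those whose full
#' membership (all codes observed anywhere in the corpus) contains at least
#' one code with training population strictly above `cfg$frequent_threshold`
#' and at least one zero-shot code (training population 0, test population
#' at least 1).
#'
#' @param candidates Character vector of candidate codes.
#' @param pop A [label_populations()] tibble over the whole corpus.
#' @param cfg A [selection_config()].
#' @return Character vector of retained family heads.
#' @export
retain_families <- function(candidates, pop, cfg = selection_config()) {
  if (length(candidates) == 0L) stop("no candidate codes", call. = FALSE)
  fams <- unique(family_of(candidates))
  pop_fam <- family_of(pop$code)
  keep <- vapply(fams, function(f) {
    members <- pop[pop_fam == f, , drop = FALSE]
    any(members$train > cfg$frequent_threshold) &&
      any(members$train == 0 & members$test >= 1)
  }, logical(1))
  sort(fams[keep])
}

#' Randomly choose generation families
#'
#' Uniform sample without replacement of `cfg$n_families` family heads,
#' reproducible from `cfg$seed`.
#'
#' @param retained Character vector of retained family heads.
#' @param cfg A [selection_config()].
#' @return Character vector of chosen family heads.
#' @export
choose_generation_families <- function(retained, cfg = selection_config()) {
  if (length(retained) < cfg$n_families) {
    stop("insufficient families: ", length(retained), " retained, ",
         cfg$n_families, " requested", call. = FALSE)
  }
  if (length(retained) == cfg$n_families) return(sort(retained))
  sort(with_seed(substream(cfg$seed, "choose_families"),
                 sample(retained, cfg$n_families)))
}

#' Enumerate generation codes within the chosen families
#'
#' All codes whose family is among `chosen` and whose training population is
#' strictly below `cfg$generation_pop_cap`, partitioned into few-shot codes
#' (training population at least 1) and zero-shot codes (training population
#' 0, test population at least 1). Codes absent from both training and test
#' are not generation targets.
#'
#' @param chosen Character vector of chosen family heads.
#' @param pop A [label_populations()] tibble.
#' @param cfg A [selection_config()].
#' @return A tibble with columns `code`, `family`, `train`, `dev`, `test`,
#'   and `stratum` (`"few_shot"` or `"zero_shot"`).
#' @export
generation_codes <- function(chosen, pop, cfg = selection_config()) {
  stopifnot(length(chosen) >= 1)
  fam <- family_of(pop$code)
  few <- fam %in% chosen & pop$train >= 1 & pop$train < cfg$generation_pop_cap
  zero <- fam %in% chosen & pop$train == 0 & pop$test >= 1
  out <- pop[few | zero, , drop = FALSE]
  out$family <- family_of(out$code)
  out$stratum <- ifelse(out$train == 0, "zero_shot", "few_shot")
  out <- out[order(out$code), c("code", "family", "train", "dev", "test", "stratum")]
  tibble::as_tibble(out)
}

#' Run the full label-selection stage
#'
#' Chains [few_shot_common_codes()], [retain_families()],
#' [choose_generation_families()], and [generation_codes()]. The selection
#' is a pure function of the population table and the configuration.
#'
#' @param pop A [label_populations()] tibble.
#' @param cfg A [selection_config()].
#' @return A list of class `selection_result` with elements
#'   `few_shot_common`, `retained_families`, `chosen_families`, and
#'   `generation_codes` (a tibble, see [generation_codes()]).
#' @export
select_generation_targets <- function(pop, cfg = selection_config()) {
  few <- few_shot_common_codes(pop, cfg)
  retained <- retain_families(few, pop, cfg)
  chosen <- choose_generation_families(retained, cfg)
  gen <- generation_codes(chosen, pop, cfg)
  structure(list(few_shot_common = few,
                 retained_families = retained,
                 chosen_families = chosen,
                 generation_codes = gen,
                 config = cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n",
      "  few-shot candidates common to all splits: ", length(x$few_shot_common), "\n",
      "  retained families: ", length(x$retained_families), "\n",
      "  chosen families:   ", paste(x$chosen_families, collapse = ", "), "\n",
      "  generation codes:  ", nrow(x$generation_codes), " (",
      sum(x$generation_codes$stratum == "few_shot"), " few-shot, ",
      sum(x$generation_codes$stratum == "zero_shot"), " zero-shot)\n", sep = "")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param selection A `selection_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(list(
    few_shot_common = selection$few_shot_common,
    retained_families = selection$retained_families,
    chosen_families = selection$chosen_families,
    few_shot_generation = selection$generation_codes$code[
      selection$generation_codes$stratum == "few_shot"],
    zero_shot_generation = selection$generation_codes$code[
      selection$generation_codes$stratum == "zero_shot"]),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
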