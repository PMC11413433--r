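# Code surface pattern. ICD-10-CM diagnosis codes are a letter, a digit,
# an alphanumeric, then an optional dot and up to four alphanumerics
# (S02.63XA, E10, D64.9). Requiring the digit in second position keeps the
# scrubber from eating ordinary capitalized words.
code_rx <- "[A-Za-z][0-9][0-9A-Za-z](\\.[0-9A-Za-z]{1,4}|[0-9A-Za-z]{0,4})"

# Specific concepts substituted for the umbrella qualifier "Other" and a
# few stock phrases used by the built-in template generator.
.other_substitutes <- c("refractory", "focal", "nodular", "intermittent",
                        "progressive", "localized", "relapsing")

.filler_sentences <- c(
  "Vital signs remained stable throughout the admission.",
  "The patient tolerated the treatment course well.",
  "Laboratory investigations were reviewed daily by the ward team.",
  "Follow up was arranged with the outpatient clinic.",
  "Medication reconciliation was completed prior to discharge.",
  "The patient was counselled on warning symptoms requiring urgent review.",
  "Physiotherapy assessed the patient and recommended home exercises.",
  "Dietary advice was provided by the nutrition service.",
  "Nursing staff monitored the patient overnight without incident.",
  "The multidisciplinary team agreed the patient was medically fit for discharge.")

#' Render a generation prompt for a silver record
#'
#' Produces the deterministic prompt text handed to a document generator:
#' one `CODE: Description` line per label in the record, followed by the
#' eight constraint blocks that govern generation — a 4000-word cap,
#' inclusion of social and family history, anonymization of personal and
#' location data, no explicit code mentions in the main text, concrete
#' numeric values rather than ranges, a specific concept in place of the
#' umbrella term "other", omission of the keyword "unspecified", and a
#' trailing enumerated diagnoses list with codes in square brackets.
#'
#' @param record A silver record (see [build_silver_set()]).
#' @param code_table Named character vector of descriptions keyed by code.
#' @return A single prompt string.
#' @export
render_prompt <- function(record, code_table) {
  missing <- setdiff(record$labels, names(code_table))
  if (length(missing)) {
    stop("no description for code(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  label_lines <- paste0(record$labels, ": ", code_table[record$labels])
  constraints <- c(
    "- Length of up to 4000 words.",
    "- Include a social history and a family history section.",
    "- Anonymize all personal and location data; keep numeric clinical values.",
    "- Do not mention any ICD code explicitly within the main text.",
    "- Prefer clear concrete numeric values over ranges.",
    "- For conditions described with the umbrella term \"other\", name a specific concept.",
    "- Omit the keyword \"unspecified\"; phrase the condition naturally.",
    "- End with the discharge diagnoses as a numbered list, each followed by its code in square brackets.")
  paste0(
    "Write a discharge summary for a patient with the following conditions and procedures:\n",
    paste(label_lines, collapse = "\n"),
    "\n\nConstraints:\n", paste(constraints, collapse = "\n"), "\n")
}

# 31-bit FNV-style hash of a string, for deriving per-record generator seeds.
hash_string <- function(s) {
  h <- 2166136
  for (b in utf8ToInt(s)) h <- (h * 16777 + b) %% 2147483647
  as.integer(h)
}

paraphrase_description <- function(desc) {
  d <- gsub(",?\\s*[Uu]nspecified\\s*,?", " ", desc)
  d <- gsub("\\s+", " ", trimws(d))
  d <- gsub("\\s+,", ",", d)
  if (grepl("^Other\\b", d, ignore.case = TRUE)) {
    sub_word <- .other_substitutes[sample.int(length(.other_substitutes), 1L)]
    d <- sub("^[Oo]ther\\b", sub_word, d)
  }
  d <- gsub("\\bother\\b", "specific", d)
  substr(d, 1, 1) <- tolower(substr(d, 1, 1))
  d
}

#' Built-in deterministic template generator
#'
#' A self-contained, seed-deterministic document generator that plays the
#' role of the external language model in the generation stage. It renders a
#' sectioned discharge summary (history of present illness, hospital course,
#' social history, family history) mentioning every label's description in
#' paraphrased form — the keyword "unspecified" is dropped, "other"-umbrella
#' descriptions are replaced by a concrete qualifier, and numeric
#' placeholders become concrete values — and closes with a numbered
#' discharge-diagnoses list carrying each code in square brackets. No code
#' token appears outside those brackets. At temperature 0 the output is a
#' pure function of the record; at higher temperatures it varies with
#' `seed` while keeping the trailing code list fixed.
#'
#' @param record A silver record.
#' @param code_table Named character vector of descriptions keyed by code.
#' @param temperature Generation temperature in `[0, 1]`.
#' @param seed Integer seed (only consulted when `temperature > 0`).
#' @return A list of class `raw_document` with fields `text`,
#'   `requested_labels`, `generator_name`, `seed`, `temperature`.
#' @export
mock_llm_generate <- function(record, code_table, temperature = 0, seed = 1L) {
  missing <- setdiff(record$labels, names(code_table))
  if (length(missing)) {
    stop("no description for code(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(record$source_doc_id, record$target_code,
               paste(record$labels, collapse = ","), record$clone_index,
               sep = "#")
  gen_seed <- if (temperature > 0) {
    substream(hash_string(key), paste0("t", seed))
  } else {
    hash_string(key)
  }
  labels <- sort(record$labels)
  with_seed(gen_seed, {
    phrases <- vapply(code_table[labels], paraphrase_description, character(1))
    days <- sample(2:14, 1L)
    age <- sample(25:90, 1L)
    hpi <- paste0(
      "History of Present Illness:\nThe patient is a ", age,
      " year old individual admitted after symptoms persisting for ", days,
      " days. Assessment on admission identified ",
      paste(phrases, collapse = "; "), ".")
    course_lines <- vapply(phrases, function(p) {
      paste0("Management of the ", p, " was undertaken with good effect.")
    }, character(1))
    filler <- .filler_sentences[sample.int(length(.filler_sentences),
                                           sample(3:6, 1L))]
    # supporting findings drawn from the same background working
    # vocabulary as the rest of the corpus (see noise_word)
    findings <- vapply(sample.int(500L, sample(10:25, 1L), replace = TRUE),
                       noise_word, character(1))
    course <- paste0("Hospital Course:\n",
                     paste(c(course_lines, filler), collapse = " "),
                     " Supporting findings during the stay included ",
                     paste(findings, collapse = ", "), ".")
    social <- paste0("Social History:\nThe patient lives independently and ",
                     sample(c("does not smoke", "is a former smoker",
                              "drinks alcohol occasionally"), 1L), ".")
    family <- paste0("Family History:\n",
                     sample(c("No relevant family history was reported.",
                              "A first degree relative has a similar condition.",
                              "Family history is notable for cardiovascular disease."), 1L))
    dx <- paste0("Discharge Diagnoses:\n",
                 paste(sprintf("%d. %s [%s]", seq_along(labels),
                               phrases, labels), collapse = "\n"))
    text <- paste(hpi, course, social, family, dx, sep = "\n\n")
    text
  }) -> text
  structure(list(text = text, requested_labels = labels,
                 generator_name = "mock_llm", seed = as.integer(seed),
                 temperature = temperature),
            class = "raw_document")
}

#' Generate a document for a silver record
#'
#' Dispatches to a pluggable generator function with the record's assigned
#' temperature. The built-in [mock_llm_generate()] is the default; an
#' adapter for a hosted model can be supplied with the same signature
#' `(record, code_table, temperature, seed)` returning a `raw_document`.
#'
#' @param record A silver record (with `temperature` set).
#' @param code_table Named character vector of descriptions keyed by code.
#' @param generator Generator function; defaults to [mock_llm_generate()].
#' @param seed Integer seed forwarded to the generator.
#' @return A `raw_document`.
#' @export
generate_document <- function(record, code_table,
                              generator = mock_llm_generate, seed = 1L) {
  out <- tryCatch(
    generator(record, code_table, temperature = record$temperature %||% 0,
              seed = seed),
    error = function(e) {
      stop("generator failure for record (source ",
           sQuote(record$source_doc_id), ", target ",
           sQuote(record$target_code), "): ", conditionMessage(e),
           call. = FALSE)
    })
  nw <- length(strsplit(out$text, "\\s+")[[1]])
  if (nw > 4000) stop("generated document exceeds the 4000-word cap",
                      call. = FALSE)
  out
}

#' Extract assigned codes from a generated document
#'
#' Finds the trailing discharge-diagnoses section and extracts all
#' square-bracketed code tokens with a regular expression; the body is the
#' document text with the code brackets removed. Bracketed codes appearing
#' outside the trailing section are not extracted (a warning notes them).
#'
#' @param raw A `raw_document`, or a plain string of document text.
#' @return A list with `codes` (character vector of parsed codes, possibly
#'   empty) and `body` (text with code brackets removed).
#' @export
extract_assigned_codes <- function(raw) {
  text <- if (inherits(raw, "raw_document")) raw$text else raw
  stopifnot(is.character(text), length(text) == 1L)
  bracket_rx <- paste0("\\[(", code_rx, ")\\]")
  pos <- regexpr("Discharge Diagnoses:", text, fixed = TRUE)
  if (pos == -1L) {
    if (grepl(bracket_rx, text)) {
      warning("bracketed codes found outside a discharge-diagnoses section")
    } else {
      warning("no bracketed codes found in document")
    }
    return(list(codes = character(0), body = text))
  }
  tail_txt <- substr(text, pos, nchar(text))
  head_txt <- substr(text, 1L, pos - 1L)
  if (grepl(bracket_rx, head_txt)) {
    warning("stray bracketed codes before the discharge-diagnoses section")
  }
  m <- gregexpr(bracket_rx, tail_txt)[[1]]
  codes <- if (m[1] == -1L) character(0) else {
    toks <- regmatches(tail_txt, gregexpr(bracket_rx, tail_txt))[[1]]
    parse_code(gsub("^\\[|\\]$", "", toks))
  }
  if (length(codes) == 0L) warning("no bracketed codes found in document")
  body <- paste0(head_txt, gsub(bracket_rx, "", tail_txt))
  body <- gsub("[ \t]+", " ", body)
  body <- gsub(" +\n", "\n", body)
  list(codes = sort(unique(codes)), body = body)
}

#' Scrub code mentions from text
#'
#' Removes every substring matching the code surface pattern, bracketed or
#' bare, and normalizes the surrounding whitespace. Idempotent.
#'
#' @param text Character vector.
#' @return Character vector with code mentions removed.
#' @export
scrub_codes <- function(text) {
  out <- gsub(paste0("\\[?(?<![0-9A-Za-z.])", code_rx,
                     "(?![0-9A-Za-z.])\\]?"), " ", text, perl = TRUE)
  out <- gsub("[ \t]+", " ", out)
  out <- gsub(" +\n", "\n", out)
  trimws(out)
}

#' Parse a coding-task response
#'
#' Structured-first parsing of a model response to an ICD-coding request:
#' if the response parses as a JSON array of objects with keys `diagnosis`
#' and `icd_code`, pairs are extracted directly; otherwise a regular
#' expression fallback scans the raw text for diagnosis/code pairs.
#' Duplicate codes keep the first diagnosis text. Unparseable responses
#' yield an empty pair list with `mode = "none"`.
#'
#' @param resp A single response string.
#' @return A list of class `coding_response` with `pairs` (tibble with
#'   columns `diagnosis`, `icd_code`) and `mode` (`"structured"`,
#'   `"fallback"`, or `"none"`).
#' @export
parse_coding_response <- function(resp) {
  stopifnot(is.character(resp), length(resp) == 1L)
  structured <- tryCatch({
    x <- jsonlite::fromJSON(resp, simplifyDataFrame = TRUE)
    if (is.data.frame(x) && all(c("diagnosis", "icd_code") %in% names(x)) &&
        nrow(x) > 0) {
      tibble::tibble(diagnosis = as.character(x$diagnosis),
                     icd_code = parse_code(as.character(x$icd_code)))
    } else NULL
  }, error = function(e) NULL)
  if (!is.null(structured)) {
    pairs <- structured[!duplicated(structured$icd_code), , drop = FALSE]
    return(structure(list(pairs = pairs, mode = "structured"),
                     class = "coding_response"))
  }
  pair_rx <- paste0(
    "[\"']?diagnosis[\"']?\\s*[:=]\\s*[\"']?([^\"'\\n,;]+?)[\"']?\\s*[,;]?\\s*",
    "[\"']?icd[_ ]?code[\"']?\\s*[:=]\\s*[\"']?(", code_rx, ")[\"']?")
  m <- gregexpr(pair_rx, resp, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] != -1L) {
    starts <- attr(m, "capture.start")
    lens <- attr(m, "capture.length")
    dg <- trimws(substring(resp, starts[, 1], starts[, 1] + lens[, 1] - 1))
    cd <- substring(resp, starts[, 2], starts[, 2] + lens[, 2] - 1)
    pairs <- tibble::tibble(diagnosis = dg, icd_code = parse_code(cd))
    pairs <- pairs[!duplicated(pairs$icd_code), , drop = FALSE]
    return(structure(list(pairs = pairs, mode = "fallback"),
                     class = "coding_response"))
  }
  structure(list(pairs = tibble::tibble(diagnosis = character(0),
                                        icd_code = character(0)),
                 mode = "none"),
            class = "coding_response")
}
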