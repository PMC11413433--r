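mini_record <- function(labels = c("D64.9", "G43.0"), target = labels[1],
                        temperature = 0, clone_index = 0L) {
  list(source_doc_id = "src-1", target_code = target,
       labels = sort(labels), is_zero_shot = FALSE,
       temperature = temperature, clone_index = clone_index)
}

mini_table <- c(D64.9 = "Anemia, unspecified",
                G43.0 = "Migraine without aura",
                K21.9 = "Other gastro-esophageal reflux disease")

test_that("render_prompt lists labels with descriptions plus all constraints", {
  r <- mini_record()
  p <- render_prompt(r, mini_table)
  expect_match(p, "D64.9: Anemia, unspecified", fixed = TRUE)
  expect_match(p, "G43.0: Migraine without aura", fixed = TRUE)
  for (needle in c("4000 words", "social history", "family history",
                   "Anonymize", "Do not mention any ICD code",
                   "numeric values", "umbrella term", "unspecified",
                   "square brackets")) {
    expect_match(p, needle, fixed = TRUE)
  }
  expect_identical(p, render_prompt(r, mini_table))
  expect_error(render_prompt(mini_record(c("D64.9", "Q99.9")), mini_table),
               "Q99.9")
})

test_that("the built-in generator honors the phrasing constraints", {
  r <- mini_record(c("D64.9", "K21.9"))
  doc <- mock_llm_generate(r, mini_table)
  body <- sub("Discharge Diagnoses:.*$", "", doc$text)
  expect_match(tolower(body), "anemia")
  expect_no_match(body, "[Uu]nspecified")
  expect_no_match(body, "\\bother\\b", ignore.case = TRUE)
  # no code token outside the trailing bracket list
  expect_no_match(gsub("\\[[^]]*\\]", "", doc$text),
                  "[A-Za-z][0-9][0-9A-Za-z]\\.")
  # concrete numerics are present
  expect_match(doc$text, "[0-9]+ days")
})

test_that("temperature-0 generation is deterministic; 0.1 varies with seed", {
  r0 <- mini_record(temperature = 0)
  a <- generate_document(r0, mini_table, seed = 1)
  b <- generate_document(r0, mini_table, seed = 2)
  expect_identical(a$text, b$text)
  r1 <- mini_record(temperature = 0.1)
  c1 <- generate_document(r1, mini_table, seed = 1)
  c2 <- generate_document(r1, mini_table, seed = 2)
  expect_false(identical(c1$text, c2$text))
  expect_identical(extract_assigned_codes(c1)$codes,
                   extract_assigned_codes(c2)$codes)
  # word cap
  expect_lte(length(strsplit(a$text, "\\s+")[[1]]), 4000)
})

test_that("extract_assigned_codes reads the trailing diagnoses section", {
  txt <- paste0("The fracture healed.\n\nDischarge Diagnoses:\n",
                "1. Type 1 diabetes with nephropathy [E10.21]")
  out <- extract_assigned_codes(txt)
  expect_equal(out$codes, "E10.21")
  expect_no_match(out$body, "\\[E10.21\\]")
  expect_warning(out2 <- extract_assigned_codes("no codes here at all"),
                 "no bracketed codes")
  expect_length(out2$codes, 0)
  expect_equal(out2$body, "no codes here at all")
  # stray brackets before the section are noted, not extracted
  expect_warning(
    out3 <- extract_assigned_codes(
      paste0("Noted [K21.9] early.\n\nDischarge Diagnoses:\n1. x [D64.9]")),
    "stray")
  expect_equal(out3$codes, "D64.9")
})

test_that("docgen round trip recovers the requested label sets", {
  space <- make_code_space(code_space_config(n_families = 8, n_background = 10))
  tbl <- space$code_table
  set.seed(31)
  codes <- names(tbl)
  for (i in 1:200) {
    labs <- sample(codes, sample(1:8, 1))
    r <- mini_record(labs, temperature = sample(c(0, 0.1), 1),
                     clone_index = i)
    doc <- generate_document(r, tbl, seed = i)
    ex <- extract_assigned_codes(doc)
    expect_identical(ex$codes, sort(unique(labs)))
    scrubbed <- scrub_codes(ex$body)
    expect_no_match(scrubbed,
                    "(?<![0-9A-Za-z.])[A-Za-z][0-9][0-9A-Za-z](\\.[0-9A-Za-z]{1,4})?(?![0-9A-Za-z.])",
                    perl = TRUE)
  }
})

test_that("scrub_codes removes bare and bracketed codes and is idempotent", {
  expect_equal(scrub_codes("fracture [S02.63XA] healed"), "fracture healed")
  expect_equal(scrub_codes("E10 and G43.909 noted"), "and noted")
  s <- scrub_codes("a [D64.9] b C03.1 c")
  expect_identical(scrub_codes(s), s)
  # ordinary words and decimals survive
  expect_equal(scrub_codes("THE dose was 1.5 mg"), "THE dose was 1.5 mg")
})

test_that("coding responses parse structured-first with pattern fallback", {
  ok <- '[{"diagnosis":"anemia","icd_code":"D64.9"}]'
  r <- parse_coding_response(ok)
  expect_equal(r$mode, "structured")
  expect_equal(r$pairs$diagnosis, "anemia")
  expect_equal(r$pairs$icd_code, "D64.9")
  mal <- "diagnosis: anemia icd_code: D64.9, diagnosis: migraine icd_code: G43.909"
  r2 <- parse_coding_response(mal)
  expect_equal(r2$mode, "fallback")
  expect_equal(nrow(r2$pairs), 2)
  expect_setequal(r2$pairs$icd_code, c("D64.9", "G43.909"))
  r3 <- parse_coding_response("I cannot code this.")
  expect_equal(r3$mode, "none")
  expect_equal(nrow(r3$pairs), 0)
  # duplicate codes keep the first diagnosis text
  dup <- '[{"diagnosis":"first","icd_code":"D64.9"},{"diagnosis":"second","icd_code":"D64.9"}]'
  r4 <- parse_coding_response(dup)
  expect_equal(r4$pairs$diagnosis, "first")
})

test_that("ten malformed response variants all parse via the fallback", {
  variants <- c(
    'diagnosis: anemia icd_code: D64.9',
    '"diagnosis": "anemia", "icd_code": "D64.9"',
    'Diagnosis: anemia ICD_CODE: D64.9',
    'diagnosis = anemia icd_code = D64.9',
    '{diagnosis: anemia, icd_code: D64.9',
    'diagnosis: anemia; icd_code: D64.9',
    "diagnosis: 'anemia' icd_code: 'D64.9'",
    'diagnosis: anemia icd code: D64.9',
    'text before diagnosis: anemia icd_code: D64.9 text after',
    'diagnosis:anemia icd_code:D64.9')
  for (v in variants) {
    r <- parse_coding_response(v)
    expect_equal(r$mode, "fallback", label = v)
    expect_equal(r$pairs$icd_code, "D64.9")
  }
})
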