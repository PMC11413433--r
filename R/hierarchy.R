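#' Parse and normalize an ICD-10-style code
#'
#' Codes are uppercased, trimmed, and validated against the ICD-10-CM/PCS
#' surface grammar used throughout the package: a leading letter, two further
#' alphanumeric characters forming the 3-character family head, then an
#' optional dot followed by up to four alphanumeric subcategory characters.
#' Seven-character procedure-style codes without a dot are accepted by the
#' same head-of-3 rule. A trailing dot with no subcategory is dropped.
#'
#' @param text Character vector of raw code tokens (e.g. `"S02.63XA"`, `"e10"`).
#' @return Character vector of normalized codes, same length as `text`.
#' @examples
#' parse_code("e10")        # "E10"
#' parse_code("S02.63XA")   # unchanged
#' @export
parse_code <- function(text) {
  if (length(text) == 0L) return(character(0))
  stopifnot(is.character(text))
  x <- toupper(trimws(text))
  x <- sub("\\.$", "", x)
  bad <- !grepl("^[A-Z][0-9A-Z]{2}(\\.[0-9A-Z]{1,4}|[0-9A-Z]{0,4})$", x)
  if (any(bad)) {
    stop("malformed code(s): ", paste(sQuote(text[bad]), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Family head of a code
#'
#' The code family is identified by the head of the code: its first three
#' characters (e.g. all of `S02.*` belong to family `"S02"`).
#'
#' @param code Character vector of codes (normalized via [parse_code()]).
#' @return Character vector of 3-character family identifiers.
#' @examples
#' family_of("D64.9")     # "D64"
#' family_of("T82.7XXA")  # "T82"
#' @export
family_of <- function(code) {
  substr(parse_code(code), 1L, 3L)
}

#' Siblings of a code within a codeset
#'
#' All members of `codeset` sharing `code`'s family head, excluding `code`
#' itself.
#'
#' @param code A single code.
#' @param codeset Character vector of codes to search.
#' @return Character vector of sibling codes (possibly empty).
#' @export
siblings_of <- function(code, codeset) {
  code <- parse_code(code)
  stopifnot(length(code) == 1L)
  codeset <- unique(parse_code(codeset))
  setdiff(codeset[family_of(codeset) == family_of(code)], code)
}

#' Construct a code hierarchy
#'
#' A hierarchy maps leaf codes to their ancestor chain, used when extending
#' gold and predicted label sets with ancestor nodes for hierarchical
#' evaluation. The default depth mode is family-only: each leaf's single
#' ancestor is its 3-character family head. A multi-level hierarchy (e.g.
#' with an ICD block layer above families) can be supplied as an explicit
#' parent map.
#'
#' @param leaves Character vector of leaf codes.
#' @param parents Optional named character vector mapping node id ->
#'   parent node id for multi-level hierarchies. Leaves without an entry
#'   default to their family head; family heads without an entry are roots.
#' @return An object of class `icd_hierarchy` with elements `leaves`,
#'   `parent` (named character vector; `NA` marks a root), and `depth_mode`.
#' @examples
#' h <- code_hierarchy(c("E10.21", "E10.9", "G43.0"))
#' ancestors_of("E10.21", h)  # "E10"
#' @export
code_hierarchy <- function(leaves, parents = NULL) {
  leaves <- unique(parse_code(leaves))
  parent <- stats::setNames(family_of(leaves), leaves)
  fams <- unique(family_of(leaves))
  parent <- c(parent, stats::setNames(rep(NA_character_, length(fams)), fams))
  depth_mode <- "family-only"
  if (!is.null(parents)) {
    stopifnot(is.character(parents), !is.null(names(parents)))
    parent[names(parents)] <- parents
    extra <- setdiff(unname(parents), names(parent))
    if (length(extra)) {
      parent <- c(parent, stats::setNames(rep(NA_character_, length(extra)), extra))
    }
    depth_mode <- "multi-level"
  }
  h <- structure(list(leaves = leaves, parent = parent,
                      depth_mode = depth_mode),
                 class = "icd_hierarchy")
  # reject cycles up front: walking from any leaf must terminate
  for (l in leaves) ancestors_of(l, h)
  h
}

#' @export
print.icd_hierarchy <- function(x, ...) {
  cat("<icd_hierarchy> ", length(x$leaves), " leaves, ",
      length(unique(family_of(x$leaves))), " families, depth mode: ",
      x$depth_mode, "\n", sep = "")
  invisible(x)
}

#' Ancestor chain of a leaf code
#'
#' Returns the chain of ancestor node ids from the immediate parent up to
#' the root. In family-only mode this is exactly the family head.
#'
#' @param code A single leaf code of `hierarchy`.
#' @param hierarchy An [code_hierarchy()] object.
#' @return Character vector of ancestor node ids, parent first.
#' @export
ancestors_of <- function(code, hierarchy) {
  stopifnot(inherits(hierarchy, "icd_hierarchy"))
  code <- parse_code(code)
  stopifnot(length(code) == 1L)
  if (!code %in% hierarchy$leaves) {
    stop("unknown leaf: ", sQuote(code), call. = FALSE)
  }
  chain <- character(0)
  node <- unname(hierarchy$parent[[code]])
  while (!is.na(node)) {
    if (node %in% chain || length(chain) > length(hierarchy$parent)) {
      stop("cycle detected in hierarchy at node ", sQuote(node), call. = FALSE)
    }
    chain <- c(chain, node)
    node <- if (node %in% names(hierarchy$parent)) {
      unname(hierarchy$parent[[node]])
    } else NA_character_
  }
  chain
}

#' Read a code-description table
#'
#' Reads a CSV with header columns `icd_code,long_title` (the schema of
#' standard hospital diagnosis dictionaries) into a named character vector of
#' descriptions keyed by normalized code.
#'
#' @param path Path to the CSV file.
#' @return Named character vector: code -> description.
#' @examples
#' tbl <- read_code_table(system.file("extdata", "example_code_table.csv",
#'                                    package = "icdaug"))
#' tbl[["D64.9"]]
#' @export
read_code_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("icd_code", "long_title") %in% names(df))) {
    stop("code table must have columns 'icd_code' and 'long_title'",
         call. = FALSE)
  }
  codes <- parse_code(df$icd_code)
  if (anyDuplicated(codes)) {
    stop("duplicate codes in code table: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(df$long_title))) stop("empty description in code table", call. = FALSE)
  stats::setNames(df$long_title, codes)
}

#' Write a code-description table
#'
#' @param code_table Named character vector: code -> description.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_code_table <- function(code_table, path) {
  utils::write.csv(
    data.frame(icd_code = names(code_table), long_title = unname(code_table),
               stringsAsFactors = FALSE),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-level hierarchy file
#'
#' Reads a delimited file with columns `node_id,parent_id,level` and builds
#' an `icd_hierarchy` whose leaves are the nodes at level `"leaf"`.
#' `parent_id` may be empty for roots.
#'
#' @param path Path to the CSV file.
#' @return An [code_hierarchy()] object in multi-level mode.
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("node_id", "parent_id", "level") %in% names(df))) {
    stop("hierarchy file must have columns 'node_id', 'parent_id', 'level'",
         call. = FALSE)
  }
  leaves <- df$node_id[df$level == "leaf"]
  par <- df$parent_id
  par[!nzchar(par)] <- NA_character_
  code_hierarchy(leaves, parents = stats::setNames(par, df$node_id))
}
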