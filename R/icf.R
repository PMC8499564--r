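# ICF codes, the mono-hierarchy, and taxonomic proximity.
#
# An ICF code is a component letter (b body functions, s body structures,
# d activities/participation, e environmental factors) followed by 1, 3, 4
# or 5 decimal digits: 1 digit is a chapter, 3 a second-level category, 4 a
# third-level and 5 a fourth-level category. Parent links follow from the
# digit string alone: every category's parent is its longest valid prefix.
# A severity qualifier 0-4 may be appended after a dot ("d4500.3").

ICF_COMPONENTS <- c("b", "s", "d", "e")
ICF_LEVEL_LENGTHS <- c(1L, 3L, 4L, 5L)

#' Parse ICF codes
#'
#' Splits code strings such as `"d4500.3"` into component letter, digit
#' string, hierarchy depth and optional severity qualifier. Invalid input
#' aborts with a message naming the offending part; use [icf_is_valid()]
#' for a non-throwing check.
#'
#' @param x Character vector of ICF codes, optionally with a `.q` qualifier
#'   suffix where `q` is a single digit 0-4.
#' @return A tibble with one row per input and columns `code` (canonical
#'   text without qualifier), `component`, `digits`, `depth` (1 = chapter
#'   ... 4 = fourth level) and `qualifier` (integer or `NA`).
#' @examples
#' icf_parse(c("d4500.3", "d450", "b152"))
#' @export
icf_parse <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(
      code = character(), component = character(), digits = character(),
      depth = integer(), qualifier = integer()
    ))
  }
  x_chr <- as.character(x)
  bad <- function(i, part, why) {
    rlang::abort(
      sprintf("Invalid ICF code '%s': %s (%s).", x_chr[i], why, part),
      class = "icfmatch_parse_error"
    )
  }
  n <- length(x_chr)
  component <- character(n)
  digits <- character(n)
  qualifier <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    txt <- x_chr[i]
    if (is.na(txt) || !nzchar(txt)) bad(i, "code", "empty or missing")
    comp <- substr(txt, 1L, 1L)
    if (!comp %in% ICF_COMPONENTS) {
      bad(i, "component", sprintf("component letter '%s' is not one of b, s, d, e", comp))
    }
    rest <- substr(txt, 2L, nchar(txt))
    dot <- regexpr(".", rest, fixed = TRUE)
    if (dot > 0L) {
      qual_txt <- substr(rest, dot + 1L, nchar(rest))
      rest <- substr(rest, 1L, dot - 1L)
      if (!grepl("^[0-4]$", qual_txt)) {
        bad(i, "qualifier", sprintf("qualifier '%s' must be a single digit 0-4", qual_txt))
      }
      qualifier[i] <- as.integer(qual_txt)
    }
    if (!grepl("^[0-9]+$", rest)) {
      bad(i, "digits", sprintf("'%s' contains non-digit characters", rest))
    }
    if (!nchar(rest) %in% ICF_LEVEL_LENGTHS) {
      bad(i, "digits", sprintf("digit string '%s' has length %d; ICF levels have 1, 3, 4 or 5 digits", rest, nchar(rest)))
    }
    component[i] <- comp
    digits[i] <- rest
  }
  tibble::tibble(
    code = paste0(component, digits),
    component = component,
    digits = digits,
    depth = match(nchar(digits), ICF_LEVEL_LENGTHS),
    qualifier = qualifier
  )
}

#' @rdname icf_parse
#' @return `icf_is_valid()`: a logical vector.
#' @export
icf_is_valid <- function(x) {
  vapply(as.character(x), function(txt) {
    if (is.na(txt) || !nzchar(txt)) return(FALSE)
    grepl("^[bsde][0-9]+(\\.[0-4])?$", txt) &&
      nchar(sub("^[bsde]([0-9]+).*$", "\\1", txt)) %in% ICF_LEVEL_LENGTHS
  }, logical(1), USE.NAMES = FALSE)
}

#' Render a code and qualifier back to canonical text
#'
#' @param code Character vector of canonical codes.
#' @param qualifier Optional integer vector of qualifiers 0-4 (`NA` omits
#'   the suffix).
#' @return Character vector, e.g. `"d4500.3"`.
#' @export
icf_render <- function(code, qualifier = NA_integer_) {
  out <- icf_parse(code)$code
  q <- rep_len(as.integer(qualifier), length(out))
  ifelse(is.na(q), out, paste0(out, ".", q))
}

#' Hierarchy accessors for ICF codes
#'
#' `icf_parent()` returns each code's parent (the longest valid digit
#' prefix), or `NA` for a chapter: the four component roots are not
#' themselves codes. `icf_depth()` returns 1 for chapters through 4 for
#' fourth-level categories. `icf_ancestors()` lists a single code's
#' ancestor-or-self chain from the chapter down.
#'
#' @param x Character vector of ICF codes (qualifier suffixes are ignored).
#' @return `icf_parent()`: character vector with `NA` for chapters;
#'   `icf_depth()`: integer vector.
#' @examples
#' icf_parent("d4500") # "d450"
#' icf_parent("d450")  # "d4"
#' icf_parent("d4")    # NA
#' @export
icf_parent <- function(x) {
  p <- icf_parse(x)
  len <- nchar(p$digits)
  parent_len <- vapply(len, function(l) {
    shorter <- ICF_LEVEL_LENGTHS[ICF_LEVEL_LENGTHS < l]
    if (length(shorter) == 0) NA_integer_ else max(shorter)
  }, integer(1))
  ifelse(is.na(parent_len), NA_character_,
         paste0(p$component, substr(p$digits, 1L, parent_len)))
}

#' @rdname icf_parent
#' @export
icf_depth <- function(x) icf_parse(x)$depth

#' @rdname icf_parent
#' @export
icf_ancestors <- function(x) {
  stopifnot(length(x) == 1L)
  p <- icf_parse(x)
  lens <- ICF_LEVEL_LENGTHS[ICF_LEVEL_LENGTHS <= nchar(p$digits)]
  paste0(p$component, substr(rep(p$digits, length(lens)), 1L, lens))
}

#' Lowest common ancestor of two ICF codes
#'
#' The deepest code that is an ancestor-or-self of both arguments. Codes
#' from different components, or from different chapters of the same
#' component, share no coded ancestor and give `NA`.
#'
#' @param a,b Character vectors of ICF codes (recycled to a common length).
#' @return Character vector of codes, `NA` where none exists.
#' @examples
#' icf_lca("d4500", "d450") # "d450"
#' icf_lca("d450", "d460")  # "d4"
#' icf_lca("d450", "b152")  # NA
#' @export
icf_lca <- function(a, b) {
  pa <- icf_parse(a)
  pb <- icf_parse(b)
  n <- max(nrow(pa), nrow(pb))
  pa <- pa[rep_len(seq_len(nrow(pa)), n), ]
  pb <- pb[rep_len(seq_len(nrow(pb)), n), ]
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (pa$component[i] != pb$component[i]) next
    da <- pa$digits[i]; db <- pb$digits[i]
    k <- 0L
    while (k < min(nchar(da), nchar(db)) &&
           substr(da, k + 1L, k + 1L) == substr(db, k + 1L, k + 1L)) {
      k <- k + 1L
    }
    valid <- ICF_LEVEL_LENGTHS[ICF_LEVEL_LENGTHS <= k]
    if (length(valid) > 0) {
      out[i] <- paste0(pa$component[i], substr(da, 1L, max(valid)))
    }
  }
  out
}

#' Taxonomic proximity of two ICF codes
#'
#' Quantifies how close two categories sit in the ICF mono-hierarchy, on a
#' 0-1 scale. The default `"wu_palmer"` strategy is a Wu-Palmer-style
#' measure restricted to a tree:
#' `depth(lca) / max(depth(a), depth(b))`, which is 1 exactly on identical
#' codes, rewards ancestor-descendant pairs, and is 0 when the codes share
#' no coded ancestor (different components or different chapters). The
#' alternative `"inverse_edge"` strategy is `1 / (1 + d)` with `d` the
#' edge distance through the lowest common ancestor.
#'
#' @param a,b Character vectors of ICF codes (recycled).
#' @param method Proximity strategy, `"wu_palmer"` (default) or
#'   `"inverse_edge"`.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' icf_proximity("d4500", "d450") # 2/3
#' icf_proximity("d450", "d460") # 1/2
#' icf_proximity("d450", "b152") # 0
#' @export
icf_proximity <- function(a, b, method = c("wu_palmer", "inverse_edge")) {
  method <- match.arg(method)
  da <- icf_depth(a)
  db <- icf_depth(b)
  n <- max(length(da), length(db))
  da <- rep_len(da, n); db <- rep_len(db, n)
  lca <- icf_lca(a, b)
  dl <- rep(0L, n)
  has <- !is.na(lca)
  if (any(has)) dl[has] <- icf_depth(lca[has])
  if (method == "wu_palmer") {
    out <- ifelse(has, dl / pmax(da, db), 0)
  } else {
    out <- ifelse(has, 1 / (1 + (da - dl) + (db - dl)), 0)
  }
  out
}

#' Load an ICF taxonomy subset
#'
#' Reads a two-column tab-separated file (`code<TAB>title`, `#` comments)
#' and validates it as a self-contained fragment of the ICF: codes must be
#' unique and every non-chapter code's parent must itself be present. The
#' package ships a subset of about sixty categories covering the bundled
#' fixtures; a user-supplied file (e.g. the full WHO classification, which
#' cannot be redistributed here) is accepted through the same format.
#'
#' @param path Path to a taxonomy TSV; `NULL` loads the bundled subset.
#' @return A tibble of class `icf_taxonomy` with columns `code`, `title`,
#'   `component`, `depth` and `parent`.
#' @examples
#' tax <- icf_taxonomy()
#' dplyr::filter(tax, code == "d450")
#' @export
icf_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "icf-subset.tsv", package = "icfmatch")
  }
  raw <- readr::read_tsv(
    path, col_names = c("code", "title"),
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  if (anyDuplicated(raw$code)) {
    rlang::abort(
      sprintf("Duplicate ICF codes in taxonomy: %s.",
              paste(unique(raw$code[duplicated(raw$code)]), collapse = ", ")),
      class = "icfmatch_validation_error"
    )
  }
  parsed <- icf_parse(raw$code)
  tax <- tibble::tibble(
    code = parsed$code, title = raw$title,
    component = parsed$component, depth = parsed$depth,
    parent = icf_parent(parsed$code)
  )
  missing_parents <- setdiff(stats::na.omit(tax$parent), tax$code)
  if (length(missing_parents) > 0) {
    rlang::abort(
      sprintf("Taxonomy is not closed under parents; missing: %s.",
              paste(missing_parents, collapse = ", ")),
      class = "icfmatch_validation_error"
    )
  }
  class(tax) <- c("icf_taxonomy", class(tax))
  tax
}

# Abort unless all codes are present in the taxonomy (qualifiers ignored).
check_in_taxonomy <- function(codes, taxonomy, what = "code") {
  if (is.null(taxonomy)) return(invisible(codes))
  canon <- icf_parse(codes)$code
  missing <- setdiff(unique(canon), taxonomy$code)
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("%s not in the active taxonomy: %s.", what,
              paste(missing, collapse = ", ")),
      class = "icfmatch_validation_error"
    )
  }
  invisible(codes)
}
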