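# From raw geriatric-assessment scores to ICF-coded functional limitations.
#
# Each instrument's admissible score range is partitioned into half-open
# bands [lo, hi), each band assigning one ICF code and a severity
# qualifier 0-4. Qualifier 0 means "no impairment": such outcomes are
# kept for audit (zero_need = TRUE) but carry no weight in ranking.

# Admissible score ranges, used for the out-of-range error before band
# lookup. IADL is scored per item (0 = dependent, 1 = independent).
instrument_ranges <- function() {
  tibble::tribble(
    ~instrument, ~lo, ~hi,
    "TUG",       0,   Inf,
    "MMSE",      0,   31,
    "GDS",       0,   16,
    "CLOCK",     1,   7,
    "IADL",      0,   2
  )
}

#' Default assessment-to-ICF mapping rules
#'
#' The bands follow the instruments' conventional cut-offs: Timed
#' Up-and-Go under 10 s is unimpaired, 10-20 s mildly, 20-30 s moderately
#' and over 30 s severely impaired walking (d450); MMSE 27-30 is normal
#' cognition, 21-26 mild, 11-20 moderate and 0-10 severe memory
#' impairment (b144); GDS-15 scores of 5-8 suggest mild, 9-11 moderate
#' and 12-15 severe depressive symptoms (b152); the Shulman clock score
#' maps 3 to mild, 4 to moderate and 5-6 to severe cognitive impairment
#' (b144). IADL items are mapped individually: a dependent item (score 0)
#' yields a moderate (qualifier 2) limitation in the matching domestic or
#' self-care category. The ANGELINA instrument ships no default rules;
#' supply your own via [read_mapping_rules()].
#'
#' Rules are half-open intervals `[lo, hi)` so boundary scores are
#' unambiguous. All bands are overridable: pass any tibble with the same
#' columns to [map_assessments()].
#'
#' @return A tibble with columns `instrument`, `item` (`NA` except for
#'   IADL), `lo`, `hi`, `code`, `qualifier`.
#' @export
default_mapping_rules <- function() {
  tibble::tribble(
    ~instrument, ~item,            ~lo, ~hi, ~code,   ~qualifier,
    "TUG",   NA_character_,          0,  10, "d450",  0L,
    "TUG",   NA_character_,         10,  20, "d450",  1L,
    "TUG",   NA_character_,         20,  30, "d450",  2L,
    "TUG",   NA_character_,         30, Inf, "d450",  3L,
    "MMSE",  NA_character_,         27,  31, "b144",  0L,
    "MMSE",  NA_character_,         21,  27, "b144",  1L,
    "MMSE",  NA_character_,         11,  21, "b144",  2L,
    "MMSE",  NA_character_,          0,  11, "b144",  3L,
    "GDS",   NA_character_,          0,   5, "b152",  0L,
    "GDS",   NA_character_,          5,   9, "b152",  1L,
    "GDS",   NA_character_,          9,  12, "b152",  2L,
    "GDS",   NA_character_,         12,  16, "b152",  3L,
    "CLOCK", NA_character_,          1,   3, "b144",  0L,
    "CLOCK", NA_character_,          3,   4, "b144",  1L,
    "CLOCK", NA_character_,          4,   5, "b144",  2L,
    "CLOCK", NA_character_,          5,   7, "b144",  3L,
    "IADL",  "shopping",             0,   1, "d620",  2L,
    "IADL",  "shopping",             1,   2, "d620",  0L,
    "IADL",  "housekeeping",         0,   1, "d640",  2L,
    "IADL",  "housekeeping",         1,   2, "d640",  0L,
    "IADL",  "meal_preparation",     0,   1, "d630",  2L,
    "IADL",  "meal_preparation",     1,   2, "d630",  0L,
    "IADL",  "transportation",       0,   1, "d470",  2L,
    "IADL",  "transportation",       1,   2, "d470",  0L,
    "IADL",  "medication_handling",  0,   1, "d5702", 2L,
    "IADL",  "medication_handling",  1,   2, "d5702", 0L,
    "IADL",  "finances",             0,   1, "d860",  2L,
    "IADL",  "finances",             1,   2, "d860",  0L
  )
}

#' Read mapping rules from YAML or JSON
#'
#' Accepts a list of records with fields `instrument`, `lo`, `hi`,
#' `icf_code` (or `code`), `qualifier` and optional `item`, validates
#' them (qualifiers 0-4, parseable codes, non-overlapping intervals per
#' instrument/item) and returns the rule tibble used by
#' [map_assessments()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` rules file.
#' @return A mapping-rule tibble; see [default_mapping_rules()].
#' @export
read_mapping_rules <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  rules <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(
      instrument = as.character(r$instrument),
      item = if (is.null(r$item)) NA_character_ else as.character(r$item),
      lo = as.numeric(r$lo),
      hi = as.numeric(if (is.null(r$hi)) Inf else r$hi),
      code = as.character(if (!is.null(r$icf_code)) r$icf_code else r$code),
      qualifier = as.integer(r$qualifier)
    )
  })
  validate_mapping_rules(rules)
}

#' @rdname read_mapping_rules
#' @param rules A mapping-rule tibble to validate.
#' @export
validate_mapping_rules <- function(rules) {
  stopifnot(all(c("instrument", "lo", "hi", "code", "qualifier") %in% names(rules)))
  if (!"item" %in% names(rules)) rules$item <- NA_character_
  if (any(is.na(rules$qualifier)) || any(rules$qualifier < 0L | rules$qualifier > 4L)) {
    rlang::abort("Rule qualifiers must be integers 0-4.",
                 class = "icfmatch_config_error")
  }
  if (any(rules$lo >= rules$hi)) {
    rlang::abort("Rule intervals must satisfy lo < hi.",
                 class = "icfmatch_config_error")
  }
  icf_parse(rules$code)
  overlap <- rules |>
    dplyr::group_by(.data$instrument, .data$item) |>
    dplyr::arrange(.data$lo, .by_group = TRUE) |>
    dplyr::summarise(
      bad = dplyr::n() > 1 && any(.data$lo[-1] < .data$hi[-dplyr::n()]),
      .groups = "drop"
    )
  if (any(overlap$bad)) {
    offenders <- overlap$instrument[overlap$bad]
    rlang::abort(
      sprintf("Overlapping rule intervals for instrument(s): %s.",
              paste(unique(offenders), collapse = ", ")),
      class = "icfmatch_config_error"
    )
  }
  rules
}

#' Map assessment results to functional limitations
#'
#' Applies the half-open rule bands to each assessment result and merges
#' the emitted limitations per ICF code (maximum qualifier wins). Results
#' landing in a qualifier-0 band are emitted with `zero_need = TRUE`;
#' they record that an instrument found nothing, and never influence
#' ranking.
#'
#' @param results A tibble of assessment results with columns
#'   `instrument`, `score` and, for IADL, `item`.
#' @param rules Mapping rules; defaults to [default_mapping_rules()].
#' @param taxonomy Optional [icf_taxonomy()] used to check emitted codes.
#' @return A tibble of limitations with columns `code`, `qualifier`,
#'   `zero_need`, `instrument`, `score`, sorted by code.
#' @examples
#' map_assessments(tibble::tibble(instrument = "TUG", score = 14))
#' @export
map_assessments <- function(results, rules = default_mapping_rules(),
                            taxonomy = NULL) {
  stopifnot(all(c("instrument", "score") %in% names(results)))
  if (!"item" %in% names(results)) results$item <- NA_character_
  rules <- validate_mapping_rules(rules)
  ranges <- instrument_ranges()
  hits <- purrr::pmap_dfr(
    list(results$instrument, results$score, results$item),
    function(inst, score, item) {
      cand <- rules[rules$instrument == inst, ]
      if (nrow(cand) == 0) {
        rlang::abort(
          sprintf("No mapping rules configured for instrument '%s'.", inst),
          class = "icfmatch_config_error"
        )
      }
      if (!is.na(item)) cand <- cand[!is.na(cand$item) & cand$item == item, ]
      else cand <- cand[is.na(cand$item), ]
      if (nrow(cand) == 0) {
        rlang::abort(
          sprintf("No mapping rules for instrument '%s', item '%s'.", inst, item),
          class = "icfmatch_config_error"
        )
      }
      rng <- ranges[ranges$instrument == inst, ]
      in_range <- nrow(rng) == 0 || (score >= rng$lo && score < rng$hi)
      hit <- cand[score >= cand$lo & score < cand$hi, ]
      if (!in_range || nrow(hit) == 0) {
        rlang::abort(
          sprintf("Score %s for instrument '%s'%s matches no mapping interval.",
                  format(score), inst,
                  if (is.na(item)) "" else sprintf(" (item '%s')", item)),
          class = "icfmatch_unmapped_score"
        )
      }
      tibble::tibble(
        code = hit$code[1], qualifier = hit$qualifier[1],
        instrument = inst, score = score
      )
    }
  )
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      code = character(), qualifier = integer(), zero_need = logical(),
      instrument = character(), score = numeric()
    ))
  }
  check_in_taxonomy(hits$code, taxonomy, "Emitted limitation code(s)")
  hits |>
    dplyr::group_by(.data$code) |>
    dplyr::arrange(dplyr::desc(.data$qualifier), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(zero_need = .data$qualifier == 0L) |>
    dplyr::select("code", "qualifier", "zero_need", "instrument", "score") |>
    dplyr::arrange(.data$code)
}

#' Merge two limitation sets
#'
#' Union by ICF code; where both sets code the same category the maximum
#' qualifier wins. Output is sorted by canonical code text, so merging is
#' deterministic and idempotent.
#'
#' @param a,b Limitation tibbles with at least `code` and `qualifier`.
#' @return A merged limitation tibble.
#' @export
merge_limitations <- function(a, b) {
  empty <- tibble::tibble(code = character(), qualifier = integer())
  combined <- dplyr::bind_rows(
    if (is.null(a) || nrow(a) == 0) empty else a,
    if (is.null(b) || nrow(b) == 0) empty else b
  )
  if (nrow(combined) == 0) return(empty)
  combined |>
    dplyr::group_by(.data$code) |>
    dplyr::arrange(dplyr::desc(.data$qualifier), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(zero_need = .data$qualifier == 0L) |>
    dplyr::arrange(.data$code)
}

#' Patient profiles
#'
#' A patient profile bundles an identifier, inert clinical metadata
#' (demographics, diagnoses, drugs - kept for fidelity, never scored),
#' raw assessment results, and any pre-coded ICF limitations. The
#' scoring-side view is [profile_limitations()], which maps the
#' assessments through the rule table and merges in the pre-coded set.
#'
#' @param id Patient identifier.
#' @param demographics Optional named list (age, sex, living situation...).
#' @param diagnoses,medications Optional character vectors (metadata only).
#' @param assessments Optional tibble with `instrument`, `score`, `item`.
#' @param limitations Optional pre-coded limitation tibble
#'   (`code`, `qualifier`).
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(id, demographics = NULL, diagnoses = NULL,
                            medications = NULL, assessments = NULL,
                            limitations = NULL) {
  if (!is.null(limitations) && nrow(limitations) > 0) {
    p <- icf_parse(limitations$code)
    limitations$code <- p$code
    limitations$qualifier <- as.integer(limitations$qualifier)
    if (any(is.na(limitations$qualifier)) ||
        any(limitations$qualifier < 0L | limitations$qualifier > 4L)) {
      rlang::abort("Limitation qualifiers must be integers 0-4.",
                   class = "icfmatch_validation_error")
    }
  }
  structure(
    list(
      id = as.character(id),
      demographics = demographics,
      diagnoses = diagnoses,
      medications = medications,
      assessments = assessments,
      limitations = limitations
    ),
    class = "patient_profile"
  )
}

#' @rdname patient_profile
#' @param profile A `patient_profile`.
#' @param rules,taxonomy Passed to [map_assessments()].
#' @return `profile_limitations()`: the merged limitation tibble.
#' @export
profile_limitations <- function(profile, rules = default_mapping_rules(),
                                taxonomy = NULL) {
  stopifnot(inherits(profile, "patient_profile"))
  from_assessments <- if (!is.null(profile$assessments) &&
                          nrow(profile$assessments) > 0) {
    map_assessments(profile$assessments, rules = rules, taxonomy = taxonomy)
  } else {
    NULL
  }
  pre <- profile$limitations
  if (!is.null(pre) && nrow(pre) > 0) {
    check_in_taxonomy(pre$code, taxonomy, "Pre-coded limitation code(s)")
  }
  out <- merge_limitations(from_assessments, pre)
  if (!"zero_need" %in% names(out)) out$zero_need <- out$qualifier == 0L
  out
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile> %s\n", x$id))
  if (!is.null(x$demographics)) {
    cat("  ", paste(names(x$demographics), unlist(x$demographics),
                    sep = ": ", collapse = "; "), "\n", sep = "")
  }
  n_a <- if (is.null(x$assessments)) 0L else nrow(x$assessments)
  n_l <- if (is.null(x$limitations)) 0L else nrow(x$limitations)
  cat(sprintf("  %d assessment result(s), %d pre-coded limitation(s)\n", n_a, n_l))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname patient_profile
#' @param x A `patient_profile`.
#' @param ... Passed to [profile_limitations()].
#' @return `tidy()`: the limitation tibble for the profile.
#' @export
tidy.patient_profile <- function(x, ...) profile_limitations(x, ...)

#' Read and write patient profiles as JSON
#'
#' The on-disk schema is
#' `{id, demographics?, diagnoses?, medications?, assessments?: [{instrument,
#' score, item?}], limitations?: [{code, qualifier}]}`. Pre-coded
#' limitations and assessment-derived ones are merged by
#' [profile_limitations()].
#'
#' @param path File path.
#' @return `read_profile()`: a [patient_profile()].
#' @export
read_profile <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  assessments <- if (!is.null(obj$assessments)) {
    a <- tibble::as_tibble(obj$assessments)
    if (!"item" %in% names(a)) a$item <- NA_character_
    a
  }
  limitations <- if (!is.null(obj$limitations)) {
    tibble::as_tibble(obj$limitations)
  }
  patient_profile(
    id = obj$id,
    demographics = obj$demographics,
    diagnoses = obj$diagnoses,
    medications = obj$medications,
    assessments = assessments,
    limitations = limitations
  )
}

#' @rdname read_profile
#' @param profile A `patient_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "patient_profile"))
  obj <- Filter(Negate(is.null), unclass(profile))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
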