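# Bundled study fixtures and the synthetic-cohort generator.

#' Case-vignette patient profiles
#'
#' The two anonymized multimorbid case vignettes used for plausibility
#' checking: no. 1, an 81-year-old man with polypharmacy, type 2
#' diabetes and hypertension (Timed Up-and-Go 14 s, GDS 7, dependent in
#' shopping and housekeeping, pain-limited daily functions); no. 2, an
#' 89-year-old woman living alone with suspected dementia (Timed
#' Up-and-Go 25 s, MMSE 25, clock test 3, hearing difficulties despite a
#' hearing aid). Diagnoses and drugs are carried as inert metadata and
#' never scored.
#'
#' @param n Vignette number, 1 or 2.
#' @return A [patient_profile()].
#' @examples
#' case_vignette(1)
#' @export
case_vignette <- function(n) {
  if (length(n) != 1 || !n %in% c(1, 2)) {
    rlang::abort("`n` must be 1 or 2.", class = "icfmatch_argument_error")
  }
  read_profile(system.file(
    "extdata", sprintf("vignette%d-profile.json", n), package = "icfmatch"
  ))
}

#' Case-vignette Delphi rating matrices
#'
#' The items-by-raters 0/1 matrices of original recommendations made by
#' the eight panel GPs for the two case vignettes: 19 recommendation
#' types for vignette 1 (48 marks in total) and 16 for vignette 2 (41
#' marks). Row totals follow the published tables; the assignment of
#' marks to individual rater columns is a reconstruction constrained to
#' reproduce every published per-rater marginal (ranges 3-10 and 1-9,
#' means 6.0 and 5.1, sd 2.9 for both, pooled mean 5.6 / sd 2.8).
#'
#' @param n Vignette number, 1 or 2.
#' @return A `delphi_matrix` tibble, see [read_delphi_matrix()].
#' @examples
#' per_rater_counts(delphi_matrix(1))
#' @export
delphi_matrix <- function(n) {
  if (length(n) != 1 || !n %in% c(1, 2)) {
    rlang::abort("`n` must be 1 or 2.", class = "icfmatch_argument_error")
  }
  read_delphi_matrix(system.file(
    "extdata", sprintf("delphi-table%d.csv", n), package = "icfmatch"
  ))
}

# Run code with a private, seeded RNG stream, restoring global state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

COHORT_TYPES <- c("polypharmacy_diabetes_hypertension", "dementia_suspect")

#' Generate a synthetic patient cohort
#'
#' Seeded generator of patient profiles emulating the two multimorbidity
#' profiles used in plausibility checking. Scores are drawn in the
#' impaired ranges typical of community-dwelling multimorbid elders:
#'
#' * `polypharmacy_diabetes_hypertension` - mobility always at least
#'   mildly limited (Timed Up-and-Go drawn from a normal with mean 18 s,
#'   sd 4, clamped to 10-40 s), GDS drawn over 0-12, and six IADL items
#'   failed independently (shopping and housekeeping most often).
#' * `dementia_suspect` - MMSE drawn uniformly over 18-26 (always below
#'   the 27-point normal-cognition cut-off) and clock test over 3-6, a
#'   milder Timed Up-and-Go (normal mean 16 s, sd 5, clamped to 6-40 s),
#'   and a pre-coded hearing limitation (b230, qualifier 1) in about
#'   half of the profiles.
#'
#' The generator is order-stable and reproducible: the same seed yields
#' an identical cohort.
#'
#' @param n Number of patients (0 gives an empty cohort).
#' @param type One of `"polypharmacy_diabetes_hypertension"`,
#'   `"dementia_suspect"`.
#' @param seed Integer random seed.
#' @return A tibble with one row per patient: `id`, `type`,
#'   `assessments` (list-column of tibbles) and `limitations`
#'   (list-column of pre-coded limitation tibbles, possibly empty).
#' @examples
#' generate_cohort(3, "dementia_suspect", seed = 42)
#' @export
generate_cohort <- function(n, type = COHORT_TYPES, seed = 1L) {
  if (length(type) != 1 || !type %in% COHORT_TYPES) {
    type <- tryCatch(match.arg(type), error = function(e) {
      rlang::abort(
        sprintf("Unknown profile type '%s'.", paste(type, collapse = "/")),
        class = "icfmatch_config_error"
      )
    })
  }
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  n <- as.integer(n)
  empty <- tibble::tibble(
    id = character(), type = character(),
    assessments = list(), limitations = list()
  )
  if (n == 0) return(empty)
  iadl_items <- c("shopping", "housekeeping", "meal_preparation",
                  "transportation", "medication_handling", "finances")
  iadl_fail_p <- c(0.6, 0.6, 0.3, 0.4, 0.3, 0.3)
  with_local_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      if (type == "polypharmacy_diabetes_hypertension") {
        tug <- round(pmin(pmax(stats::rnorm(1, 18, 4), 10), 40), 1)
        gds <- sample(0:12, 1)
        fails <- stats::rbinom(length(iadl_items), 1, iadl_fail_p)
        a <- dplyr::bind_rows(
          tibble::tibble(instrument = "TUG", score = tug, item = NA_character_),
          tibble::tibble(instrument = "GDS", score = gds, item = NA_character_),
          tibble::tibble(instrument = "IADL", score = as.numeric(1 - fails),
                         item = iadl_items)
        )
        lim <- tibble::tibble(code = character(), qualifier = integer())
      } else {
        tug <- round(pmin(pmax(stats::rnorm(1, 16, 5), 6), 40), 1)
        mmse <- sample(18:26, 1)
        clock <- sample(3:6, 1)
        a <- tibble::tibble(
          instrument = c("TUG", "MMSE", "CLOCK"),
          score = c(tug, mmse, clock),
          item = NA_character_
        )
        lim <- if (stats::runif(1) < 0.5) {
          tibble::tibble(code = "b230", qualifier = 1L)
        } else {
          tibble::tibble(code = character(), qualifier = integer())
        }
      }
      list(assessments = a, limitations = lim)
    })
    tibble::tibble(
      id = sprintf("%s-%03d", substr(type, 1, 4), seq_len(n)),
      type = type,
      assessments = purrr::map(rows, "assessments"),
      limitations = purrr::map(rows, "limitations")
    )
  })
}

#' Limitations for every cohort member
#'
#' Maps each synthetic patient's assessments through the rule table and
#' merges pre-coded limitations, returning one long tibble.
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param rules,taxonomy Passed to [map_assessments()].
#' @return A tibble of limitations with a leading `id` column.
#' @export
cohort_limitations <- function(cohort, rules = default_mapping_rules(),
                               taxonomy = NULL) {
  purrr::map2_dfr(cohort$id, seq_len(nrow(cohort)), function(id, i) {
    mapped <- map_assessments(cohort$assessments[[i]], rules = rules,
                              taxonomy = taxonomy)
    dplyr::mutate(merge_limitations(mapped, cohort$limitations[[i]]),
                  id = id, .before = 1)
  })
}
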