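# The ranking core: need-weighted taxonomic matching of patient
# limitations against service treatment targets.
#
# A limitation with qualifier q matched against one target code scores
# (q / 4) * proximity(limitation, target): severity expresses need,
# proximity expresses how directly the service addresses the impaired
# function. Per service, each limitation contributes its best-matching
# target; the service total aggregates those contributions.

#' Pair score of one limitation against one treatment target
#'
#' `(qualifier / 4) * proximity(code, target)`, in `[0, 1]`. Zero when
#' the qualifier is 0 (no impairment means no need) or when the codes
#' share no coded ancestor.
#'
#' @param code,qualifier Limitation ICF code(s) and severity qualifier(s)
#'   0-4.
#' @param target Treatment-target ICF code(s).
#' @param method Proximity strategy, see [icf_proximity()].
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' pair_score("d4500", 3, "d450") # 0.75 * 2/3 = 0.5
#' @export
pair_score <- function(code, qualifier, target,
                       method = c("wu_palmer", "inverse_edge")) {
  qualifier <- as.integer(qualifier)
  if (any(is.na(qualifier)) || any(qualifier < 0L | qualifier > 4L)) {
    rlang::abort("Qualifiers must be integers 0-4.",
                 class = "icfmatch_validation_error")
  }
  (qualifier / 4) * icf_proximity(code, target, method = match.arg(method))
}

# Score one service's target set against a limitation tibble.
# Returns list(total, matches): per limitation the argmax target (ties
# broken towards the lexicographically smallest target code).
score_one_service <- function(limitations, targets,
                              agg = c("sum_best", "max"),
                              method = c("wu_palmer", "inverse_edge")) {
  agg <- match.arg(agg)
  method <- match.arg(method)
  live <- limitations[limitations$qualifier > 0L, , drop = FALSE]
  if (nrow(live) == 0 || length(targets) == 0) {
    return(list(total = 0, matches = tibble::tibble(
      code = character(), qualifier = integer(),
      target = character(), score = numeric()
    )))
  }
  targets <- sort(unique(targets))
  nl <- nrow(live)
  nt <- length(targets)
  s <- matrix(
    pair_score(rep(live$code, times = nt), rep(live$qualifier, times = nt),
               rep(targets, each = nl), method = method),
    nrow = nl, ncol = nt
  )
  # targets are sorted, so "first" resolves score ties towards the
  # lexicographically smallest target code
  best_j <- max.col(s, ties.method = "first")
  matches <- tibble::tibble(
    code = live$code,
    qualifier = live$qualifier,
    target = targets[best_j],
    score = s[cbind(seq_len(nl), best_j)]
  )
  total <- switch(agg,
    sum_best = sum(matches$score),
    max = if (nrow(matches) > 0) max(matches$score) else 0
  )
  list(total = total, matches = matches)
}

#' Score every catalogue service against a patient
#'
#' Computes each service's match score without dropping or truncating
#' anything; [rank_services()] builds the recommendation list on top.
#'
#' @param profile A [patient_profile()] or a limitation tibble with
#'   columns `code` and `qualifier`.
#' @param catalogue A `service_catalogue` (see [read_catalogue()]).
#' @param agg Aggregation over limitations: `"sum_best"` (default) sums
#'   each limitation's best-matching target so services addressing
#'   several impaired functions accumulate need; `"max"` scores only the
#'   single strongest match.
#' @param method Proximity strategy, see [icf_proximity()].
#' @param rules,taxonomy Passed to [profile_limitations()] when `profile`
#'   is a `patient_profile`.
#' @return A tibble with one row per service: `id`, `name`, `category`,
#'   `score`, and a `matches` list-column of per-limitation detail
#'   (`code`, `qualifier`, `target`, `score`).
#' @export
score_services <- function(profile, catalogue,
                           agg = c("sum_best", "max"),
                           method = c("wu_palmer", "inverse_edge"),
                           rules = default_mapping_rules(),
                           taxonomy = NULL) {
  agg <- match.arg(agg)
  method <- match.arg(method)
  limitations <- if (inherits(profile, "patient_profile")) {
    profile_limitations(profile, rules = rules, taxonomy = taxonomy)
  } else {
    tibble::as_tibble(profile)
  }
  stopifnot(all(c("code", "qualifier") %in% names(limitations)))
  scored <- purrr::map(catalogue$targets, score_one_service,
                       limitations = limitations, agg = agg, method = method)
  tibble::tibble(
    id = catalogue$id,
    name = catalogue$name,
    category = catalogue$category,
    score = vapply(scored, `[[`, numeric(1), "total"),
    matches = purrr::map(scored, "matches")
  )
}

#' Rank services for a patient
#'
#' Scores every service with [score_services()], drops services with
#' zero score (nothing in their target set addresses any coded need),
#' sorts by score descending with ties broken by ascending service id,
#' and keeps the `top_n` head. Scoring is fully deterministic: identical
#' inputs give identical rankings.
#'
#' @inheritParams score_services
#' @param top_n Maximum number of recommendations, default 20.
#' @return A tibble of class `drs_ranking` with columns `rank`, `id`,
#'   `name`, `category`, `score`, `matches`; the patient id and scoring
#'   configuration are stored as attributes.
#' @examples
#' tax <- icf_taxonomy()
#' prof <- patient_profile("p1", limitations = tibble::tibble(
#'   code = "d4500", qualifier = 3
#' ))
#' rank_services(prof, demo_catalogue(), taxonomy = tax)
#' @export
rank_services <- function(profile, catalogue, top_n = 20,
                          agg = c("sum_best", "max"),
                          method = c("wu_palmer", "inverse_edge"),
                          rules = default_mapping_rules(),
                          taxonomy = NULL) {
  if (!is.numeric(top_n) || length(top_n) != 1 || is.na(top_n) || top_n < 1) {
    rlang::abort("`top_n` must be a single integer >= 1.",
                 class = "icfmatch_argument_error")
  }
  agg <- match.arg(agg)
  method <- match.arg(method)
  scores <- score_services(profile, catalogue, agg = agg, method = method,
                           rules = rules, taxonomy = taxonomy)
  ranked <- scores |>
    dplyr::filter(.data$score > 0) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$id) |>
    utils::head(n = floor(top_n)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  structure(
    ranked,
    patient_id = if (inherits(profile, "patient_profile")) profile$id else NA_character_,
    config = list(top_n = floor(top_n), agg = agg, method = method),
    class = c("drs_ranking", class(ranked))
  )
}

#' @rdname rank_services
#' @param x A `drs_ranking`.
#' @param ... Unused.
#' @return `tidy()`: one row per (service, contributing limitation) with
#'   the matched target and pair score.
#' @export
tidy.drs_ranking <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("rank", "id", "score", "matches") |>
    dplyr::rename(total_score = "score") |>
    tidyr::unnest("matches", names_sep = "_") |>
    dplyr::rename(
      limitation = "matches_code", qualifier = "matches_qualifier",
      target = "matches_target", pair_score = "matches_score"
    )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname rank_services
#' @return `glance()`: a one-row tibble with the patient id, number of
#'   recommendations, top score and configuration.
#' @export
glance.drs_ranking <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    patient_id = attr(x, "patient_id"),
    n_recommended = nrow(x),
    top_score = if (nrow(x) > 0) max(x$score) else NA_real_,
    top_n = cfg$top_n, agg = cfg$agg, method = cfg$method
  )
}

#' Plot a recommendation ranking
#'
#' Horizontal bar chart of service scores, coloured by service category,
#' best match on top.
#'
#' @param object A `drs_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drs_ranking <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$name, -.data$rank),
    fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "match score", y = NULL, fill = "category",
      title = sprintf("Service recommendations for %s",
                      attr(object, "patient_id"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.drs_ranking <- function(x, ...) print(autoplot(x, ...))

#' Serialize a ranking to JSON
#'
#' Fixed field order and sorted match details give byte-identical output
#' for identical inputs, so rankings can be diffed and cached.
#'
#' @param ranking A `drs_ranking`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path, or the JSON string when `path` is `NULL`.
#' @export
write_ranking <- function(ranking, path = NULL) {
  obj <- list(
    patient_id = attr(ranking, "patient_id"),
    config = attr(ranking, "config"),
    recommendations = purrr::pmap(
      list(ranking$rank, ranking$id, ranking$name, ranking$category,
           ranking$score, ranking$matches),
      function(rank, id, name, category, score, matches) {
        list(rank = rank, id = id, name = name, category = category,
             score = score,
             matches = purrr::pmap(
               list(matches$code, matches$qualifier, matches$target, matches$score),
               function(code, qualifier, target, score) {
                 list(limitation = code, qualifier = qualifier,
                      target = target, score = score)
               }
             ))
      }
    )
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
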