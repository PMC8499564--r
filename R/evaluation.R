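# Plausibility-check statistics for expert-panel (Delphi) rating data.
#
# The raw material is an items-by-raters 0/1 matrix: which recommendation
# types each panelist marked for a case vignette. From it we derive
# per-rater counts and their summary, majority-consensus items, and -
# when a paired set of counts is available (e.g. recommendations judged
# appropriate from algorithm output) - the asymptotic Wilcoxon
# signed-rank test and Cohen's effect size.

#' Read a Delphi rating matrix
#'
#' CSV with the item label in the first column and one 0/1 column per
#' rater. Rejects non-rectangular input, non-binary cells, and duplicate
#' item or rater labels.
#'
#' @param path Path to the CSV file.
#' @return A tibble of class `delphi_matrix`: `item` plus one integer
#'   column per rater.
#' @export
read_delphi_matrix <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_integer(),
    item = readr::col_character()
  ), progress = FALSE, name_repair = "minimal")
  if (!identical(names(m)[1], "item")) {
    names(m)[1] <- "item"
    m$item <- as.character(m$item)
  }
  validate_delphi_matrix(m)
}

validate_delphi_matrix <- function(m) {
  raters <- names(m)[names(m) != "item"]
  if (length(raters) < 1) {
    rlang::abort("A Delphi matrix needs at least one rater column.",
                 class = "icfmatch_argument_error")
  }
  if (anyDuplicated(m$item) || anyDuplicated(raters)) {
    rlang::abort("Item and rater labels must be unique.",
                 class = "icfmatch_validation_error")
  }
  vals <- unlist(m[names(m) != "item"], use.names = FALSE)
  if (anyNA(vals) || !all(vals %in% c(0L, 1L))) {
    rlang::abort("Delphi matrix cells must all be 0 or 1.",
                 class = "icfmatch_validation_error")
  }
  class(m) <- unique(c("delphi_matrix", class(m)))
  m
}

#' Per-rater recommendation counts
#'
#' How many items each rater marked - the "number of recommendations"
#' a panelist made for the vignette.
#'
#' @param m A `delphi_matrix` (see [read_delphi_matrix()]).
#' @return A tibble with columns `rater` and `count`, in column order.
#' @examples
#' per_rater_counts(delphi_matrix(1))
#' @export
per_rater_counts <- function(m) {
  raters <- names(m)[names(m) != "item"]
  if (length(raters) < 1) {
    rlang::abort("Matrix has no rater columns.", class = "icfmatch_argument_error")
  }
  mat <- as.matrix(m[names(m) != "item"])
  tibble::tibble(
    rater = raters,
    count = as.integer(unname(colSums(mat)))
  )
}

#' Summary statistics of a count vector
#'
#' @param counts A numeric vector, or the tibble from
#'   [per_rater_counts()] (its `count` column is used).
#' @return A one-row tibble: `n`, `mean`, `sd` (sample, n-1 denominator),
#'   `min`, `max`.
#' @examples
#' summarize_counts(c(1, 9)) # mean 5, sd 4*sqrt(2)
#' @export
summarize_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- as.numeric(counts)
  if (length(counts) == 0 || anyNA(counts)) {
    rlang::abort("`counts` must be a nonempty numeric vector.",
                 class = "icfmatch_argument_error")
  }
  tibble::tibble(
    n = length(counts),
    mean = mean(counts),
    sd = stats::sd(counts),
    min = min(counts),
    max = max(counts)
  )
}

#' Items endorsed by a majority of raters
#'
#' Items marked by strictly more than `threshold` raters; with the
#' default threshold of half the panel ("more than 4 of 8"), the items a
#' majority endorsed.
#'
#' @param m A `delphi_matrix`.
#' @param threshold Integer between 0 and the number of raters; an item
#'   needs `> threshold` marks to qualify.
#' @return Character vector of item labels, in matrix order.
#' @export
majority_items <- function(m, threshold = floor(ncol(m[-1]) / 2)) {
  raters <- setdiff(names(m), "item")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > length(raters)) {
    rlang::abort("`threshold` must be between 0 and the number of raters.",
                 class = "icfmatch_argument_error")
  }
  marks <- rowSums(as.matrix(m[names(m) != "item"]))
  m$item[marks > threshold]
}

#' Paired Wilcoxon signed-rank test, asymptotic
#'
#' Tests whether paired counts `y` systematically exceed (or fall below)
#' `x`. Differences `d = y - x` of zero are dropped by default
#' (`zero_method = "wilcox"`); the absolute differences are ranked with
#' mid-ranks for ties; `W` is the sum of ranks of positive differences.
#' The normal approximation uses
#' `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)`
#' with `t` the tie-group sizes, and a two-sided p from the standard
#' normal. No continuity correction is applied unless requested.
#' `zero_method = "pratt"` ranks zeros along with the rest before
#' discarding their ranks.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @param continuity Apply the 0.5 continuity correction to `|W - mu|`.
#' @param zero_method `"wilcox"` (drop zero differences, default) or
#'   `"pratt"`.
#' @return An object of class `paired_wilcoxon`: a list with `W`,
#'   `n_effective`, `z`, `p.value`, `zero_method`, `continuity`.
#' @examples
#' paired_wilcoxon(c(6, 4, 7), c(11, 13, 12))
#' @export
paired_wilcoxon <- function(x, y, continuity = FALSE,
                            zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have the same length.",
                 class = "icfmatch_argument_error")
  }
  if (length(x) < 2) {
    rlang::abort("Need at least two pairs.", class = "icfmatch_argument_error")
  }
  d <- as.numeric(y) - as.numeric(x)
  if (all(d == 0)) {
    rlang::abort("All paired differences are zero; the test is degenerate.",
                 class = "icfmatch_degenerate_error")
  }
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  } else {
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    n0 <- sum(d == 0)
    mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    ties <- table(r[d != 0])
    sigma2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(ties^3 - ties) / 48
    n <- sum(d != 0)
  }
  if (sigma2 <= 0) {
    rlang::abort("Zero variance; the test is degenerate.",
                 class = "icfmatch_degenerate_error")
  }
  num <- W - mu
  if (continuity) num <- sign(num) * pmax(abs(num) - 0.5, 0)
  z <- num / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(W = W, n_effective = n, z = z, p.value = min(p, 1),
         zero_method = zero_method, continuity = continuity),
    class = "paired_wilcoxon"
  )
}

#' @export
print.paired_wilcoxon <- function(x, ...) {
  cat("Asymptotic Wilcoxon signed-rank test (paired)\n")
  cat(sprintf("W = %g, n = %d, z = %.2f, two-sided p = %.3f\n",
              x$W, x$n_effective, x$z, x$p.value))
  invisible(x)
}

#' @rdname paired_wilcoxon
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `statistic` (W),
#'   `n_effective`, `z` and `p.value`.
#' @export
tidy.paired_wilcoxon <- function(x, ...) {
  tibble::tibble(statistic = x$W, n_effective = x$n_effective,
                 z = x$z, p.value = x$p.value)
}

#' Cohen's d from group summaries
#'
#' `d = (m2 - m1) / sqrt((s1^2 + s2^2) / 2)`: the mean difference scaled
#' by the root-mean-square of the two standard deviations. Values of 0.8
#' and above are conventionally read as strong effects.
#'
#' @param m1,s1 Mean and sd of the first group.
#' @param m2,s2 Mean and sd of the second group.
#' @return The effect size (numeric scalar).
#' @examples
#' cohens_d(6, 2.9, 11.9, 2.6)
#' @export
cohens_d <- function(m1, s1, m2, s2) {
  if (any(c(s1, s2) < 0)) {
    rlang::abort("Standard deviations must be nonnegative.",
                 class = "icfmatch_argument_error")
  }
  if (s1 == 0 && s2 == 0) {
    rlang::abort("Both standard deviations are zero; d is undefined.",
                 class = "icfmatch_degenerate_error")
  }
  (m2 - m1) / sqrt((s1^2 + s2^2) / 2)
}

#' Evaluate Delphi matrices against paired counts
#'
#' Convenience wrapper producing the full plausibility-check report for
#' one or two vignette matrices: per-rater counts and summaries, the
#' majority-consensus item lists, pooled summary when two matrices are
#' given, and - when per-rater counts from a second source (e.g.
#' recommendations judged appropriate from algorithm output) are
#' supplied - the paired signed-rank test and effect size per matrix.
#'
#' @param m1 A `delphi_matrix`.
#' @param m2 Optional second `delphi_matrix`.
#' @param drs_counts Optional list of numeric vectors (one per matrix)
#'   of paired per-rater counts to compare against.
#' @param threshold Majority threshold, see [majority_items()].
#' @return A list with elements `summary` (tibble, one row per matrix
#'   plus a pooled row when both are given), `majority` (list of
#'   character vectors) and, when `drs_counts` is supplied, `wilcoxon`
#'   (list of `paired_wilcoxon`) and `cohens_d` (numeric vector).
#' @export
evaluate_delphi <- function(m1, m2 = NULL, drs_counts = NULL, threshold = 4) {
  mats <- Filter(Negate(is.null), list(m1, m2))
  counts <- purrr::map(mats, ~ per_rater_counts(.x)$count)
  summaries <- purrr::imap_dfr(counts, function(cc, i) {
    dplyr::mutate(summarize_counts(cc), matrix = paste0("matrix", i), .before = 1)
  })
  if (length(counts) == 2) {
    summaries <- dplyr::bind_rows(
      summaries,
      dplyr::mutate(summarize_counts(unlist(counts)), matrix = "pooled", .before = 1)
    )
  }
  out <- list(
    summary = summaries,
    majority = purrr::map(mats, majority_items, threshold = threshold)
  )
  if (!is.null(drs_counts)) {
    if (length(drs_counts) != length(mats)) {
      rlang::abort("Need one vector of paired counts per matrix.",
                   class = "icfmatch_argument_error")
    }
    out$wilcoxon <- purrr::map2(counts, drs_counts, paired_wilcoxon)
    out$cohens_d <- purrr::map2_dbl(counts, drs_counts, function(gp, drs) {
      cohens_d(mean(gp), stats::sd(gp), mean(drs), stats::sd(drs))
    })
  }
  out
}
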