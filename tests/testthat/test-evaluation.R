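test_that("per-rater counts are column sums, invariant under column permutation", {
  m <- tibble::tibble(
    item = c("a", "b", "c"),
    GP1 = c(1L, 0L, 1L), GP2 = c(0L, 0L, 0L), GP3 = c(1L, 1L, 1L)
  )
  m <- icfmatch:::validate_delphi_matrix(m)
  counts <- per_rater_counts(m)
  expect_equal(counts$count, c(2L, 0L, 3L))

  perm <- m[, c("item", "GP3", "GP1", "GP2")]
  expect_equal(sort(per_rater_counts(perm)$count), sort(counts$count))
  expect_equal(sum(per_rater_counts(perm)$count), sum(counts$count))

  allfalse <- tibble::tibble(item = c("a", "b", "c"),
                             GP1 = 0L, GP2 = 0L, GP3 = 0L, GP4 = 0L)
  expect_equal(per_rater_counts(allfalse)$count, rep(0L, 4))

  expect_error(per_rater_counts(tibble::tibble(item = "a")),
               class = "icfmatch_argument_error")
})

test_that("count summaries use the sample (n-1) standard deviation", {
  s <- summarize_counts(c(5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)

  s <- summarize_counts(c(1, 9))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, sqrt(32)) # ~5.657, closed form with n-1

  expect_error(summarize_counts(numeric(0)), class = "icfmatch_argument_error")
})

test_that("majority selection requires strictly more than the threshold", {
  m <- icfmatch:::validate_delphi_matrix(tibble::tibble(
    item = c("five", "four", "eight"),
    GP1 = c(1L, 1L, 1L), GP2 = c(1L, 1L, 1L), GP3 = c(1L, 1L, 1L),
    GP4 = c(1L, 1L, 1L), GP5 = c(1L, 0L, 1L), GP6 = c(0L, 0L, 1L),
    GP7 = c(0L, 0L, 1L), GP8 = c(0L, 0L, 1L)
  ))
  expect_equal(majority_items(m, 4), c("five", "eight"))
  expect_equal(majority_items(m, 7), "eight")
  expect_error(majority_items(m, 9), class = "icfmatch_argument_error")

  alltrue <- icfmatch:::validate_delphi_matrix(tibble::tibble(
    item = c("a", "b"), GP1 = 1L, GP2 = 1L, GP3 = 1L, GP4 = 1L,
    GP5 = 1L, GP6 = 1L, GP7 = 1L, GP8 = 1L
  ))
  expect_equal(majority_items(alltrue, 4), c("a", "b"))
})

test_that("the matrix reader enforces rectangular 0/1 input", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("item,GP1,GP2", "a,1,0", "b,0,1"), p)
  m <- read_delphi_matrix(p)
  expect_s3_class(m, "delphi_matrix")
  expect_equal(per_rater_counts(m)$count, c(1L, 1L))

  writeLines(c("item,GP1,GP2", "a,1,2", "b,0,1"), p)
  expect_error(read_delphi_matrix(p), class = "icfmatch_validation_error")
  writeLines(c("item,GP1,GP2", "a,1", "b,0,1"), p)
  expect_error(suppressWarnings(read_delphi_matrix(p)))
  writeLines(c("item,GP1,GP1", "a,1,0"), p)
  expect_error(read_delphi_matrix(p), class = "icfmatch_validation_error")
})

test_that("the signed-rank z and p reproduce the closed form on clean shifts", {
  x <- 1:8
  y <- x + c(1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5) # distinct positive shifts
  res <- paired_wilcoxon(x, y)
  expect_equal(res$W, 36)
  expect_equal(res$n_effective, 8L)
  # mu = 18, sigma^2 = 8*9*17/24 = 51
  expect_equal(res$z, 18 / sqrt(51), tolerance = 1e-12)
  expect_equal(res$z, 2.5205, tolerance = 1e-4)
  expect_equal(res$p.value, 2 * stats::pnorm(-18 / sqrt(51)), tolerance = 1e-12)
  expect_equal(res$p.value, 0.0117, tolerance = 1e-2)

  # antisymmetry: swapping the samples negates z, p unchanged
  swapped <- paired_wilcoxon(y, x)
  expect_equal(swapped$z, -res$z)
  expect_equal(swapped$p.value, res$p.value)

  expect_error(paired_wilcoxon(x, x), class = "icfmatch_degenerate_error")
  expect_error(paired_wilcoxon(1:4, 1:5), class = "icfmatch_argument_error")
})

test_that("W matches the Walsh-average oracle and z the enumerated null moments", {
  set.seed(404)
  for (trial in 1:50) {
    n <- sample(4:10, 1)
    x <- sample(0:12, n, replace = TRUE)
    y <- sample(0:18, n, replace = TRUE)
    d <- y - x
    if (all(d == 0)) next
    res <- paired_wilcoxon(x, y)
    expect_equal(res$W, oracle_walsh_W(d))

    d_nz <- d[d != 0]
    r <- rank(abs(d_nz))
    mom <- oracle_sign_enumeration_moments(r)
    if (mom$var <= 0) next
    expect_equal(res$z, (res$W - mom$mean) / sqrt(mom$var), tolerance = 1e-9)
  }
})

test_that("the test agrees with the standard library implementation", {
  set.seed(405)
  for (trial in 1:25) {
    n <- sample(5:12, 1)
    x <- sample(0:10, n, replace = TRUE)
    y <- sample(0:15, n, replace = TRUE)
    if (all(y - x == 0)) next
    res <- paired_wilcoxon(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = FALSE)
    )
    expect_equal(res$W, unname(ref$statistic))
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
    res_cc <- paired_wilcoxon(x, y, continuity = TRUE)
    ref_cc <- suppressWarnings(
      stats::wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = TRUE)
    )
    expect_equal(res_cc$p.value, ref_cc$p.value, tolerance = 1e-12)
  }
})

test_that("Pratt zero handling ranks zeros before discarding them", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 4, 1, 8, 9)
  res <- paired_wilcoxon(x, y, zero_method = "pratt")
  # |d| = 0,2,2,4,4 -> ranks 1, 2.5, 2.5, 4.5, 4.5; positive: 2.5+4.5+4.5
  expect_equal(res$W, 11.5)
  expect_equal(res$n_effective, 4L)
})

test_that("Cohen's d from summaries is antisymmetric and scale-invariant", {
  expect_equal(cohens_d(6, 2.9, 11.9, 2.6), 2.14, tolerance = 5e-3)
  expect_equal(cohens_d(5.1, 2.9, 12, 2.6), 2.51, tolerance = 5e-3)
  expect_equal(cohens_d(5, 1, 5, 1), 0)
  expect_equal(cohens_d(6, 2.9, 11.9, 2.6), -cohens_d(11.9, 2.9, 6, 2.6))
  k <- 3.7
  expect_equal(cohens_d(6 * k, 2.9 * k, 11.9 * k, 2.6 * k),
               cohens_d(6, 2.9, 11.9, 2.6))
  expect_error(cohens_d(1, 0, 2, 0), class = "icfmatch_degenerate_error")
  expect_error(cohens_d(1, -1, 2, 1), class = "icfmatch_argument_error")
})

test_that("evaluate_delphi assembles summaries, majorities and paired tests", {
  m1 <- delphi_matrix(1)
  m2 <- delphi_matrix(2)
  drs <- list(c(12, 9, 13, 7, 14, 11, 12, 17), c(13, 10, 12, 8, 15, 11, 12, 15))
  rep <- evaluate_delphi(m1, m2, drs_counts = drs)
  expect_equal(rep$summary$matrix, c("matrix1", "matrix2", "pooled"))
  expect_equal(rep$summary$n, c(8L, 8L, 16L))
  expect_length(rep$majority, 2)
  expect_length(rep$wilcoxon, 2)
  expect_true(all(rep$cohens_d > 0))
  td <- tidy(rep$wilcoxon[[1]])
  expect_true(all(c("statistic", "z", "p.value") %in% names(td)))
})
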