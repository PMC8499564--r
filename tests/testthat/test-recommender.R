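tax <- icf_taxonomy()
cata <- demo_catalogue(taxonomy = tax)

lim <- function(code, qualifier) tibble::tibble(code = code, qualifier = qualifier)

test_that("pair scores weight proximity by normalized severity", {
  expect_equal(pair_score("d4500", 3, "d450"), 0.75 * 2 / 3) # = 0.5
  expect_equal(pair_score("d450", 0, "d450"), 0)
  expect_equal(pair_score("d450", 4, "d450"), 1)
  expect_equal(pair_score("d4500", 3, "b230"), 0)
  expect_error(pair_score("d450", 5, "d450"), class = "icfmatch_validation_error")
})

test_that("service totals take each limitation's best target and sum", {
  wf <- cata[cata$id == "walking_frame", ]
  s <- score_services(lim("d4500", 3L), wf)
  expect_equal(s$score, 0.5)
  expect_equal(s$matches[[1]]$target, "d450")

  aud <- cata[cata$id == "audiologist", ]
  expect_equal(score_services(lim("d4500", 3L), aud)$score, 0)

  s2 <- score_services(lim(c("d4500", "b152"), c(3L, 1L)), wf)
  expect_equal(s2$score, 0.5 + 0) # the b-code contributes nothing
  expect_equal(nrow(s2$matches[[1]]), 2L)

  # max aggregation scores only the strongest match
  s3 <- score_services(lim(c("d620", "d640"), c(2L, 2L)),
                       cata[cata$id == "housekeeper", ], agg = "max")
  expect_equal(s3$score, 0.5)
})

test_that("service scores equal the brute-force all-pairs oracle", {
  set.seed(202)
  profiles <- lapply(1:100, function(i) random_limitations(6))
  services <- lapply(1:10, function(i) random_service_targets(4))
  for (prof in profiles) {
    fake <- structure(
      tibble::tibble(
        id = sprintf("s%02d", seq_along(services)),
        name = sprintf("Service %d", seq_along(services)),
        category = "medical",
        targets = services,
        description = NA_character_
      ),
      class = c("service_catalogue", "tbl_df", "tbl", "data.frame")
    )
    got <- score_services(prof, fake)
    want <- vapply(services, oracle_service_score, numeric(1),
                   limitations = prof)
    expect_equal(got$score, want)
    got_max <- score_services(prof, fake, agg = "max")
    want_max <- vapply(services, oracle_service_score, numeric(1),
                       limitations = prof, agg = "max")
    expect_equal(got_max$score, want_max)
  }
})

test_that("the worked mobility case ranks the walking frame first", {
  prof <- patient_profile("fig1", limitations = lim("d4500", 3L))
  r <- rank_services(prof, cata[cata$id %in% c("walking_frame", "audiologist"), ],
                     taxonomy = tax)
  expect_equal(r$id, "walking_frame")
  expect_equal(r$score, 0.5)

  # against the full catalogue, every service without a d-component
  # target scores below the walking frame
  full <- rank_services(prof, cata, taxonomy = tax)
  wf_score <- full$score[full$id == "walking_frame"]
  no_d <- vapply(cata$targets, function(t) !any(startsWith(t, "d")), logical(1))
  expect_true(all(full$score[full$id %in% cata$id[no_d]] < wf_score))
})

test_that("ranking drops zero scores, truncates, and breaks ties by id", {
  prof <- lim("d4500", 3L)
  r <- rank_services(prof, cata)
  expect_true(all(r$score > 0))
  expect_true(all(diff(r$score) <= 0))
  expect_lte(nrow(r), 20)

  r3 <- rank_services(prof, cata, top_n = 3)
  expect_equal(nrow(r3), 3L)
  expect_equal(r3$rank, 1:3)

  # empty-limitation profile recommends nothing
  none <- rank_services(lim(character(), integer()), cata)
  expect_equal(nrow(none), 0L)

  # two services with identical targets order by id
  twin <- structure(
    tibble::tibble(
      id = c("zeta", "alpha"), name = c("Z", "A"), category = "medical",
      targets = list("d450", "d450"), description = NA_character_
    ),
    class = c("service_catalogue", "tbl_df", "tbl", "data.frame")
  )
  rt <- rank_services(lim("d450", 2L), twin)
  expect_equal(rt$id, c("alpha", "zeta"))

  expect_error(rank_services(prof, cata, top_n = 0),
               class = "icfmatch_argument_error")
})

test_that("raising a qualifier never lowers scores or the targeted service's rank", {
  set.seed(303)
  for (trial in 1:60) {
    prof <- random_limitations(5)
    base <- score_services(prof, cata)
    i <- sample(nrow(prof), 1)
    if (prof$qualifier[i] == 4) next
    bumped <- prof
    bumped$qualifier[i] <- bumped$qualifier[i] + 1L
    after <- score_services(bumped, cata)
    expect_true(all(after$score >= base$score - 1e-12))
  }
})

test_that("moving a target closer to a limitation never lowers the service score", {
  set.seed(304)
  for (trial in 1:60) {
    code <- random_icf_code(c("b", "d"), max_depth = 4)
    prof <- lim(code, sample(1:4, 1))
    far <- random_icf_code(c("b", "d"))
    svc <- function(tgt) structure(
      tibble::tibble(id = "s", name = "s", category = "medical",
                     targets = list(tgt), description = NA_character_),
      class = c("service_catalogue", "tbl_df", "tbl", "data.frame")
    )
    s_far <- score_services(prof, svc(far))$score
    # replace the target with an ancestor of the limitation (strictly closer
    # than a random draw unless the draw already hit the subtree)
    closer <- icf_ancestors(code)[icf_depth(code)]
    s_closer <- score_services(prof, svc(closer))$score
    if (icf_proximity(code, closer) >= icf_proximity(code, far)) {
      expect_gte(s_closer, s_far)
    }
  }
})

test_that("duplicate targets do not change a service's score", {
  prof <- lim(c("d4500", "b144"), c(3L, 2L))
  svc <- function(tgt) structure(
    tibble::tibble(id = "s", name = "s", category = "medical",
                   targets = list(tgt), description = NA_character_),
    class = c("service_catalogue", "tbl_df", "tbl", "data.frame")
  )
  once <- score_services(prof, svc(c("d450", "b144")))$score
  thrice <- score_services(prof, svc(c("d450", "b144", "d450", "b144", "d450")))$score
  expect_equal(once, thrice)
})

test_that("identical inputs give byte-identical serialized rankings", {
  prof <- patient_profile("p1", limitations = lim(c("d4500", "b152"), c(3L, 2L)))
  j1 <- write_ranking(rank_services(prof, cata, taxonomy = tax))
  j2 <- write_ranking(rank_services(prof, cata, taxonomy = tax))
  expect_identical(j1, j2)
})

test_that("tidy, glance and autoplot expose the ranking", {
  prof <- patient_profile("p1", limitations = lim(c("d4500", "b152"), c(3L, 2L)))
  r <- rank_services(prof, cata, taxonomy = tax)
  td <- tidy(r)
  expect_true(all(c("rank", "id", "total_score", "limitation", "qualifier",
                    "target", "pair_score") %in% names(td)))
  gl <- glance(r)
  expect_equal(gl$patient_id, "p1")
  expect_equal(gl$n_recommended, nrow(r))
  expect_s3_class(autoplot(r), "ggplot")
})
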