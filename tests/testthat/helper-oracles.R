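# Independent brute-force oracles used by the property tests. These are
# deliberately written against the definitions, not against the package
# internals: proximity via explicit ancestor-set intersection, service
# scores via an all-pairs loop, the signed-rank statistic via Walsh
# averages and its null moments via full sign-pattern enumeration.

# Ancestor-or-self set of a code, by explicit prefix enumeration.
oracle_ancestor_set <- function(code) {
  comp <- substr(code, 1, 1)
  digs <- substr(code, 2, nchar(code))
  lens <- c(1, 3, 4, 5)
  lens <- lens[lens <= nchar(digs)]
  paste0(comp, vapply(lens, function(l) substr(digs, 1, l), character(1)))
}

oracle_depth <- function(code) {
  match(nchar(code) - 1L, c(1L, 3L, 4L, 5L))
}

# Wu-Palmer-style proximity from the ancestor-set definition.
oracle_proximity <- function(a, b) {
  common <- intersect(oracle_ancestor_set(a), oracle_ancestor_set(b))
  if (length(common) == 0) return(0)
  max(vapply(common, oracle_depth, integer(1))) /
    max(oracle_depth(a), oracle_depth(b))
}

# Service total: per limitation the maximum over all targets of
# (q/4) * proximity, summed (or max-aggregated) over limitations.
oracle_service_score <- function(limitations, targets, agg = "sum_best") {
  per_lim <- vapply(seq_len(nrow(limitations)), function(i) {
    if (limitations$qualifier[i] == 0) return(0)
    max(vapply(targets, function(t) {
      (limitations$qualifier[i] / 4) * oracle_proximity(limitations$code[i], t)
    }, numeric(1)))
  }, numeric(1))
  if (length(per_lim) == 0) return(0)
  if (agg == "sum_best") sum(per_lim) else max(per_lim)
}

# Count-based signed-rank statistic: the number of positive Walsh
# averages (i <= j), counting zeros half. Equals the midrank-based sum
# of positive ranks on zero-free data.
oracle_walsh_W <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  W <- 0
  for (i in seq_len(n)) {
    for (j in i:n) {
      w <- d[i] + d[j]
      if (w > 0) W <- W + 1 else if (w == 0) W <- W + 0.5
    }
  }
  W
}

# Exact null moments of W for given absolute-rank vector, by enumerating
# all 2^n sign assignments.
oracle_sign_enumeration_moments <- function(r) {
  n <- length(r)
  ws <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    sum(r[signs])
  }, numeric(1))
  list(mean = mean(ws), var = mean((ws - mean(ws))^2), values = ws)
}

# Random valid ICF code drawn from a component, any depth.
random_icf_code <- function(components = c("b", "d"), max_depth = 4) {
  comp <- sample(components, 1)
  len <- sample(c(1, 3, 4, 5)[seq_len(max_depth)], 1)
  paste0(comp, paste0(sample(0:9, len, replace = TRUE), collapse = ""))
}

random_limitations <- function(n_max = 6) {
  n <- sample(1:n_max, 1)
  tibble::tibble(
    code = vapply(seq_len(n), function(i) random_icf_code(), character(1)),
    qualifier = sample(0:4, n, replace = TRUE)
  ) |> dplyr::distinct(code, .keep_all = TRUE)
}

random_service_targets <- function(n_max = 4) {
  unique(vapply(seq_len(sample(1:n_max, 1)),
                function(i) random_icf_code(), character(1)))
}
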