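random_pmf <- function(delta) {
  # valid distance pmf with some mass left for "absent"
  x <- runif(delta + 2)
  x <- x / sum(x)
  as_pmf <- x[seq_len(delta + 1)]
  structure(list(log_probs = log(as_pmf), delta = as.integer(delta),
                 log_present = log(sum(as_pmf))), class = "distance_pmf")
}

test_that("distance pmf telescopes over thresholds", {
  m <- frequency_model(c(1, 2, 3))
  cc <- with_length(m, 1)
  pmf <- distance_pmf(c(1, 2), 1, cc)
  # d'=0 impossible at n=1; d'=1 hits the boundary rule (delta' = |C|-1)
  expect_equal(exp(pmf$log_probs), c(0, 1))

  set.seed(21)
  for (i in 1:8) {
    mm <- random_model(6, 25)
    C <- sample(6, 4)
    delta <- 2
    pmf <- distance_pmf(C, delta, mm, mode = "exact")
    total <- exp(single_genome_pvalue(C, delta, mm, mode = "exact")$log_p)
    expect_equal(sum(exp(pmf$log_probs)), total, tolerance = 1e-9)
    expect_true(all(exp(pmf$log_probs) >= 0))
  }
})

test_that("sum-distance recurrence matches small closed cases", {
  expect_equal(
    exp(combine_sum_distance(list(c(0.1, 0.2)), 1, 1)$p$log_p), 0.3)
  expect_equal(
    exp(combine_sum_distance(list(c(0.1, 0.2), c(0.1, 0.2)), 1, 1)$p$log_p),
    0.05)
  # d_obs = k * delta leaves only the presence constraint
  expect_equal(
    exp(combine_sum_distance(list(c(0.1, 0.2), c(0.3, 0.4)), 2, 1)$p$log_p),
    0.3 * 0.7)
  expect_error(combine_sum_distance(list(c(0.1, 0.2)), 5, 1), "d_obs")
})

test_that("sum-distance recurrence equals the exhaustive oracle", {
  set.seed(22)
  for (i in 1:20) {
    k <- sample(1:5, 1)
    delta <- sample(0:3, 1)
    pmfs <- replicate(k, random_pmf(delta), simplify = FALSE)
    d_obs <- sample(0:(k * delta + 0), 1)
    got <- combine_sum_distance(pmfs, d_obs, delta)$p$log_p
    # oracle with quorum = k: all genomes present, sum of all <= d_obs
    ref <- combine_exhaustive_oracle(pmfs, k, d_obs)
    if (ref == 0) expect_equal(got, -Inf)
    else expect_equal(got, log(ref), tolerance = 1e-12)
  }
})

test_that("global bound equals the Poisson-binomial tail", {
  expect_equal(exp(combine_global_bound(list(0.5, 0.5), 2)$p$log_p), 0.25)
  expect_equal(exp(combine_global_bound(list(0.5, 0.5), 1)$p$log_p), 0.75)
  # independent enumeration over all success subsets
  pois_binom_tail <- function(p, q) {
    k <- length(p)
    tot <- 0
    for (msk in 0:(2^k - 1)) {
      on <- as.logical(bitwAnd(msk, 2^(0:(k - 1))))
      if (sum(on) >= q) tot <- tot + prod(ifelse(on, p, 1 - p))
    }
    tot
  }
  expect_equal(exp(combine_global_bound(list(0.1, 0.2, 0.3), 2)$p$log_p),
               pois_binom_tail(c(0.1, 0.2, 0.3), 2), tolerance = 1e-12)
  set.seed(23)
  for (i in 1:15) {
    k <- sample(2:12, 1)
    p <- runif(k)
    q <- sample(k, 1)
    got <- exp(combine_global_bound(as.list(p), q)$p$log_p)
    expect_equal(got, pois_binom_tail(p, q), tolerance = 1e-10)
  }
})

test_that("global bound survives extreme log-space magnitudes", {
  p_tiny <- lprob(log_p = -800)
  res <- combine_global_bound(list(p_tiny, p_tiny, p_tiny), 3)
  expect_equal(res$p$log_p, 3 * -800, tolerance = 1e-9)
})

test_that("individual bounds reward well-conserved occurrences", {
  set.seed(24)
  g <- sample(10, 40, replace = TRUE)
  models <- list(frequency_model(g), frequency_model(g), frequency_model(g))
  C <- sort(sample(10, 6))
  good <- combine_individual_bounds(c(0, 1, 4), C, models, delta = 4,
                                    quorum = 4, mode = "exact")
  poor <- combine_individual_bounds(c(3, 4, 4), C, models, delta = 4,
                                    quorum = 4, mode = "exact")
  expect_lt(good$p$log_p, poor$p$log_p)

  # all distances at delta' with all genomes present reduces to global bound
  all4 <- combine_individual_bounds(c(4, 4, 4), C, models, delta = 4,
                                    quorum = 4, mode = "exact")
  p4 <- single_genome_pvalue(C, 4, models[[1]], mode = "exact")
  glob <- combine_global_bound(list(p4, p4, p4), 3)
  expect_equal(all4$p$log_p, glob$p$log_p, tolerance = 1e-12)

  # single genome: p-value at its observed distance
  one <- combine_individual_bounds(2, C, models[1], delta = 4, quorum = 2,
                                   mode = "exact")
  expect_equal(one$p$log_p,
               single_genome_pvalue(C, 2, models[[1]], mode = "exact")$log_p,
               tolerance = 1e-12)
  expect_error(combine_individual_bounds(c(NA, NA), C, models[1:2], 4, 2),
               "no genome")
})

test_that("individual bounds are at most the global bound at delta'", {
  set.seed(25)
  for (i in 1:6) {
    k <- sample(2:4, 1)
    models <- replicate(k, random_model(8, 30), simplify = FALSE)
    C <- sample(8, 5)
    d <- sample(0:3, k, replace = TRUE)
    dp <- max(d)
    ind <- combine_individual_bounds(d, C, models, delta = 3, quorum = k + 1,
                                     mode = "exact")
    plist <- lapply(models, function(m)
      single_genome_pvalue(C, dp, m, mode = "exact"))
    glob <- combine_global_bound(plist, k)
    expect_lte(ind$p$log_p, glob$p$log_p + 1e-9)
  }
})

test_that("exhaustive oracle special cases", {
  set.seed(26)
  # quorum = 1, d_obs = delta: 1 - prod(1 - presence)
  pmfs <- replicate(3, random_pmf(2), simplify = FALSE)
  pres <- vapply(pmfs, function(pm) sum(exp(pm$log_probs)), numeric(1))
  expect_equal(combine_exhaustive_oracle(pmfs, 1, 2),
               1 - prod(1 - pres), tolerance = 1e-12)
  # k = 3, delta = 1: direct 27-outcome enumeration
  pmfs2 <- replicate(3, random_pmf(1), simplify = FALSE)
  probs <- lapply(pmfs2, function(pm) {
    pr <- exp(pm$log_probs)
    c(pr, 1 - sum(pr))
  })
  direct <- 0
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
    v <- c(a, b, cc)
    d <- v - 1
    pres_n <- sum(v <= 2)
    if (pres_n >= 2 && sum(sort(d[v <= 2])[1:2]) <= 1)
      direct <- direct + probs[[1]][a] * probs[[2]][b] * probs[[3]][cc]
  }
  expect_equal(combine_exhaustive_oracle(pmfs2, 2, 1), direct,
               tolerance = 1e-12)
})

test_that("combined p-values are monotone in quorum and observed distance", {
  set.seed(27)
  pmfs <- replicate(4, random_pmf(2), simplify = FALSE)
  by_quorum <- vapply(1:4, function(q)
    combine_exhaustive_oracle(pmfs, q, 4), numeric(1))
  expect_true(all(diff(by_quorum) <= 1e-12))
  by_dobs <- vapply(0:8, function(d)
    exp(combine_sum_distance(pmfs, d, 2)$p$log_p), numeric(1))
  expect_true(all(diff(by_dobs) >= -1e-12))
  plist <- list(lprob(log(0.2)), lprob(log(0.4)), lprob(log(0.6)))
  by_q2 <- vapply(1:3, function(q)
    combine_global_bound(plist, q)$p$log_p, numeric(1))
  expect_true(all(diff(by_q2) <= 1e-12))
})
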