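test_that("frequency model reproduces counts, pools and normalization", {
  m <- frequency_model(c(1, 1, 2, 3))
  comp <- m$components[[1]]
  expect_equal(comp$prob, c(0.5, 0.25, 0.25))
  expect_equal(length(comp$pools), 2)
  expect_equal(comp$pools[[1]]$freq, 1)
  expect_equal(comp$pools[[1]]$genes, c(2L, 3L))
  expect_equal(comp$pools[[2]]$genes, 1L)

  expect_equal(frequency_model(c(7, 7, 7))$components[[1]]$prob, 1)
  u <- frequency_model(1:6)$components[[1]]
  expect_equal(u$prob, rep(1 / 6, 6))
  expect_length(u$pools, 1)
  set.seed(2)
  for (i in 1:10) {
    comp <- random_model(sample(3:8, 1), sample(10:30, 1))$components[[1]]
    expect_equal(sum(comp$prob), 1, tolerance = 1e-12)
    expect_setequal(unlist(lapply(comp$pools, `[[`, "genes")), comp$ids)
  }
})

test_that("per-chromosome vs genome-wide frequencies differ as documented", {
  g <- genome(list(c(1, 1, 2), c(2, 3, 3, 3)))
  pc <- frequency_model(g)
  gw <- frequency_model(g, per_chromosome = FALSE)
  expect_equal(pc$components[[1]]$prob, c(2, 1) / 3)
  expect_equal(gw$components[[1]]$prob, c(2, 2, 3) / 7)
  expect_equal(gw$components[[1]]$n, 3)  # lengths stay per chromosome
})

test_that("p0 is the binomial composition probability", {
  expect_equal(p0(1, 2, 0.5), 0.5)
  expect_equal(p0(0, 3, 0.25), 0.421875)
  expect_equal(p0(2, 2, 1.0), 1.0)
})

test_that("missing-characters table matches string enumeration", {
  pm <- p_minus_table(c(1, 2), frequency_model(c(1, 2)), 2)
  expect_equal(pm["1", "1"], 1)  # one roll always misses one of two
  expect_equal(pm["1", "0"], 0)
  expect_equal(pm["2", "0"], 0.5)
  expect_equal(pm["2", "1"], 0.5)
  pm2 <- p_minus_table(c(1, 2), frequency_model(c(1, 1, 1, 2)), 2)
  expect_equal(pm2["2", "0"], 0.375)  # 2 * 0.75 * 0.25

  set.seed(3)
  for (i in 1:12) {
    sigma <- sample(2:6, 1)
    m <- random_model(sigma, sample(8:20, 1))
    comp <- m$components[[1]]
    C <- sample(sigma, sample(2:min(4, sigma), 1))
    r <- comp$prob[match(C, comp$ids)] / sum(comp$prob[match(C, comp$ids)])
    pm <- p_minus_table(C, m, 6)
    for (l in 0:6) {
      ref <- enum_missing(r, C, C, l)
      expect_equal(unname(pm[l + 1, ]), ref, tolerance = 1e-12)
    }
  }
})

test_that("cluster genes with zero probability are always missing", {
  pm <- p_minus_table(c(1, 2, 99), frequency_model(c(1, 2, 3)), 3)
  expect_equal(unname(pm[, "0"]), rep(0, 4))  # 99 can never be covered
  expect_equal(pm["2", "1"], 0.5)             # {1,2} both seen, 99 missing
  expect_warning(p_minus_table(c(98, 99), frequency_model(c(1, 2)), 2),
                 "zero probability")
})

test_that("pooled additional-characters table matches string enumeration", {
  # uniform complement {4,5}
  pp <- p_plus_exact_table(1:3, frequency_model(c(1, 2, 3, 4, 5)), 2, 2)
  expect_equal(pp["1", "1"], 1)
  expect_equal(pp["2", "1"], 0.5)
  expect_equal(pp["2", "2"], 0.5)
  # two pools: {4} freq 2, {5,6} freq 1; conditional probs (.5,.25,.25)
  m <- frequency_model(c(1, 1, 4, 4, 5, 6, 1, 1))
  pp2 <- p_plus_exact_table(1, m, 2, 3)
  ref <- enum_distinct(c(0.5, 0.25, 0.25), c(4, 5, 6), 2)
  expect_equal(unname(pp2["2", ]), ref, tolerance = 1e-12)

  set.seed(4)
  for (i in 1:12) {
    sigma <- sample(3:6, 1)
    m <- random_model(sigma, sample(8:20, 1))
    comp <- m$components[[1]]
    C <- sample(sigma, sample(1:(sigma - 1), 1))
    cbar <- setdiff(comp$ids, C)
    r <- comp$prob[match(cbar, comp$ids)]
    r <- r / sum(r)
    pp <- p_plus_exact_table(C, m, 5, length(cbar))
    for (l in 0:5) {
      ref <- enum_distinct(r, cbar, l)
      expect_equal(unname(pp[l + 1, ]), ref[seq_len(ncol(pp))],
                   tolerance = 1e-12)
    }
  }
})

test_that("empty complement admits only the empty string", {
  pp <- p_plus_exact_table(1:3, frequency_model(c(1, 2, 3)), 3, 1)
  expect_equal(pp["0", "0"], 1)
  expect_true(all(pp[2:4, ] == 0))
})

test_that("fast additional-characters approximation has the documented form", {
  m <- frequency_model(c(1, 1, 2, 3, 4, 5))
  gl <- global_p_plus_table(m, 4, 3)
  # d+ = 0 and empty-cluster limits
  expect_equal(p_plus_fast(integer(0), m, gl, 2, 2), gl["2", "2"])
  expect_equal(p_plus_fast(c(1, 2), m, gl, 3, 0), gl["3", "0"])
  # P(C) = 0.5: factor (1-0.5)^2
  expect_equal(p_plus_fast(c(1, 2), m, gl, 2, 2), 0.25 * gl["2", "2"])
})

test_that("interval distance distribution matches enumeration, both modes", {
  tb <- prob_tables(c(1, 2), frequency_model(c(1, 2, 3)), L_max = 2,
                    mode = "exact")
  expect_equal(p_L_d(1, 1, tb), 2 / 3)
  expect_equal(p_L_d(1, 3, tb), 1 / 3)
  expect_equal(p_L_d(1, 0, tb) + p_L_d(1, 2, tb), 0)
  tb2 <- prob_tables(c(1, 2), frequency_model(c(1, 2)), L_max = 2,
                     mode = "exact")
  expect_equal(p_L_d(2, 0, tb2), 0.5)
  expect_equal(p_L_d(2, 1, tb2), 0.5)

  set.seed(12)
  for (i in 1:8) {
    sigma <- sample(3:5, 1)
    m <- random_model(sigma, sample(6:15, 1))
    comp <- m$components[[1]]
    C <- sample(sigma + 1, sample(2:3, 1))
    L <- sample(2:4, 1)
    tb <- prob_tables(C, m, L_max = L, mode = "exact")
    ref <- enum_distance_distribution(comp$prob, comp$ids, C, L)
    got <- vapply(seq_along(ref) - 1, function(d) p_L_d(L, d, tb), numeric(1))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("distance distribution normalizes over its full support", {
  set.seed(13)
  for (i in 1:6) {
    sigma <- sample(4:9, 1)
    m <- random_model(sigma, sample(15:40, 1))
    C <- sample(sigma, sample(2:4, 1))
    tb <- prob_tables(C, m, L_max = 20, mode = "exact")
    sums <- rowSums(tb$pLd)
    expect_equal(unname(sums), rep(1, 20), tolerance = 1e-9)
    # fast mode: approximate normalization for low-mass clusters
    if (sum(m$components[[1]]$prob[match(C, m$components[[1]]$ids)],
            na.rm = TRUE) < 0.2) {
      tbf <- prob_tables(C, m, L_max = 20, mode = "fast")
      expect_equal(unname(rowSums(tbf$pLd)), rep(1, 20), tolerance = 0.1)
    }
  }
})

test_that("q is the cumulative distance probability", {
  tb <- prob_tables(c(1, 2), frequency_model(c(1, 2, 3)), L_max = 2,
                    mode = "exact")
  expect_equal(q_L_delta(1, 1, tb), 2 / 3)
  expect_equal(q_L_delta(1, 10, tb), 1)      # beyond max distance
  tb3 <- prob_tables(1:3, frequency_model(c(1, 2, 3)), L_max = 2,
                     mode = "exact")
  expect_equal(q_L_delta(2, 0, tb3), 0)      # L < |C| cannot cover C
  # q monotone in delta
  set.seed(14)
  m <- random_model(5, 12)
  tb4 <- prob_tables(c(1, 2, 3), m, L_max = 6, mode = "exact")
  for (L in 1:6) {
    qs <- vapply(0:6, function(d) q_L_delta(L, d, tb4), numeric(1))
    expect_true(all(diff(qs) >= -1e-12))
  }
})

test_that("boundary law: p-value is 1 at delta' >= |C|-1 with shared genes", {
  m <- frequency_model(c(1, 4, 4, 5))
  expect_equal(single_genome_pvalue(c(1, 2, 3), 2, m)$log_p, 0)
  expect_equal(single_genome_pvalue(c(1, 2, 3), 5, m)$log_p, 0)
  # disjoint cluster: p = 0 at any threshold
  expect_equal(single_genome_pvalue(c(8, 9), 5, m)$log_p, -Inf)
  expect_equal(single_genome_pvalue(c(8, 9), 0, m)$log_p, -Inf)
})

test_that("single-genome p-value is monotone in threshold and length", {
  set.seed(15)
  for (i in 1:6) {
    m <- random_model(6, 20)
    C <- sample(6, 4)
    lp <- vapply(0:3, function(d)
      single_genome_pvalue(C, d, m, mode = "exact")$log_p, numeric(1))
    expect_true(all(diff(lp) >= -1e-9))
    comp <- m$components[[1]]
    lpn <- vapply(c(5, 10, 20, 40), function(n) {
      cp <- comp; cp$n <- as.integer(n)
      single_genome_pvalue(C, 1, cp, mode = "exact")$log_p
    }, numeric(1))
    expect_true(all(diff(lpn) >= -1e-9))
  }
})

test_that("fast and exact modes yield nearly identical p-values", {
  set.seed(16)
  for (i in 1:10) {
    sigma <- sample(6:12, 1)
    m <- random_model(sigma, sample(30:80, 1))  # few pools, f small
    C <- sample(sigma, sample(2:4, 1))
    delta <- sample(0:(length(C) - 2), 1)
    pe <- single_genome_pvalue(C, delta, m, mode = "exact")$log_p
    pf <- single_genome_pvalue(C, delta, m, mode = "fast")$log_p
    if (is.finite(pe) && is.finite(pf))
      expect_lt(abs(exp(pf) / exp(pe) - 1), 0.1)
    else expect_equal(pe, pf)
  }
})

test_that("enumeration oracle agrees with closed cases and refuses huge ones", {
  expect_equal(exact_pvalue_oracle(frequency_model(c(1, 2)), 2, c(1, 2), 0),
               0.5)
  # n = 1 equals the direct interval probability
  m3 <- frequency_model(c(1, 2, 3))
  expect_equal(exact_pvalue_oracle(m3, 1, c(1, 2, 3), 1), 0)
  expect_equal(exact_pvalue_oracle(m3, 3, c(1, 2), 0),
               {  # manual count over 27 strings
         cnt <- 0
         for (x in 1:3) for (y in 1:3) for (z in 1:3) {
           S <- c(x, y, z); hit <- FALSE
           for (a in 1:3) for (b in a:3) {
             cs <- unique(S[a:b])
             if (setequal(cs, c(1, 2))) hit <- TRUE
           }
           if (hit) cnt <- cnt + 1
         }
         cnt / 27
       })
  expect_error(exact_pvalue_oracle(frequency_model(1:10), 10, c(1, 2), 0),
               "too large")
})

test_that("multi-chromosome p-values combine as 1 - prod(1 - p)", {
  g <- genome(list(c(1, 2, 3, 4), c(1, 2, 5, 6)))
  m <- frequency_model(g)
  C <- c(1, 2, 3)
  p_all <- single_genome_pvalue(C, 1, m, mode = "exact")
  p1 <- single_genome_pvalue(C, 1, m$components[[1]], mode = "exact")
  p2 <- single_genome_pvalue(C, 1, m$components[[2]], mode = "exact")
  expect_equal(p_all$log_1mp, p1$log_1mp + p2$log_1mp, tolerance = 1e-12)
})
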