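# Null model for a single genome and the dynamic programs behind the
# single-genome p-value: a random string of the same length as the genome,
# each position drawn independently with probability proportional to the
# gene's frequency.  The probability that an interval of length L has
# symmetric set distance d to a fixed cluster C factorises into
#   p(L,d) = sum_l sum_{d-} p0(l,L) * p-(l,d-) * p+(L-l, d-d-),
# where l positions carry cluster characters: p0 is binomial, p- is the
# distinct-outcomes ("dice") recurrence over the cluster alphabet, and p+
# is the same recurrence over the complement alphabet, pooled by gene
# frequency.

#' Frequency null model of a genome
#'
#' Builds the random gene-order null model: per-gene occurrence
#' probabilities proportional to observed counts, and gene pools grouped by
#' identical frequency (used by the pooled additional-characters
#' recurrence). Multi-chromosomal genomes are modelled per chromosome by
#' default: each chromosome gets its own probabilities and random-string
#' length. With `per_chromosome = FALSE`, probabilities come from
#' genome-wide counts while string lengths remain per chromosome.
#'
#' @param source A [genome()] or a bare integer vector (one chromosome).
#' @param per_chromosome Logical; compute gene frequencies per chromosome
#'   (default) or genome-wide.
#' @return An object of class `"frequency_model"`: a list with `genome_id`
#'   and `components`, one component per chromosome, each holding `n`, `ids`,
#'   `count`, `prob` and `pools` (list of `freq` + `genes`, ascending
#'   frequency).
#' @examples
#' m <- frequency_model(c(1, 1, 2, 3))
#' m$components[[1]]$prob
#' @export
frequency_model <- function(source, per_chromosome = TRUE) {
  g <- as_genome(source)
  make_comp <- function(counts, n) {
    ids <- as.integer(names(counts))
    o <- order(ids)
    ids <- ids[o]
    counts <- as.integer(counts)[o]
    freqs <- sort(unique(counts))
    pools <- lapply(freqs, function(f) list(freq = f, genes = ids[counts == f]))
    structure(list(n = n, ids = ids, count = counts,
                   prob = counts / sum(counts), pools = pools),
              class = "freq_component")
  }
  comps <- if (per_chromosome) {
    lapply(g$chromosomes, function(S) make_comp(table(S), length(S)))
  } else {
    cnt <- table(unlist(g$chromosomes))
    lapply(g$chromosomes, function(S) make_comp(cnt, length(S)))
  }
  structure(list(genome_id = g$id, per_chromosome = per_chromosome,
                 components = comps),
            class = "frequency_model")
}

#' @export
print.frequency_model <- function(x, ...) {
  cat(sprintf("<frequency_model> genome '%s': %d chromosome(s), %s frequencies\n",
              x$genome_id, length(x$components),
              if (x$per_chromosome) "per-chromosome" else "genome-wide"))
  for (nm in names(x$components)) {
    comp <- x$components[[nm]]
    cat(sprintf("  %s: n = %d, sigma = %d, f = %d frequency pools\n",
                nm, comp$n, length(comp$ids), length(comp$pools)))
  }
  invisible(x)
}

# Resolve a model argument to a single freq_component.
as_component <- function(model) {
  if (inherits(model, "freq_component")) return(model)
  if (inherits(model, "genome") || is.numeric(model))
    model <- frequency_model(model)
  if (inherits(model, "frequency_model")) {
    if (length(model$components) != 1L)
      stop("this operation needs a single-chromosome model; ",
           "pass model$components[[i]]")
    return(model$components[[1L]])
  }
  stop("cannot interpret 'model'")
}

as_model <- function(model) {
  if (inherits(model, "frequency_model")) return(model)
  if (inherits(model, "freq_component"))
    return(structure(list(genome_id = "component", per_chromosome = TRUE,
                          components = list(chr1 = model)),
                     class = "frequency_model"))
  frequency_model(model)
}

comp_prob <- function(comp, genes) {
  p <- comp$prob[match(genes, comp$ids)]
  p[is.na(p)] <- 0
  p
}

#' Interval composition probability p0(l, L)
#'
#' Probability that exactly `l` of `L` independent positions carry cluster
#' characters, the remainder complement characters: binomial with success
#' probability `PC`, the total probability mass of the cluster genes.
#'
#' @param l,L Integers, `0 <= l <= L`.
#' @param PC Probability mass of the cluster gene set.
#' @export
p0 <- function(l, L, PC) stats::dbinom(l, L, PC)

# Distinct-outcomes recurrence: rolling l dice over an alphabet with given
# (conditional) probabilities r (sum(r) = 1 unless degenerate), probability
# that exactly h distinct symbols appear, for one symbol added at a time:
#   p[z,l,h] = B(0; l, rho_z) p[z-1,l,h]
#            + sum_{j>=1} B(j; l, rho_z) p[z-1,l-j,h-1],
# rho_z the probability of symbol z conditional on symbols 1..z.
# Returns matrix (l_max+1) x (Z+1): rows l = 0..l_max, cols h = 0..Z.
distinct_outcomes_dp <- function(r, l_max) {
  Z <- length(r)
  prev <- matrix(0, l_max + 1L, Z + 1L)
  prev[1L, 1L] <- 1
  if (Z == 0L) return(prev)
  R <- 0
  for (z in seq_len(Z)) {
    R <- R + r[z]
    rho <- if (R > 0) r[z] / R else 0
    cur <- matrix(0, l_max + 1L, Z + 1L)
    for (l in 0:l_max) {
      db <- stats::dbinom(0:l, l, rho)
      cur[l + 1L, ] <- db[1L] * prev[l + 1L, ]
      if (l > 0L) for (j in seq_len(l)) {
        if (db[j + 1L] == 0) next
        cur[l + 1L, 2:(Z + 1L)] <- cur[l + 1L, 2:(Z + 1L)] +
          db[j + 1L] * prev[l - j + 1L, 1:Z]
      }
    }
    prev <- cur
  }
  prev
}

#' Missing-characters table p-(l, d-)
#'
#' Probability that a random string of length `l` over the cluster alphabet
#' (conditional probabilities `P(c)/P(C)`) is missing exactly `d-` of the
#' `|C|` cluster characters. Cluster genes absent from the genome are kept
#' with conditional probability 0, so they always count as missing.
#'
#' @param C Cluster gene-id set.
#' @param model A [frequency_model()] (single chromosome) or component.
#' @param l_max Largest string length needed (>= 1).
#' @return Matrix with rows `l = 0..l_max` and columns `d- = 0..|C|`.
#' @export
p_minus_table <- function(C, model, l_max) {
  comp <- as_component(model)
  C <- sort(unique(as.integer(C)))
  Z <- length(C)
  stopifnot(l_max >= 1)
  r <- comp_prob(comp, C)
  PC <- sum(r)
  if (PC == 0) {
    warning("cluster has zero probability mass; all characters always missing")
    out <- matrix(0, l_max + 1L, Z + 1L)
    out[, Z + 1L] <- 1
  } else {
    ph <- distinct_outcomes_dp(r / PC, l_max)
    out <- ph[, (Z + 1L):1L, drop = FALSE]  # d- = Z - h
  }
  dimnames(out) <- list(l = 0:l_max, d_minus = 0:Z)
  out
}

# Pooled distinct-outcomes DP over an alphabet partitioned into pools of
# equiprobable genes.  'pools' is a list of (weight, size): weight = total
# (conditional) probability mass of the pool, size = number of genes in it.
# Returns matrix (l_max+1) x (d_max+1): rows l, cols h = number of distinct
# genes drawn, truncated at d_max (h only ever increases, so truncation is
# safe).
pooled_distinct_dp <- function(pools, l_max, d_max) {
  prev <- matrix(0, l_max + 1L, d_max + 1L)
  prev[1L, 1L] <- 1
  R <- 0
  for (pool in pools) {
    m <- pool$size
    if (m == 0L) next
    R <- R + pool$weight
    rho <- if (R > 0) pool$weight / R else 0
    # within-pool occupancy: j uniform draws from m genes -> h' distinct
    hcap <- min(m, d_max)
    u <- matrix(0, l_max + 1L, hcap + 1L)
    u[1L, 1L] <- 1
    if (l_max > 0L) for (j in seq_len(l_max)) {
      for (h in seq_len(min(j, hcap))) {
        u[j + 1L, h + 1L] <- u[j, h + 1L] * h / m +
          u[j, h] * (m - h + 1L) / m
      }
    }
    cur <- matrix(0, l_max + 1L, d_max + 1L)
    for (l in 0:l_max) {
      db <- stats::dbinom(0:l, l, rho)
      cur[l + 1L, ] <- db[1L] * prev[l + 1L, ]
      if (l > 0L) for (j in seq_len(l)) {
        if (db[j + 1L] == 0) next
        for (hp in seq_len(min(j, hcap))) {
          if (u[j + 1L, hp + 1L] == 0) next
          cur[l + 1L, (hp + 1L):(d_max + 1L)] <-
            cur[l + 1L, (hp + 1L):(d_max + 1L)] +
            db[j + 1L] * u[j + 1L, hp + 1L] *
            prev[l - j + 1L, 1:(d_max + 1L - hp)]
        }
      }
    }
    prev <- cur
  }
  prev
}

#' Additional-characters table p+(l', d+), exact pooled recurrence
#'
#' Probability that a random string of length `l'` over the complement
#' alphabet (all genes not in `C`, conditional probabilities renormalised)
#' contains exactly `d+` distinct characters. Genes are pooled by occurrence
#' frequency; genes within a pool are equiprobable and need not be
#' distinguished.
#'
#' @inheritParams p_minus_table
#' @param d_max Largest number of additional characters needed.
#' @return Matrix with rows `l' = 0..l_max` and columns `d+ = 0..d_max`.
#' @export
p_plus_exact_table <- function(C, model, l_max, d_max) {
  comp <- as_component(model)
  C <- unique(as.integer(C))
  pools <- lapply(comp$pools, function(pool) {
    genes <- setdiff(pool$genes, C)
    list(size = length(genes),
         weight = length(genes) * pool$freq / comp$n)
  })
  W <- sum(vapply(pools, `[[`, numeric(1), "weight"))
  out <- matrix(0, l_max + 1L, d_max + 1L)
  if (W == 0) {
    out[1L, 1L] <- 1  # empty complement: only the empty string qualifies
  } else {
    pools <- lapply(pools, function(p) { p$weight <- p$weight / W; p })
    out <- pooled_distinct_dp(pools, l_max, d_max)
  }
  dimnames(out) <- list(l_prime = 0:l_max, d_plus = 0:d_max)
  out
}

#' Genome-wide additional-characters table P+(l', d+)
#'
#' The fast preprocessing variant: the pooled recurrence run once per
#' genome over the complete alphabet (complement set to the whole of Sigma),
#' reusable for every cluster via [p_plus_fast()].
#'
#' @inheritParams p_plus_exact_table
#' @return Matrix with rows `l' = 0..l_max`, columns `d+ = 0..d_max`.
#' @export
global_p_plus_table <- function(model, l_max, d_max) {
  p_plus_exact_table(integer(0), model, l_max, d_max)
}

#' Fast approximation of p+(l', d+)
#'
#' Approximates the cluster-specific additional-characters probability from
#' the genome-wide table, correcting for the cluster's own probability mass:
#' `p+(l', d+) ~ (1 - P(C))^{d+} * P+(l', d+)`.
#'
#' @inheritParams p_plus_exact_table
#' @param P_plus_global Table from [global_p_plus_table()].
#' @param l_prime,d_plus Scalar indices.
#' @export
p_plus_fast <- function(C, model, P_plus_global, l_prime, d_plus) {
  comp <- as_component(model)
  PC <- sum(comp_prob(comp, unique(C)))
  (1 - PC)^d_plus * P_plus_global[l_prime + 1L, d_plus + 1L]
}

#' Interval distance distribution tables
#'
#' Precomputes, for one cluster and one chromosome model, the full tables
#' behind `p(L,d)`: the missing-characters table, the additional-characters
#' table (exact pooled recurrence, or the fast genome-wide approximation),
#' and the resulting distance distribution for intervals of length
#' `1..L_max` over the full distance support.
#'
#' @inheritParams p_minus_table
#' @param L_max Largest interval length tabulated (defaults to the
#'   chromosome length).
#' @param mode `"exact"` for the pooled per-cluster recurrence, `"fast"` for
#'   the genome-wide approximation.
#' @param delta Distance threshold recorded for display; the tables cover
#'   the full support regardless.
#' @return An object of class `"prob_tables"` with elements `p_minus`,
#'   `p_plus`, `pLd` (matrix `L` by `d`), `PC`, `mode`.
#' @seealso [p_L_d()], [q_L_delta()]
#' @export
prob_tables <- function(C, model, delta = NULL, L_max = NULL,
                        mode = c("exact", "fast")) {
  mode <- match.arg(mode)
  comp <- as_component(model)
  C <- sort(unique(as.integer(C)))
  Z <- length(C)
  if (is.null(L_max)) L_max <- comp$n
  PC <- sum(comp_prob(comp, C))
  dplus_max <- if (mode == "fast") length(comp$ids) else
    length(setdiff(comp$ids, C))
  dplus_max <- max(min(L_max, dplus_max), 0L)
  pm <- p_minus_table(C, comp, L_max)
  pp <- if (mode == "exact") {
    p_plus_exact_table(C, comp, L_max, dplus_max)
  } else {
    (1 - PC)^matrix(0:dplus_max, L_max + 1L, dplus_max + 1L, byrow = TRUE) *
      global_p_plus_table(comp, L_max, dplus_max)
  }
  d_sup <- Z + dplus_max
  pLd <- matrix(0, L_max, d_sup + 1L)
  for (L in seq_len(L_max)) {
    p0v <- stats::dbinom(0:L, L, PC)
    for (l in 0:L) {
      if (p0v[l + 1L] == 0) next
      for (dm in 0:Z) {
        if (pm[l + 1L, dm + 1L] == 0) next
        idx <- dm + 0:dplus_max
        pLd[L, idx + 1L] <- pLd[L, idx + 1L] +
          p0v[l + 1L] * pm[l + 1L, dm + 1L] * pp[L - l + 1L, ]
      }
    }
  }
  dimnames(pLd) <- list(L = 1:L_max, d = 0:d_sup)
  structure(list(cluster = C, delta = delta, mode = mode, PC = PC,
                 p_minus = pm, p_plus = pp, pLd = pLd, L_max = L_max),
            class = "prob_tables")
}

#' Interval distance probability p(L, d)
#'
#' Probability that a random interval of length `L` has symmetric set
#' distance exactly `d` to the cluster.
#'
#' @param L Interval length (`1 <= L <= L_max` of the tables).
#' @param d Distance (probability 0 outside the tabulated support).
#' @param tables A [prob_tables()] object.
#' @export
p_L_d <- function(L, d, tables) {
  stopifnot(inherits(tables, "prob_tables"), L >= 1, L <= tables$L_max, d >= 0)
  if (d + 1L > ncol(tables$pLd)) return(0)
  tables$pLd[L, d + 1L]
}

#' Cumulative distance probability q(L, delta)
#'
#' Probability that a random interval of length `L` has symmetric set
#' distance at most `delta` to the cluster: `q(L,delta) = sum_{d<=delta}
#' p(L,d)`, clamped to `[0,1]`.
#'
#' @inheritParams p_L_d
#' @param delta Distance threshold (>= 0).
#' @export
q_L_delta <- function(L, delta, tables) {
  stopifnot(inherits(tables, "prob_tables"), delta >= 0)
  up <- min(delta + 1L, ncol(tables$pLd))
  min(1, sum(tables$pLd[L, seq_len(up)]))
}

# q(L, delta) for L = 1..L_max, computed directly (no full-support table):
# q(L) = sum_l p0(l,L) sum_{d-<=delta} p-(l,d-) * cumP+(L-l, delta-d-).
q_delta_vec <- function(C, comp, delta, L_max, mode, pplus_global = NULL) {
  C <- sort(unique(as.integer(C)))
  Z <- length(C)
  PC <- sum(comp_prob(comp, C))
  dmx <- min(delta, L_max)
  pm <- p_minus_table(C, comp, L_max)
  pp <- if (mode == "exact") {
    p_plus_exact_table(C, comp, L_max, dmx)
  } else {
    gl <- pplus_global
    if (is.null(gl) || nrow(gl) < L_max + 1L || ncol(gl) < dmx + 1L)
      gl <- global_p_plus_table(comp, L_max, dmx)
    (1 - PC)^matrix(0:dmx, L_max + 1L, dmx + 1L, byrow = TRUE) *
      gl[1:(L_max + 1L), 1:(dmx + 1L), drop = FALSE]
  }
  ppcum <- pp
  if (ncol(ppcum) > 1L)
    ppcum <- t(apply(pp, 1L, cumsum))
  q <- numeric(L_max)
  for (L in seq_len(L_max)) {
    p0v <- stats::dbinom(0:L, L, PC)
    inner <- numeric(L + 1L)
    for (dm in 0:min(delta, Z)) {
      rem <- delta - dm
      if (rem > dmx) rem <- dmx
      # rows of ppcum for l' = L-l, l = 0..L -> L+1 down to 1
      inner <- inner + pm[1:(L + 1L), dm + 1L] *
        ppcum[(L + 1L):1L, rem + 1L]
    }
    q[L] <- min(1, sum(p0v * inner))
  }
  q
}

# Per-chromosome log(1 - p): sum over L of (n-L+1) * log1p(-q(L,delta)),
# with adaptive truncation of the L loop once the remaining terms cannot
# contribute relative weight 'tol'.
chrom_log_1mp <- function(C, comp, delta, mode, tol, pplus_global = NULL) {
  C <- sort(unique(as.integer(C)))
  Z <- length(C)
  n <- comp$n
  if (sum(comp_prob(comp, C) > 0) < Z - delta)
    return(0)  # cluster can never be covered to within delta: p = 0
  L_cap <- min(n, max(4L * (Z + delta) + 20L, 60L))
  repeat {
    q <- q_delta_vec(C, comp, delta, L_cap, mode, pplus_global)
    terms <- (n - seq_len(L_cap) + 1) * log1p(-pmin(q, 1))
    if (L_cap == n) return(sum(terms))
    S <- sum(terms)
    tail_idx <- (L_cap - 7L):L_cap
    tail_w <- max((n - tail_idx + 1) * q[tail_idx])
    peaked <- q[L_cap] < max(q)
    if (L_cap > Z + delta && peaked &&
        (S == -Inf || tail_w < tol * max(abs(S), 1e-300) / 10))
      return(S)
    L_cap <- min(n, 2L * L_cap)
  }
}

#' Single-genome p-value of a gene cluster
#'
#' Probability that a random genome (random gene order null model) contains
#' at least one delta-location of the cluster, i.e. an interval whose
#' character set is within symmetric set distance `delta_prime` of `C` and
#' intersects `C`. Computed as
#' `1 - prod_L (1 - q(L, delta'))^(n-L+1)` in log space, assuming
#' independence of interval occurrences. For `delta_prime >= |C| - 1` the
#' p-value is exactly 1 whenever a cluster gene occurs in the genome, and 0
#' otherwise. Multi-chromosomal models combine per-chromosome results as
#' `1 - prod(1 - p_chrom)`.
#'
#' @param C Cluster gene-id set.
#' @param delta_prime Distance threshold (>= 0).
#' @param model A [frequency_model()], [genome()], component or integer
#'   vector.
#' @param mode `"fast"` (genome-wide additional-characters table, default) or
#'   `"exact"` (pooled per-cluster recurrence).
#' @param tol Relative contribution below which remaining terms of the
#'   interval-length sum are truncated.
#' @param pplus_global Optional precomputed [global_p_plus_table()] (single
#'   chromosome models only), reused across clusters.
#' @return An [lprob()]: the p-value in log space.
#' @examples
#' single_genome_pvalue(c(1, 2), 1, frequency_model(c(1, 2, 3)))
#' @export
single_genome_pvalue <- function(C, delta_prime, model,
                                 mode = c("fast", "exact"), tol = 1e-12,
                                 pplus_global = NULL) {
  mode <- match.arg(mode)
  model <- as_model(model)
  C <- sort(unique(as.integer(C)))
  stopifnot(length(C) >= 1, delta_prime >= 0)
  if (delta_prime >= length(C) - 1L) {
    present <- any(vapply(model$components,
                          function(cp) any(comp_prob(cp, C) > 0), logical(1)))
    return(if (present) lprob(log_p = 0) else lprob(log_p = -Inf))
  }
  log_1mp <- sum(vapply(model$components, function(cp)
    chrom_log_1mp(C, cp, delta_prime, mode, tol, pplus_global), numeric(1)))
  lprob(log_1mp = log_1mp)
}

#' Exact single-genome p-value by string enumeration
#'
#' Independent test oracle for the interval-independence assumption:
#' enumerates all `sigma^n` strings over the model alphabet, weighted by
#' their probabilities, and reports the exact probability that a string
#' contains a delta-location of `C`. Refuses instances with more than 1e7
#' strings.
#'
#' @inheritParams single_genome_pvalue
#' @param n String length.
#' @param delta Distance threshold.
#' @return Exact probability (plain numeric).
#' @export
exact_pvalue_oracle <- function(model, n, C, delta) {
  comp <- as_component(model)
  C <- unique(as.integer(C))
  stopifnot(n >= 1, delta >= 0)
  in_c <- comp$ids %in% C
  cpp_exact_oracle(comp$prob, as.integer(n), in_c, length(C),
                   as.integer(delta))
}
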