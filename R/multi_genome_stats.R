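# Combining per-genome probabilities into one cluster p-value: the
# sum-distance recurrence, the global distance bound (Poisson-binomial
# quorum recurrence), and the individual distance bounds method.  All
# arithmetic is in log space: combined p-values for well-conserved clusters
# in many genomes underflow double precision by hundreds of orders of
# magnitude.

combined_result <- function(log_p, method, ...) {
  structure(c(list(p = lprob(log_p = log_p), method = method), list(...)),
            class = "combined_result")
}

#' @export
print.combined_result <- function(x, ...) {
  cat(sprintf("<combined_result> method = %s\n", x$method))
  print(x$p)
  invisible(x)
}

#' Distribution of the best-occurrence distance in one genome
#'
#' Probability mass function over `d' = 0..delta` of the distance between a
#' cluster and its best approximate occurrence in a random genome: entry
#' `d'` equals the probability of a `d'`-location existing minus that of a
#' `(d'-1)`-location. The entries sum to the probability of any
#' delta-location; the remainder is the probability of no occurrence.
#'
#' @inheritParams single_genome_pvalue
#' @param delta Distance threshold (>= 0).
#' @return An object of class `"distance_pmf"` with `log_probs` (log-scale
#'   vector over `d' = 0..delta`) and `delta`.
#' @export
distance_pmf <- function(C, delta, model, mode = c("fast", "exact")) {
  mode <- match.arg(mode)
  stopifnot(delta >= 0)
  lp <- vapply(0:delta, function(d)
    single_genome_pvalue(C, d, model, mode)$log_p, numeric(1))
  log_probs <- numeric(delta + 1L)
  log_probs[1L] <- lp[1L]
  if (delta > 0) for (d in seq_len(delta)) {
    a <- lp[d + 1L]; b <- lp[d]
    if (b > a) {  # rounding: P(d'-location) must be >= P((d'-1)-location)
      if (exp(b) - exp(a) > 1e-9)
        warning(sprintf("pmf entry %d negative beyond tolerance; clamped", d))
      log_probs[d + 1L] <- -Inf
    } else {
      log_probs[d + 1L] <- logdiffexp(a, b)
    }
  }
  structure(list(log_probs = log_probs, delta = as.integer(delta),
                 log_present = lp[delta + 1L]),
            class = "distance_pmf")
}

as_distance_pmf <- function(x) {
  if (inherits(x, "distance_pmf")) return(x)
  x <- as.numeric(x)  # plain probability vector over d' = 0..delta
  stopifnot(all(x >= 0), sum(x) <= 1 + 1e-9)
  structure(list(log_probs = log(x), delta = length(x) - 1L,
                 log_present = log(sum(x))),
            class = "distance_pmf")
}

#' Combine genomes by total distance (sum-distance recurrence)
#'
#' Probability that, in random genomes, the cluster has a delta-location in
#' every genome and the distances sum to at most `d_obs`. Applicable when a
#' delta-location was observed in all non-reference genomes. The recurrence
#' runs over genomes and partial distance sums in `O(k^2 delta^2)`.
#'
#' @param pmfs List of [distance_pmf()] objects (or plain probability
#'   vectors over `d' = 0..delta`), one per non-reference genome.
#' @param d_obs Observed sum of best distances.
#' @param delta Per-genome distance threshold.
#' @return A `combined_result` with the p-value in log space.
#' @examples
#' combine_sum_distance(list(c(0.1, 0.2)), d_obs = 1, delta = 1)
#' @export
combine_sum_distance <- function(pmfs, d_obs, delta) {
  pmfs <- lapply(pmfs, as_distance_pmf)
  k <- length(pmfs)
  stopifnot(k >= 1, delta >= 0)
  if (d_obs > k * delta) stop("d_obs exceeds k * delta")
  M <- c(0, rep(-Inf, d_obs))  # log M[0, ]
  for (i in seq_len(k)) {
    lp <- pmfs[[i]]$log_probs
    Mi <- vapply(0:d_obs, function(d) {
      dd <- 0:min(d, delta)
      logsumexp(lp[dd + 1L] + M[d - dd + 1L])
    }, numeric(1))
    M <- Mi
  }
  combined_result(logsumexp(M), "sum_distance", k_used = k,
                  d_obs = as.integer(d_obs))
}

#' Combine genomes by occurrence count (global distance bound)
#'
#' Poisson-binomial recurrence over genomes: probability that at least
#' `quorum` of the genomes contain a location at the shared threshold, given
#' per-genome occurrence probabilities. `O(k^2)` in log space.
#'
#' @param p_list List of per-genome probabilities: [lprob()] objects or
#'   plain numerics in `[0,1]`.
#' @param quorum Minimum number of the listed genomes that must contain a
#'   location (for a cluster quorum `k'` including the reference genome,
#'   pass `k' - 1`).
#' @return A `combined_result`.
#' @examples
#' combine_global_bound(list(0.5, 0.5), quorum = 2)
#' @export
combine_global_bound <- function(p_list, quorum) {
  p_list <- lapply(p_list, function(p) if (inherits(p, "lprob")) p else
    lprob(log_p = log(as.numeric(p))))
  k <- length(p_list)
  stopifnot(k >= 1, quorum >= 1, quorum <= k)
  Q <- c(0, rep(-Inf, k))  # log Q[i, j=0], i = 0..k
  for (j in seq_len(k)) {
    lp <- p_list[[j]]$log_p
    l1 <- p_list[[j]]$log_1mp
    Qn <- rep(-Inf, k + 1L)
    Qn[1L] <- l1 + Q[1L]
    for (i in seq_len(j))
      Qn[i + 1L] <- logsumexp(c(l1 + Q[i + 1L], lp + Q[i]))
    Q <- Qn
  }
  combined_result(logsumexp(Q[(quorum:k) + 1L]), "global_bound",
                  k_used = k, quorum = as.integer(quorum))
}

#' Combine genomes with per-genome distance thresholds
#'
#' The individual distance bounds method: each genome with an observed
#' delta-location contributes its single-genome p-value at that genome's
#' observed distance; genomes without one contribute the p-value at
#' `delta' = max` observed distance. The heterogeneous probabilities are
#' combined with the Poisson-binomial quorum recurrence, requiring at least
#' `quorum - 1` of the non-reference genomes to succeed. Unlike the global
#' bound, this distinguishes a cluster observed at distances (0, 1, 4) from
#' one observed at (3, 4, 4).
#'
#' @param profile Observed best distances for the non-reference genomes:
#'   either a cluster record from [find_reference_clusters()] or a numeric
#'   vector with `NA` for genomes without a delta-location.
#' @param C Cluster gene-id set.
#' @param models List of [frequency_model()] objects for the non-reference
#'   genomes, aligned with `profile`.
#' @param delta Search distance threshold (>= all observed distances).
#' @param quorum Cluster quorum `k'` including the reference genome.
#' @inheritParams single_genome_pvalue
#' @return A `combined_result`.
#' @export
combine_individual_bounds <- function(profile, C, models, delta, quorum,
                                      mode = c("fast", "exact")) {
  mode <- match.arg(mode)
  d <- if (is.list(profile) && !is.null(profile$distances))
    profile$distances else profile
  d <- as.numeric(d)
  k <- length(models)
  stopifnot(length(d) == k, quorum >= 2, quorum - 1 <= k)
  present <- !is.na(d)
  if (!any(present)) stop("no genome has a delta-location")
  if (any(d[present] > delta)) stop("observed distance exceeds delta")
  delta_prime <- max(d[present])
  thr <- ifelse(present, d, delta_prime)
  p_list <- lapply(seq_len(k), function(j)
    single_genome_pvalue(C, thr[j], models[[j]], mode))
  res <- combine_global_bound(p_list, quorum - 1L)
  combined_result(res$p$log_p, "individual_bounds", k_used = k,
                  quorum = as.integer(quorum),
                  delta_prime = as.integer(delta_prime),
                  thresholds = as.integer(thr))
}

#' Exhaustive distance-vector combination oracle
#'
#' Exact probability that at least `quorum` genomes contain a
#' delta-location and the smallest `quorum` observed distances sum to at
#' most `d_obs`, by full enumeration of all `(delta+2)^k` outcome vectors
#' (distances `0..delta` plus "absent" per genome). Independent test oracle
#' for the combination schemes; refuses instances above 1e7 vectors.
#'
#' @inheritParams combine_sum_distance
#' @param quorum Minimum number of the listed genomes with a delta-location.
#' @return Exact probability (plain numeric).
#' @export
combine_exhaustive_oracle <- function(pmfs, quorum, d_obs) {
  pmfs <- lapply(pmfs, as_distance_pmf)
  k <- length(pmfs)
  delta <- pmfs[[1L]]$delta
  stopifnot(all(vapply(pmfs, `[[`, integer(1), "delta") == delta),
            quorum >= 1, quorum <= k, d_obs >= 0)
  if ((delta + 2)^k > 1e7) stop("instance too large for exhaustive oracle")
  outc <- lapply(pmfs, function(pm) {
    pr <- exp(pm$log_probs)
    c(pr, max(0, 1 - sum(pr)))  # outcomes: d' = 0..delta, then "absent"
  })
  total <- 0
  vec <- integer(k)  # outcome index per genome, 0..delta+1
  recurse <- function(i, w) {
    if (w == 0) return()
    if (i > k) {
      dist <- vec[vec <= delta]
      if (length(dist) >= quorum &&
          sum(sort(dist)[seq_len(quorum)]) <= d_obs)
        total <<- total + w
      return()
    }
    for (o in 0:(delta + 1L)) {
      vec[i] <<- o
      recurse(i + 1L, w * outc[[i]][o + 1L])
    }
  }
  recurse(1L, 1)
  total
}
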