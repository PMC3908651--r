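# Monte-Carlo validation of the calculated p-values: empirical p-values
# under the null, Agresti-Coull confidence intervals for the hit
# proportions, and log-log agreement statistics between calculated and
# empirical values.

#' Draw a random genome from a frequency model
#'
#' I.i.d. positions with the model's per-gene probabilities; the null model
#' the p-value calculation assumes.
#'
#' @param model A [frequency_model()] (single chromosome) or component.
#' @param n Genome length.
#' @param seed Optional RNG seed (`set.seed()` is called when given).
#' @return A [genome()] with one chromosome.
#' @export
sample_random_genome <- function(model, n, seed = NULL) {
  comp <- as_component(model)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  genome(comp$ids[sample.int(length(comp$ids), n, replace = TRUE,
                             prob = comp$prob)],
         id = "random")
}

#' Agresti-Coull binomial confidence interval
#'
#' Adjusted-Wald interval for a binomial proportion: with `z` the two-sided
#' normal quantile, `N~ = N + z^2`, `p~ = (x + z^2/2) / N~` and half-width
#' `z * sqrt(p~ (1 - p~) / N~)`; bounds clamped to `[0, 1]`. Used to judge
#' whether calculated p-values are compatible with Monte-Carlo hit counts,
#' including the zero-hit case.
#'
#' @param x Number of successes (`0 <= x <= N`).
#' @param N Number of trials.
#' @param confidence Two-sided confidence level.
#' @return Named numeric `c(low, high)`.
#' @examples
#' agresti_coull(0, 1e10)
#' @export
agresti_coull <- function(x, N, confidence = 0.95) {
  stopifnot(N >= 1, x >= 0, x <= N)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  Nt <- N + z^2
  pt <- (x + z^2 / 2) / Nt
  hw <- z * sqrt(pt * (1 - pt) / Nt)
  c(low = max(0, pt - hw), high = min(1, pt + hw))
}

#' Empirical p-value of a cluster by Monte-Carlo simulation
#'
#' Draws random genomes from the null model and counts those containing at
#' least one interval within symmetric set distance `delta_prime` of the
#' cluster (with non-empty intersection). The scan maintains missing/extra
#' character counts incrementally per left endpoint and exits on the first
#' hit.
#'
#' @inheritParams single_genome_pvalue
#' @param n Random genome length (defaults to the model's).
#' @param draws Number of random genomes.
#' @param seed Optional RNG seed.
#' @return An object of class `"validation_record"`: hit count `x`, `draws`,
#'   `empirical_p`, Agresti-Coull bounds `ac_low`/`ac_high`, the calculated
#'   `log_p_calc` for the same setting, `delta_prime` and `seed`.
#' @export
empirical_pvalue <- function(C, delta_prime, model, n = NULL, draws,
                             seed = NULL, mode = c("fast", "exact")) {
  mode <- match.arg(mode)
  comp <- as_component(model)
  C <- sort(unique(as.integer(C)))
  if (is.null(n)) n <- comp$n
  stopifnot(draws >= 1, n >= 1, delta_prime >= 0)
  if (!is.null(seed)) set.seed(seed)
  in_c <- comp$ids %in% C
  x <- cpp_empirical_hits(cumsum(comp$prob), as.integer(n), draws, in_c,
                          length(C), as.integer(delta_prime))
  comp_n <- comp
  comp_n$n <- as.integer(n)
  calc <- single_genome_pvalue(C, delta_prime, comp_n, mode)
  ac <- agresti_coull(x, draws)
  structure(list(cluster = C, delta_prime = as.integer(delta_prime),
                 x = x, draws = draws, empirical_p = x / draws,
                 ac_low = ac[["low"]], ac_high = ac[["high"]],
                 log_p_calc = calc$log_p, n = as.integer(n),
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "validation_record")
}

#' @export
print.validation_record <- function(x, ...) {
  cat(sprintf(
    "<validation_record> |C| = %d, delta' = %d: calc p = %.4g, emp p = %.4g (%g/%g), 95%% AC [%.3g, %.3g]\n",
    length(x$cluster), x$delta_prime, exp(x$log_p_calc), x$empirical_p,
    x$x, x$draws, x$ac_low, x$ac_high))
  invisible(x)
}

records_df <- function(records) {
  if (is.data.frame(records)) return(records)
  do.call(rbind, lapply(records, function(r)
    data.frame(size = length(r$cluster), delta_prime = r$delta_prime,
               x = r$x, draws = r$draws, empirical_p = r$empirical_p,
               ac_low = r$ac_low, ac_high = r$ac_high,
               log_p_calc = r$log_p_calc, n = r$n)))
}

#' Log-log agreement between calculated and empirical p-values
#'
#' Pearson correlation and coefficient of determination of the
#' (log calculated, log empirical) pairs, with the calculated values as
#' predictions: `R^2 = 1 - sum((y - x)^2) / sum((y - ybar)^2)` where `y` are
#' the log empirical values. Zero-hit records carry no usable empirical
#' estimate and are excluded (they should instead satisfy
#' `calculated p <= ac_high`).
#'
#' @param records List of [empirical_pvalue()] records, or a data.frame with
#'   columns `x`, `empirical_p` and `log_p_calc`.
#' @return List with `pearson_r`, `r_squared` and `n_used`.
#' @export
loglog_agreement <- function(records) {
  df <- records_df(records)
  df <- df[df$x >= 1, , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 records with observed hits")
  x <- df$log_p_calc / log(10)
  y <- log10(df$empirical_p)
  list(pearson_r = stats::cor(x, y),
       r_squared = 1 - sum((y - x)^2) / sum((y - mean(y))^2),
       n_used = nrow(df))
}

#' Scaled replication of the simulated-genome validation study
#'
#' Generates random genomes with Pareto-distributed gene-family sizes,
#' constructs test clusters by the common/rare/random strategies with a
#' random distance threshold `delta` in `[0, |C|-2]`, keeps clusters whose
#' calculated p-value is at least `min_p`, estimates each empirical p-value
#' by Monte-Carlo, and reports the log-log agreement statistics. The
#' defaults are a desk-scale version of the full study (which uses genome
#' lengths 1250-1750 and billions of draws); the `min_p` floor keeps the
#' empirical estimates accurate at the chosen draw count.
#'
#' @param n_clusters Target number of cluster/p-value pairs.
#' @param draws Monte-Carlo draws per cluster.
#' @param n_genomes Number of Pareto genomes.
#' @param alpha Pareto shape for gene-family sizes.
#' @param length_range Genome length range (uniform).
#' @param size_range Cluster size range.
#' @param min_p Minimum calculated p-value for a cluster to enter the study.
#' @param seed Optional RNG seed.
#' @param mode Passed to [single_genome_pvalue()].
#' @return An object of class `"validation_study"`: `records` (data.frame),
#'   `pearson_r`, `r_squared`, `n_used`.
#' @export
validation_study <- function(n_clusters = 60, draws = 2e5, n_genomes = 6,
                             alpha = 2.8, length_range = c(60, 200),
                             size_range = c(2, 10), min_p = 0.02,
                             seed = NULL, mode = c("exact", "fast")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  per_g <- ceiling(n_clusters / n_genomes)
  # strategy proportions follow the full study (9 : 9 : 82)
  n_com0 <- max(1L, round(0.09 * per_g))
  n_rand0 <- max(per_g - 2L * n_com0, 1L)
  records <- list()
  for (gi in seq_len(n_genomes)) {
    g <- sample_pareto_genome(alpha = alpha, length_range = length_range,
                              id = paste0("sim", gi))
    model <- frequency_model(g)
    comp <- model$components[[1L]]
    clusters <- construct_test_clusters(g, n_common = n_com0, n_rare = n_com0,
                                        n_random = n_rand0,
                                        size_range = size_range)
    tries <- 0L
    kept <- list()
    while (TRUE) {
      for (cl in clusters) {
        lp <- single_genome_pvalue(cl$genes, cl$delta, comp, mode)$log_p
        if (lp >= log(min_p)) kept[[length(kept) + 1L]] <- cl
      }
      tries <- tries + 1L
      if (length(kept) >= per_g || tries >= 6L) break
      clusters <- construct_test_clusters(g, n_common = 0L, n_rare = 0L,
                                          n_random = n_rand0,
                                          size_range = size_range)
    }
    if (length(kept) > per_g) kept <- kept[seq_len(per_g)]
    for (cl in kept)
      records[[length(records) + 1L]] <-
        empirical_pvalue(cl$genes, cl$delta, comp, draws = draws, mode = mode)
  }
  agr <- loglog_agreement(records)
  structure(list(records = records_df(records), pearson_r = agr$pearson_r,
                 r_squared = agr$r_squared, n_used = agr$n_used,
                 draws = draws, alpha = alpha,
                 length_range = length_range, min_p = min_p),
            class = "validation_study")
}

#' @export
print.validation_study <- function(x, ...) {
  cat(sprintf(
    "<validation_study> %d clusters (p >= %g), %g draws each\n  Pearson r = %.6f, R^2 = %.6f\n",
    nrow(x$records), x$min_p, x$draws, x$pearson_r, x$r_squared))
  invisible(x)
}

#' @export
plot.validation_study <- function(x, ...) {
  df <- x$records[x$records$x >= 1, ]
  px <- df$log_p_calc / log(10)
  py <- log10(df$empirical_p)
  graphics::plot(px, py, xlab = "log10 calculated p-value",
       ylab = "log10 empirical p-value",
       main = sprintf("Calculated vs empirical p-values (R^2 = %.5f)",
                      x$r_squared), ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}

#' Write validation records as TSV
#'
#' @param records List of records or data.frame (see [loglog_agreement()]).
#' @param path Output file.
#' @export
write_validation_tsv <- function(records, path) {
  df <- records_df(records)
  df$calculated_p <- exp(df$log_p_calc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
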