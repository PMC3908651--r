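# Synthetic genomes with Pareto-distributed gene-family sizes and test
# cluster construction, emulating the simulated validation data: real
# bacterial gene-family sizes approximately follow a Pareto law with shape
# alpha = 2.8.

#' Random genome with Pareto gene-family sizes
#'
#' Draws a genome length uniformly from `length_range`, then adds new gene
#' families with copy counts `floor(X)`, `X ~ Pareto(alpha, x_m = 1)`, until
#' all positions are filled (surplus copies of the last family are
#' discarded), and shuffles the gene order uniformly. The scale `x_m = 1`
#' guarantees every family at least one copy; flooring preserves the tail
#' law `P(count >= m) = m^-alpha` exactly.
#'
#' @param alpha Pareto shape (> 0); 2.8 matches bacterial gene-family sizes.
#' @param length_range Integer range for the genome length (uniform draw).
#' @param seed Optional RNG seed.
#' @param id Genome label.
#' @return A [genome()] with one chromosome and gene ids `1..#families`.
#' @export
sample_pareto_genome <- function(alpha = 2.8, length_range = c(1250, 1750),
                                 seed = NULL, id = "pareto") {
  stopifnot(alpha > 0, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  if (!is.null(seed)) set.seed(seed)
  n <- sample(length_range[1]:length_range[2], 1L)
  counts <- integer(0)
  filled <- 0L
  while (filled < n) {
    x <- floor(stats::runif(1)^(-1 / alpha))  # inverse-CDF Pareto, floored
    x <- min(as.integer(x), n - filled)
    counts <- c(counts, max(x, 1L))
    filled <- filled + max(x, 1L)
  }
  genome(sample(rep.int(seq_along(counts), counts)), id = id)
}

#' Construct test clusters from a genome
#'
#' Builds gene clusters by three strategies: the most commonly occurring
#' genes, the rarest genes, and uniformly random gene sets, with sizes
#' spanning `size_range` and, for each cluster, a distance threshold
#' `delta` drawn uniformly from `0..|C|-2`. The defaults (9/9/82, sizes
#' 2-10) reproduce the 100-cluster layout of the simulated validation
#' study. Ties between equally frequent genes are broken by gene id.
#'
#' @param genome A [genome()] or integer vector.
#' @param n_common,n_rare,n_random Number of clusters per strategy.
#' @param size_range Cluster size range.
#' @param seed Optional RNG seed.
#' @return List of cluster specs: `genes`, `delta`, `strategy`.
#' @export
construct_test_clusters <- function(genome, n_common = 9, n_rare = 9,
                                    n_random = 82, size_range = c(2, 10),
                                    seed = NULL) {
  g <- as_genome(genome)
  if (!is.null(seed)) set.seed(seed)
  cnt <- table(unlist(g$chromosomes))
  ids <- as.integer(names(cnt))
  cnt <- as.integer(cnt)
  if (length(ids) < max(size_range))
    stop("genome has fewer distinct families than the largest cluster size")
  by_common <- ids[order(-cnt, ids)]
  by_rare <- ids[order(cnt, ids)]
  sizes <- function(k) if (k == 0) integer(0) else
    rep_len(seq(size_range[1], size_range[2]), k)
  rand_delta <- function(m) if (m == 2L) 0L else sample(0:(m - 2L), 1L)
  out <- list()
  add <- function(genes, strategy) {
    genes <- sort(as.integer(genes))
    out[[length(out) + 1L]] <<-
      list(genes = genes, delta = rand_delta(length(genes)),
           strategy = strategy)
  }
  for (m in sizes(n_common)) add(by_common[seq_len(m)], "common")
  for (m in sizes(n_rare)) add(by_rare[seq_len(m)], "rare")
  if (n_random > 0) for (i in seq_len(n_random)) {
    m <- sample(size_range[1]:size_range[2], 1L)
    add(sample(ids, m), "random")
  }
  out
}
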