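# End-to-end scoring: cluster search, per-genome p-values, multi-genome
# combination, FDR correction, duplicate and overlap resolution.

score_cluster <- function(rec, models, method, mode) {
  others <- names(rec$distances)
  mods <- models[others]
  if (method == "individual") {
    combine_individual_bounds(rec$distances, rec$genes, mods, rec$delta,
                              rec$quorum, mode)
  } else if (method == "global") {
    dp <- max(rec$distances, na.rm = TRUE)
    p_list <- lapply(mods, function(m)
      single_genome_pvalue(rec$genes, dp, m, mode))
    res <- combine_global_bound(p_list, rec$quorum - 1L)
    combined_result(res$p$log_p, "global_bound", k_used = res$k_used,
                    quorum = rec$quorum, delta_prime = as.integer(dp))
  } else {
    if (anyNA(rec$distances))
      stop("sum-distance combination requires a delta-location in every ",
           "non-reference genome")
    pmfs <- lapply(mods, function(m)
      distance_pmf(rec$genes, rec$delta, m, mode))
    combine_sum_distance(pmfs, rec$d_obs, rec$delta)
  }
}

cluster_occurrences <- function(rec, genomes) {
  occ <- data.frame(genome = rec$reference$genome, chrom = rec$reference$chrom,
                    a = rec$reference$a, b = rec$reference$b)
  for (gid in names(rec$distances)) {
    d <- rec$distances[[gid]]
    if (is.na(d)) next
    locs <- optimal_delta_locations(genomes[[gid]], rec$genes, rec$delta)
    locs <- locs[locs$distance == min(locs$distance), , drop = FALSE][1L, ]
    occ <- rbind(occ, data.frame(genome = gid, chrom = locs$chrom,
                                 a = locs$a, b = locs$b))
  }
  occ
}

occ_intersect <- function(o1, o2) {
  m <- merge(o1, o2, by = c("genome", "chrom"))
  nrow(m) > 0 && any(m$a.x <= m$b.y & m$a.y <= m$b.x)
}

#' Gene cluster significance analysis
#'
#' The main entry point: searches a set of genomes for reference gene
#' clusters, computes each cluster's p-value under the random gene-order
#' null model, combines per-genome probabilities under the quorum
#' constraint, applies FDR correction per search run, merges runs, removes
#' duplicate gene sets and resolves clusters with intersecting occurrences
#' by keeping the one with the smaller p-value.
#'
#' @param genomes List of [genome()] objects (or integer vectors).
#' @param s Minimum cluster size (ignored when `params` is given).
#' @param delta Distance threshold (ignored when `params` is given).
#' @param quorum Minimum number of genomes containing the cluster,
#'   including the reference genome.
#' @param reference Optional genome id to restrict reference intervals to;
#'   also fixes the multiple-testing universe to that genome's intervals.
#' @param params Optional list of `list(s=, delta=)` settings for a
#'   multi-run search; each run is FDR-corrected separately before merging.
#' @param method Multi-genome combination: `"individual"` distance bounds
#'   (default), `"global"` distance bound, or `"sum"` distance (requires
#'   occurrences in all non-reference genomes).
#' @param mode Additional-characters computation, see
#'   [single_genome_pvalue()].
#' @param resolve_overlaps Drop the worse of two clusters whose occurrences
#'   intersect in any genome.
#' @return An object of class `"clustersig"`: `table` (one row per reported
#'   cluster, Table-style columns plus full-precision log p-values),
#'   `clusters` (the underlying records), `T` (interval universe), and the
#'   call parameters.
#' @examples
#' gs <- list(genome(c(1:6, 9, 9), id = "a"), genome(c(7, 6:1, 8), id = "b"),
#'            genome(c(8, 1:3, 7, 4:6), id = "c"))
#' fit <- gene_cluster_significance(gs, s = 3, delta = 1, quorum = 3)
#' print(fit)
#' @export
gene_cluster_significance <- function(genomes, s = 4, delta = 1, quorum = 2,
                                      reference = NULL, params = NULL,
                                      method = c("individual", "global", "sum"),
                                      mode = c("fast", "exact"),
                                      resolve_overlaps = TRUE) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  genomes <- lapply(genomes, as_genome)
  names(genomes) <- vapply(genomes, `[[`, character(1), "id")
  models <- lapply(genomes, frequency_model)
  if (is.null(params)) params <- list(list(s = s, delta = delta))
  T_univ <- if (!is.null(reference)) {
    count_reference_intervals(lengths(genomes[[reference]]$chromosomes))
  } else {
    count_reference_intervals(unlist(lapply(genomes, function(g)
      lengths(g$chromosomes))))
  }
  all_rows <- NULL
  all_recs <- list()
  for (ri in seq_along(params)) {
    pr <- params[[ri]]
    recs <- find_reference_clusters(genomes, s = pr$s, delta = pr$delta,
                                    quorum = quorum, reference = reference)
    if (length(recs) == 0L) next
    rows <- do.call(rbind, lapply(seq_along(recs), function(i) {
      rec <- recs[[i]]
      comb <- score_cluster(rec, models, method, mode)
      pres <- rec$distances[!is.na(rec$distances)]
      data.frame(id = sprintf("r%d.%d", ri, i),
                 genes = paste(rec$genes, collapse = " "),
                 G = length(rec$genes), GN = rec$k_obs + 1L,
                 dmin = min(pres), dmax = max(pres),
                 davg = mean(pres), s = pr$s, delta = pr$delta,
                 reference = rec$reference$genome,
                 log_p = comb$p$log_p)
    }))
    rows <- fdr_correct(rows, T_univ)
    for (i in seq_along(recs)) all_recs[[sprintf("r%d.%d", ri, i)]] <- recs[[i]]
    all_rows <- rbind(all_rows, rows)
  }
  if (is.null(all_rows)) {
    tab <- data.frame(id = character(0))
  } else {
    tab <- all_rows[order(all_rows$log_p_corr, all_rows$id), , drop = FALSE]
    tab <- tab[!duplicated(tab$genes), , drop = FALSE]  # same set: keep best
    if (resolve_overlaps && nrow(tab) > 1L) {
      occs <- lapply(tab$id, function(id)
        cluster_occurrences(all_recs[[id]], genomes))
      keep <- logical(nrow(tab))
      for (i in seq_len(nrow(tab))) {
        keep[i] <- !any(vapply(which(keep), function(j)
          occ_intersect(occs[[i]], occs[[j]]), logical(1)))
      }
      tab <- tab[keep, , drop = FALSE]
    }
    rownames(tab) <- NULL
  }
  structure(list(table = tab, clusters = all_recs, T = T_univ,
                 quorum = quorum, method = method, mode = mode,
                 params = params, reference = reference,
                 genome_ids = names(genomes)),
            class = "clustersig")
}

#' @export
print.clustersig <- function(x, n = 10, ...) {
  cat(sprintf(
    "Gene cluster significance: %d cluster(s) from %d genome(s)\n",
    nrow(x$table), length(x$genome_ids)))
  cat(sprintf("  combination: %s bounds; quorum k' = %d; FDR universe T = %s intervals\n",
              x$method, x$quorum, format(x$T, big.mark = ",")))
  if (nrow(x$table) == 0) return(invisible(x))
  df <- utils::head(x$table, n)
  show <- data.frame(ID = seq_len(nrow(df)), G = df$G, GN = df$GN,
                     min = df$dmin, max = df$dmax,
                     avg = sprintf("%.1f", df$davg),
                     `p-score` = sprintf("%.2f", df$p_score),
                     `corr. p-score` = sprintf("%.2f", df$p_score_corr),
                     genes = df$genes, check.names = FALSE)
  print(show, row.names = FALSE)
  if (nrow(x$table) > n) cat(sprintf("  ... %d more\n", nrow(x$table) - n))
  invisible(x)
}

#' @export
summary.clustersig <- function(object, ...) {
  tab <- object$table
  cat(sprintf("Runs: %s; quorum %d; method %s\n",
              paste(vapply(object$params, function(p)
                sprintf("(s=%d, delta=%d)", p$s, p$delta), character(1)),
                collapse = ", "),
              object$quorum, object$method))
  cat(sprintf("Clusters reported: %d; significant at corrected p < 0.05: %d\n",
              nrow(tab), sum(tab$log_p_corr < log(0.05))))
  invisible(object)
}

#' @export
as.data.frame.clustersig <- function(x, ...) x$table
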