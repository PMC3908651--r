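# Genomes as strings of gene-family ids, symmetric set distance,
# delta-locations, and the exact brute-force reference-cluster finder.

#' Genome object
#'
#' A genome is an ordered sequence of positive integer gene-family
#' identifiers, split into one or more chromosomes (or contigs). Intervals
#' never span a chromosome boundary. Positions are 1-based and inclusive.
#'
#' @param chromosomes A single integer vector (one chromosome) or a list of
#'   integer vectors, one per chromosome, in chromosomal order.
#' @param id Genome label.
#' @param chromosome_ids Optional labels for the chromosomes.
#' @return An object of class `"genome"` with elements `id`, `chromosomes`
#'   (named list of integer vectors) and `n` (total gene count).
#' @examples
#' g <- genome(c(1L, 2L, 2L, 3L), id = "g1")
#' g$n
#' @export
genome <- function(chromosomes, id = "genome", chromosome_ids = NULL) {
  if (!is.list(chromosomes)) chromosomes <- list(chromosomes)
  if (length(chromosomes) == 0L) stop("genome needs at least one chromosome")
  chromosomes <- lapply(chromosomes, function(x) {
    x <- as.integer(x)
    if (length(x) == 0L) stop("chromosomes must be non-empty")
    if (anyNA(x) || any(x < 1L))
      stop("gene ids must be positive integers (0 is reserved)")
    x
  })
  if (is.null(chromosome_ids))
    chromosome_ids <- paste0("chr", seq_along(chromosomes))
  names(chromosomes) <- as.character(chromosome_ids)
  structure(list(id = as.character(id), chromosomes = chromosomes,
                 n = sum(lengths(chromosomes))),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> '%s': %d genes on %d chromosome(s), %d distinct families\n",
              x$id, x$n, length(x$chromosomes),
              length(unique(unlist(x$chromosomes)))))
  invisible(x)
}

as_genome <- function(x, id = "genome") {
  if (inherits(x, "genome")) x else genome(x, id = id)
}

check_interval <- function(genome, a, b, chrom) {
  if (chrom < 1L || chrom > length(genome$chromosomes))
    stop("chromosome index out of range")
  n <- length(genome$chromosomes[[chrom]])
  if (a < 1L || b > n || a > b)
    stop(sprintf("invalid interval [%d,%d] on chromosome of length %d", a, b, n))
  invisible(TRUE)
}

#' Character set of an interval
#'
#' The set of distinct gene ids occurring in positions `a..b` of one
#' chromosome, ignoring order and multiplicity.
#'
#' @param genome A [genome()] (or a bare integer vector).
#' @param a,b 1-based inclusive interval bounds.
#' @param chrom 1-based chromosome index.
#' @return Sorted integer vector of distinct gene ids.
#' @examples
#' character_set(genome(c(1, 2, 2, 3)), 1, 3)
#' @export
character_set <- function(genome, a, b, chrom = 1L) {
  genome <- as_genome(genome)
  check_interval(genome, a, b, chrom)
  sort(unique(genome$chromosomes[[chrom]][a:b]))
}

#' Symmetric set distance
#'
#' The cardinality of the symmetric difference of two gene sets,
#' `|A \ B| + |B \ A|`. This is a metric on finite sets; in the gene cluster
#' context it counts genes missing from an occurrence plus foreign genes
#' inserted into it.
#'
#' @param A,B Gene-id vectors (treated as sets).
#' @return Non-negative integer distance.
#' @examples
#' symmetric_set_distance(c(1, 2, 3), c(2, 3, 4))
#' @export
symmetric_set_distance <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  length(setdiff(A, B)) + length(setdiff(B, A))
}

#' Interval maximality
#'
#' An interval is left-maximal if it starts at position 1 or the preceding
#' character is not in its character set; right-maximal symmetrically; and
#' maximal if both. Maximal intervals are the reference intervals of the
#' cluster search.
#'
#' @inheritParams character_set
#' @return Logical.
#' @export
is_maximal <- function(genome, a, b, chrom = 1L) {
  genome <- as_genome(genome)
  check_interval(genome, a, b, chrom)
  S <- genome$chromosomes[[chrom]]
  cs <- unique(S[a:b])
  left <- a == 1L || !(S[a - 1L] %in% cs)
  right <- b == length(S) || !(S[b + 1L] %in% cs)
  left && right
}

# Map a genome + cluster onto the integer index space used by the C++
# scanning kernels: genes are re-indexed 1..m over the union of ids.
scan_encoding <- function(genome, genes) {
  ids <- sort(unique(c(unlist(genome$chromosomes), genes)))
  list(ids = ids,
       chrom = lapply(genome$chromosomes, function(x) match(x, ids)),
       in_c = ids %in% genes)
}

#' Best approximate occurrence distance
#'
#' Minimum symmetric set distance between a cluster's gene set and the
#' character set of any interval of the genome, restricted to
#' delta-locations: intervals with distance at most `delta` and non-empty
#' intersection with the cluster.
#'
#' @param genome A [genome()] or integer vector.
#' @param genes Gene-id set of the cluster.
#' @param delta Maximum allowed symmetric set distance (>= 0).
#' @return Integer distance in `0..delta`, or `NA` if the genome has no
#'   delta-location of the cluster.
#' @examples
#' best_location_distance(genome(c(1, 2, 5, 3)), c(1, 2, 3), delta = 1)
#' @export
best_location_distance <- function(genome, genes, delta) {
  genome <- as_genome(genome)
  genes <- unique(as.integer(genes))
  if (length(genes) == 0L) stop("empty cluster")
  stopifnot(delta >= 0)
  enc <- scan_encoding(genome, genes)
  best <- NA_integer_
  for (S in enc$chrom) {
    d <- cpp_best_distance(S, enc$in_c, sum(enc$in_c), as.integer(delta))
    if (d >= 0L && (is.na(best) || d < best)) best <- d
    if (!is.na(best) && best == 0L) break
  }
  best
}

#' Optimal delta-locations of a cluster
#'
#' Enumerates all delta-locations of a gene set in a genome and discards
#' those that are sub-intervals of a delta-location with strictly smaller
#' distance (the non-optimal ones).
#'
#' @inheritParams best_location_distance
#' @return A data.frame with columns `chrom`, `a`, `b`, `distance`, sorted by
#'   (chrom, a, b). Zero rows when no delta-location exists.
#' @export
optimal_delta_locations <- function(genome, genes, delta) {
  genome <- as_genome(genome)
  genes <- unique(as.integer(genes))
  stopifnot(delta >= 0)
  out <- list()
  for (ci in seq_along(genome$chromosomes)) {
    S <- genome$chromosomes[[ci]]
    n <- length(S)
    locs <- NULL
    for (a in seq_len(n)) {
      seen <- integer(0)
      missing <- length(genes)
      extra <- 0L
      for (b in a:n) {
        ch <- S[b]
        if (!(ch %in% seen)) {
          seen <- c(seen, ch)
          if (ch %in% genes) missing <- missing - 1L else extra <- extra + 1L
        }
        if (extra > delta) break  # extra chars only accumulate with b
        d <- missing + extra
        if (d <= delta && missing < length(genes))
          locs <- rbind(locs, c(a, b, d))
      }
    }
    if (is.null(locs)) next
    keep <- vapply(seq_len(nrow(locs)), function(i) {
      !any(locs[, 1] <= locs[i, 1] & locs[, 2] >= locs[i, 2] &
             locs[, 3] < locs[i, 3])
    }, logical(1))
    locs <- locs[keep, , drop = FALSE]
    out[[length(out) + 1L]] <-
      data.frame(chrom = ci, a = locs[, 1], b = locs[, 2], distance = locs[, 3])
  }
  if (length(out) == 0L)
    return(data.frame(chrom = integer(0), a = integer(0), b = integer(0),
                      distance = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$a, res$b), , drop = FALSE]
}

# All maximal intervals of one genome whose character set has >= s genes,
# deduplicated by gene set (first interval in (chrom, a, b) order is kept:
# duplicate gene sets are tested once).
maximal_interval_sets <- function(genome, s) {
  found <- new.env(parent = emptyenv())
  res <- list()
  for (ci in seq_along(genome$chromosomes)) {
    S <- genome$chromosomes[[ci]]
    n <- length(S)
    for (a in seq_len(n)) {
      cs <- integer(0)
      for (b in a:n) {
        cs <- union(cs, S[b])
        left <- a == 1L || !(S[a - 1L] %in% cs)
        if (!left) next
        right <- b == n || !(S[b + 1L] %in% cs)
        if (!right || length(cs) < s) next
        key <- paste(sort(cs), collapse = ",")
        if (!exists(key, envir = found)) {
          assign(key, TRUE, envir = found)
          res[[length(res) + 1L]] <-
            list(genes = sort(cs), chrom = ci, a = a, b = b)
        }
      }
    }
  }
  res
}

#' Exact brute-force reference gene cluster search
#'
#' A reference gene cluster for parameters (`s`, `delta`, `quorum`) is a gene
#' set `C` with at least `s` genes that occurs exactly as a maximal interval
#' in one genome (the reference occurrence) and has delta-locations in at
#' least `quorum - 1` of the other genomes. This finder enumerates all
#' maximal intervals of the candidate reference genome(s) directly; it is
#' exact and intended for desk-scale inputs.
#'
#' @param genomes List of [genome()] objects (or integer vectors).
#' @param s Minimum cluster size (>= 2).
#' @param delta Distance threshold (>= 0).
#' @param quorum Minimum number of genomes, including the reference genome, in
#'   which the cluster must occur (`2 <= quorum <= length(genomes)`).
#' @param reference Optional genome id: restrict reference intervals to this
#'   genome. By default every genome serves as reference in turn; candidates
#'   with identical gene sets from different reference genomes are all
#'   returned (downstream scoring deduplicates by smaller p-value).
#' @return A list of cluster records, each a list with elements `genes`,
#'   `s`, `delta`, `quorum`, `reference` (genome id, chrom, a, b),
#'   `distances` (named vector over non-reference genomes, `NA` = no
#'   delta-location), `d_obs` (sum of present distances), `k_obs` (number of
#'   non-reference genomes with a delta-location) and `delta_prime` (largest
#'   present distance).
#' @examples
#' gs <- list(genome(1:4, id = "a"), genome(4:1, id = "b"))
#' length(find_reference_clusters(gs, s = 2, delta = 0, quorum = 2))
#' @export
find_reference_clusters <- function(genomes, s, delta, quorum,
                                    reference = NULL) {
  genomes <- lapply(genomes, as_genome)
  ids <- vapply(genomes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("genome ids must be unique")
  names(genomes) <- ids
  k <- length(genomes)
  stopifnot(s >= 2, delta >= 0)
  if (quorum < 2 || quorum > k)
    stop("quorum must be between 2 and the number of genomes")
  refs <- if (is.null(reference)) ids else {
    if (!reference %in% ids) stop("reference genome id not found")
    reference
  }
  out <- list()
  for (rid in refs) {
    others <- setdiff(ids, rid)
    for (cand in maximal_interval_sets(genomes[[rid]], s)) {
      dists <- vapply(others, function(gid)
        best_location_distance(genomes[[gid]], cand$genes, delta),
        integer(1))
      names(dists) <- others
      present <- !is.na(dists)
      if (sum(present) < quorum - 1L) next
      out[[length(out) + 1L]] <- list(
        genes = cand$genes, s = s, delta = delta, quorum = quorum,
        reference = list(genome = rid, chrom = cand$chrom,
                         a = cand$a, b = cand$b),
        distances = dists,
        d_obs = sum(dists[present]),
        k_obs = sum(present),
        delta_prime = if (any(present)) max(dists[present]) else NA_integer_)
    }
  }
  out
}
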