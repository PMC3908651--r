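# False discovery rate control over ranked cluster p-values and p-score
# reporting.  Because cluster p-values underflow double precision, the
# correction is applied on log scale; corrected values above one are
# reported as-is (the correction is conservative).

#' Number of possible reference intervals
#'
#' The multiple-testing universe: every interval of every genome is a
#' potential reference interval, `sum_j n_j (n_j + 1) / 2` over the genome
#' (or chromosome) lengths.
#'
#' @param lengths Positive integer vector of sequence lengths.
#' @return Exact interval count (numeric to avoid integer overflow).
#' @examples
#' count_reference_intervals(4189)
#' @export
count_reference_intervals <- function(lengths) {
  lengths <- as.numeric(lengths)
  stopifnot(all(lengths >= 1))
  sum(lengths * (lengths + 1) / 2)
}

#' p-score of a log-space p-value
#'
#' `-log10(p)`. The standard reporting scale for cluster p-values, which
#' reach magnitudes far below floating-point underflow.
#'
#' @param p An [lprob()] or a natural-log p-value.
#' @return `-log10(p)`; `Inf` for p = 0.
#' @examples
#' p_score(lprob(log_p = log(0.05)))
#' @export
p_score <- function(p) {
  lp <- if (inherits(p, "lprob")) p$log_p else as.numeric(p)
  stopifnot(all(lp <= 1e-9))
  -lp / log(10)
}

#' FDR correction of ranked cluster p-values
#'
#' Sorts clusters by p-value (ties broken by id for determinism) and
#' multiplies the p-value at rank `i` by `T / i`, where `T` is the number of
#' possible reference intervals. No clamping at one and no step-up
#' monotonicity enforcement: the raw conservative factor is reported.
#'
#' @param reports A data.frame with columns `id` and `log_p` (natural-log
#'   p-values; `-Inf` allowed).
#' @param T Reference interval count, e.g. from
#'   [count_reference_intervals()].
#' @return The data.frame sorted by p-value with added columns `rank`,
#'   `log_p_corr`, `p_score` and `p_score_corr`.
#' @export
fdr_correct <- function(reports, T) {
  stopifnot(is.data.frame(reports), all(c("id", "log_p") %in% names(reports)),
            T >= 1)
  o <- order(reports$log_p, reports$id)
  reports <- reports[o, , drop = FALSE]
  i <- seq_len(nrow(reports))
  reports$rank <- i
  reports$log_p_corr <- reports$log_p + log(T) - log(i)
  reports$p_score <- -reports$log_p / log(10)
  reports$p_score_corr <- -reports$log_p_corr / log(10)
  rownames(reports) <- NULL
  reports
}
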