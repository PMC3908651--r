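# Log-space probabilities.
#
# Cluster p-values routinely underflow double precision (combined p-values
# below 1e-1000 occur for well-conserved clusters in ~100 genomes), so all
# p-value arithmetic is carried in log space.  An "lprob" stores both log(p)
# and log(1-p): the complement is needed by the quorum recurrence and cannot
# be recovered from log(p) once p is numerically 0 or 1.

#' Log-space probability
#'
#' Constructs a probability stored as the pair (log(p), log(1-p)). Either
#' component may be `-Inf`. If one component is missing it is derived from the
#' other via [log1mexp()].
#'
#' @param log_p Natural logarithm of the probability.
#' @param log_1mp Natural logarithm of the complement. Derived from `log_p`
#'   when `NULL`.
#' @return An object of class `"lprob"`.
#' @examples
#' lprob(log(0.25))
#' as.numeric(lprob(log_1mp = log(0.75)))
#' @export
lprob <- function(log_p = NULL, log_1mp = NULL) {
  if (is.null(log_p) && is.null(log_1mp))
    stop("one of 'log_p', 'log_1mp' must be given")
  if (is.null(log_p)) log_p <- log1mexp(log_1mp)
  if (is.null(log_1mp)) log_1mp <- log1mexp(log_p)
  stopifnot(length(log_p) == 1L, length(log_1mp) == 1L)
  if (is.nan(log_p) || log_p > 1e-9 || is.nan(log_1mp) || log_1mp > 1e-9)
    stop("invalid log-probability pair")
  structure(list(log_p = min(log_p, 0), log_1mp = min(log_1mp, 0)),
            class = "lprob")
}

#' @export
print.lprob <- function(x, ...) {
  score <- -x$log_p / log(10)
  if (score == 0) score <- 0  # normalize -0
  cat(sprintf("<lprob> p = %s (log p = %.6g, p-score = %.4f)\n",
              format(exp(x$log_p), digits = 6), x$log_p, score))
  invisible(x)
}

#' @export
as.numeric.lprob <- function(x, ...) exp(x$log_p)

#' Accurate log(1 - exp(a)) for a <= 0
#'
#' @param a Numeric vector of non-positive values.
#' @return `log(1 - exp(a))`, computed without cancellation.
#' @export
log1mexp <- function(a) {
  stopifnot(all(a <= 1e-12 | is.nan(a)))
  a <- pmin(a, 0)
  ifelse(a > -log(2), log(-expm1(a)), log1p(-exp(a)))
}

#' Stable log-sum-exp
#'
#' @param x Numeric vector of log-scale values (may contain `-Inf`).
#' @return `log(sum(exp(x)))`.
#' @export
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; tiny negative differences from rounding
# are clamped to -Inf (caller may warn).
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (b >= a) return(-Inf)
  a + log1mexp(b - a)
}
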