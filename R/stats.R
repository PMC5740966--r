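#' Paired t-test on per-pair values
#'
#' The statistic is t = mean(d) / (sd(d)/sqrt(n)) on the per-pair
#' differences d = a - b with the n-1 denominator standard deviation,
#' referred to a t distribution with n-1 degrees of freedom. Delegates to
#' [stats::t.test()] except in the degenerate constant-difference case,
#' which base R refuses: all-zero differences report t = 0 (one-tailed
#' p = 0.5, two-tailed p = 1), and a nonzero constant difference reports an
#' infinite statistic with the corresponding 0/1 tail.
#'
#' @param a,b Numeric vectors of equal length (values per pair).
#' @param alternative `"greater"` (a > b), `"less"`, or `"two_sided"`.
#' @return An object of class `paired_t_test`: list with `t`, `df`, `p`,
#'   `alternative`, `n`, `mean_diff`.
#' @export
paired_t_test <- function(a, b, alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b))
    stop("paired vectors have different lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs, got ", n, call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values in paired data", call. = FALSE)
  d <- a - b
  md <- mean(d)
  if (sd(d) == 0) {
    tval <- if (md == 0) 0 else sign(md) * Inf
    p <- switch(alternative,
      greater   = if (md > 0) 0 else if (md < 0) 1 else 0.5,
      less      = if (md < 0) 0 else if (md > 0) 1 else 0.5,
      two_sided = if (md == 0) 1 else 0)
  } else {
    fit <- t.test(a, b, paired = TRUE,
                  alternative = sub("two_sided", "two.sided", alternative))
    tval <- unname(fit$statistic)
    p <- fit$p.value
  }
  structure(list(t = tval, df = n - 1L, p = p, alternative = alternative,
                 n = n, mean_diff = md),
            class = "paired_t_test")
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat(sprintf("Paired t-test (%s): t = %.4g, df = %d, p = %.4g, n = %d\n",
              x$alternative, x$t, x$df, x$p, x$n))
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) where X counts pathway members among `n` genes drawn without
#' replacement from a universe of `N` genes of which `K` belong to the
#' pathway. Computed with [stats::phyper()], which works in log space
#' internally and is exact to double precision.
#'
#' @param k Observed overlap (scalar or vector).
#' @param K Pathway size within the universe.
#' @param n Number of selected genes.
#' @param N Universe size.
#' @return Upper-tail probability, same length as `k`.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N))
    stop("pathway size and selection must not exceed the universe",
         call. = FALSE)
  if (any(k < 0) || any(k > pmin(K, n)))
    stop("overlap k must lie in [0, min(K, n)]", call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing correction
#'
#' Bonferroni correction: each p-value is multiplied by the number of tests
#' and capped at 1 (via [stats::p.adjust()]); input order is preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method Only `"bonferroni"` is offered.
#' @param m Number of tests; defaults to `length(p)`.
#' @return Corrected p-values, same order as `p`.
#' @export
multiplicity_correct <- function(p, method = "bonferroni", m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "bonferroni", n = max(m, length(p)))
}
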