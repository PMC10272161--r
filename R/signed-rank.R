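#' Exact two-sided Wilcoxon signed-rank test
#'
#' Paired two-sided signed-rank test used throughout the package: the
#' responder criterion compares per-trial response-bin firing rates with the
#' same trial's background rate, behavioral preference indices are compared
#' with zero, and the paired-recording epoch comparison uses it as well. For
#' `n <= 25` non-zero differences the null distribution of the rank sum is
#' enumerated exactly (dynamic programming over the signed average ranks, so
#' tied differences are handled exactly rather than by a normal fallback);
#' above that a normal approximation with tie correction and continuity
#' correction is used. Zero differences are dropped before ranking, the
#' standard Wilcoxon convention.
#'
#' @param x,y paired numeric vectors; the test is on `x - y`. Supply `y = 0`
#'   (the default) to test a single sample against zero.
#' @param n_exact largest number of non-zero differences for which the exact
#'   enumeration is used.
#'
#' @return A tibble with one row: `statistic` (rank sum of positive
#'   differences `W+`), `p_value` (two-sided), `n_used` (non-zero pairs),
#'   `n_zero` (dropped pairs), and `method` ("exact" or "normal").
#'   By convention `p_value = 1` when every difference is zero.
#'
#' @examples
#' signed_rank_test(c(3, 5, 2, 6, 9, 4, 7))          # 7 positive: p = 2/2^7
#' signed_rank_test(rnorm(10), rnorm(10))
#' @export
signed_rank_test <- function(x, y = 0, n_exact = 25) {
  res <- signed_rank_stat(x, y, n_exact)
  tibble(statistic = res$statistic, p_value = res$p_value,
         n_used = res$n_used, n_zero = res$n_zero, method = res$method)
}

# Lean internal version returning a plain list (hot path for the
# responder criterion over many cell-odor pairs).
signed_rank_stat <- function(x, y = 0, n_exact = 25) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(y) == 1L) y <- rep(y, length(x))
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  d <- x - y
  d <- d[is.finite(d)]
  # differences at floating-point noise level are ties, not signal
  tol <- 1e-8 * max(abs(c(x, y, 1)), na.rm = TRUE)
  d[abs(d) < tol] <- 0
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                n_zero = n_zero, method = "degenerate"))
  }
  r <- rank(abs(d))                      # average ranks on ties
  w <- sum(r[d > 0])
  if (n <= n_exact) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4               # equals n(n+1)(2n+1)/24 adj. for ties
    cc <- 0.5
    z <- if (w > mu) (w - mu - cc) else (w - mu + cc)
    p <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n_used = n, n_zero = n_zero,
       method = method)
}

# Exact two-sided p for rank sum w given the multiset of average ranks r.
# Ranks are doubled to integers; the generating polynomial prod(1 + x^(2r_i))
# is built by convolution, giving the exact count of sign assignments for
# every achievable doubled rank sum.
signed_rank_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)          # index i -> doubled sum i-1
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
    counts <- counts + shifted
  }
  w2 <- round(2 * w)
  n_assign <- 2^length(r2)
  p_le <- sum(counts[seq_len(w2 + 1L)]) / n_assign
  p_ge <- sum(counts[seq.int(w2 + 1L, total + 1L)]) / n_assign
  min(1, 2 * min(p_le, p_ge))
}
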