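#' Hypergeometric upper-tail probability
#'
#' Computes `P(X >= b)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `b` "successes" when `n` elements are sampled without
#' replacement from a universe of `N` elements of which `K` are successes.
#' Evaluated through [stats::phyper()], so it is numerically stable far into
#' the tail.
#'
#' @param N Universe size (non-negative integer).
#' @param K Number of successes in the universe, `0 <= K <= N`.
#' @param n Sample size, `0 <= n <= N`.
#' @param b Tail threshold (non-negative integer). Vectorised over `n` and `b`.
#'
#' @return Numeric vector of tail probabilities in `[0, 1]`.
#' @examples
#' hypergeometric_tail(5, 2, 2, 2) # C(2,2)/C(5,2) = 0.1
#' @export
hypergeometric_tail <- function(N, K, n, b) {
  stopifnot(length(N) == 1, length(K) == 1, N >= 0, K >= 0, K <= N)
  if (any(n < 0) || any(n > N) || any(b < 0)) {
    stop("require 0 <= n <= N and b >= 0", call. = FALSE)
  }
  out <- phyper(b - 1, K, N - K, n, lower.tail = FALSE)
  out[b <= 0] <- 1
  out[b > pmin(K, n)] <- 0
  out
}

as_binary_vector <- function(x) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || length(x) == 0) {
    stop("`x` must be a non-empty 0/1 vector", call. = FALSE)
  }
  x <- as.integer(x)
  if (any(is.na(x)) || any(x != 0L & x != 1L)) {
    stop("`x` must contain only 0 and 1", call. = FALSE)
  }
  x
}

#' Minimum-hypergeometric statistic of a ranked binary list
#'
#' For a binary list `lambda` of length `N` with `K` ones, the mHG statistic
#' is the minimum over prefix cutoffs `n` of the hypergeometric tail
#' `P(X >= b_n)` where `b_n` counts ones in the first `n` entries. It measures
#' how surprisingly the ones concentrate at the top of the list, before
#' correcting for the optimisation over cutoffs (see [mhg_pvalue_dp()]).
#'
#' @param x Binary (0/1 or logical) vector, most-enriched end first.
#' @param X,L Optional bounds: only cutoffs with at least `X` ones and
#'   `n <= L` participate in the minimisation. Defaults `(1, N)` give the
#'   plain mHG statistic.
#'
#' @return An object of class `mhg_result`: a list with `statistic`,
#'   `n_star` (smallest minimising cutoff), `b_star`, `N`, `K`.
#'   `K == 0` yields statistic 1.
#' @examples
#' mhg_statistic(c(1, 1, 0, 0, 0)) # statistic 0.1 at n* = 2
#' @export
mhg_statistic <- function(x, X = 1L, L = length(x)) {
  x <- as_binary_vector(x)
  stopifnot(X >= 1, L >= 1, L <= length(x))
  res <- mhg_statistic_cpp(x, as.integer(X), as.integer(L))
  structure(res, class = "mhg_result")
}

#' Exact mHG p-value by path-counting dynamic programming
#'
#' The p-value of an observed mHG statistic `s` is the exact fraction of the
#' `choose(N, K)` distinct arrangements of `K` ones in `N` slots whose own mHG
#' statistic is `<= s`. It is computed by a dynamic program over the `(n, b)`
#' lattice: lattice cells whose hypergeometric tail is `<= s` form the
#' rejection region, and the program counts the paths that avoid it,
#' accumulating in scaled arithmetic so that `N` of a few tens of thousands
#' and p-values down to ~1e-300 are handled without overflow or cancellation.
#' The result depends only on `(s, N, K)`.
#'
#' @param statistic Observed mHG statistic in `(0, 1]`.
#' @param N,K List length and number of ones.
#' @param X,L Optional mHG bounds, as in [mhg_statistic()].
#'
#' @return Exact p-value in `(0, 1]`; always `>= statistic` and
#'   `<= min(1, N * statistic)`.
#' @examples
#' s <- mhg_statistic(c(1, 1, 0, 0, 0))$statistic
#' mhg_pvalue_dp(s, N = 5, K = 2) # 0.1
#' @export
mhg_pvalue_dp <- function(statistic, N, K, X = 1L, L = N) {
  stopifnot(
    length(statistic) == 1, is.finite(statistic), statistic > 0, statistic <= 1,
    N >= 1, K >= 0, K <= N, X >= 1, L >= 1, L <= N
  )
  mhg_pvalue_cpp(statistic, as.integer(N), as.integer(K),
                 as.integer(X), as.integer(L))
}

#' Brute-force mHG p-value by exhaustive enumeration
#'
#' Literal implementation of the permutation-fraction definition: enumerates
#' every distinct arrangement of the ones, recomputes the statistic for each,
#' and counts those at least as extreme as the observed list. Serves as the
#' independent oracle for [mhg_pvalue_dp()]; guarded against combinatorial
#' explosion.
#'
#' @param x Binary (0/1 or logical) vector.
#' @param max_arrangements Guard on `choose(N, K)`.
#' @return Exact p-value as a fraction of arrangements.
#' @examples
#' mhg_pvalue_bruteforce(c(1, 0, 1, 0)) # 2/3
#' @export
mhg_pvalue_bruteforce <- function(x, max_arrangements = 1e6) {
  x <- as_binary_vector(x)
  N <- length(x)
  K <- sum(x)
  if (choose(N, K) > max_arrangements) {
    stop("choose(N, K) exceeds the enumeration guard", call. = FALSE)
  }
  if (K == 0L || K == N) return(1)
  s <- mhg_statistic_cpp(x, 1L, N)$statistic
  combs <- utils::combn(N, K)
  hits <- 0L
  for (j in seq_len(ncol(combs))) {
    lam <- integer(N)
    lam[combs[, j]] <- 1L
    if (mhg_statistic_cpp(lam, 1L, N)$statistic <= s * (1 + 1e-12)) {
      hits <- hits + 1L
    }
  }
  hits / ncol(combs)
}

#' mHG enrichment test for a ranked binary list
#'
#' Convenience wrapper combining [mhg_statistic()] and [mhg_pvalue_dp()].
#'
#' @inheritParams mhg_statistic
#' @return An `mhg_result` with the additional element `pvalue`.
#' @examples
#' mhg_test(c(1, 1, 0, 0, 0))
#' @export
mhg_test <- function(x, X = 1L, L = length(x)) {
  res <- mhg_statistic(x, X = X, L = L)
  res$pvalue <- if (res$K == 0L) {
    1
  } else {
    mhg_pvalue_dp(res$statistic, res$N, res$K, X = X, L = L)
  }
  res
}

#' @export
print.mhg_result <- function(x, ...) {
  cat("mHG test: N =", x$N, ", K =", x$K, "\n")
  cat("  statistic =", format(x$statistic), "at n* =", x$n_star,
      "(b =", paste0(x$b_star, ")"), "\n")
  if (!is.null(x$pvalue)) cat("  exact p-value =", format(x$pvalue), "\n")
  invisible(x)
}

#' @export
tidy.mhg_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    n_star = x$n_star,
    b_star = x$b_star,
    N = x$N,
    K = x$K,
    p.value = if (is.null(x$pvalue)) NA_real_ else x$pvalue
  )
}
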