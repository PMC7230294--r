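#' Exact binomial coefficient
#'
#' Computes `choose(n, k)` by the multiplicative formula with exact integer
#' intermediates (every partial product is itself a binomial coefficient, so
#' each division is exact). Errors if the result would exceed 2^53, the range
#' in which doubles represent integers exactly.
#'
#' @param n,k Non-negative integers, `k <= n`.
#' @return Exact count as a double.
#' @examples
#' count_combinations(30, 20)  # 30045015
#' @export
count_combinations <- function(n, k) {
  if (length(n) != 1 || length(k) != 1 || is.na(n) || is.na(k)) {
    abort("n and k must be single integers")
  }
  if (n < 0 || k < 0 || k > n || n != floor(n) || k != floor(k)) {
    abort("need integers 0 <= k <= n")
  }
  k <- min(k, n - k)
  res <- 1
  for (i in seq_len(k)) {
    res <- res * (n - k + i) / i
    if (res > 2^53) abort("binomial coefficient exceeds exact double range (2^53)")
  }
  res
}

#' Lexicographic combination unranking
#'
#' Returns the `rank`-th (0-based) k-subset of `{1, ..., n}` in lexicographic
#' order, without materializing the full combination matrix. Bijective over
#' ranks `0 .. C(n,k) - 1`: rank 0 gives `1:k`, the final rank gives
#' `(n-k+1):n`, matching column order of `utils::combn(n, k)`.
#'
#' @param rank 0-based rank, `0 <= rank < C(n, k)`.
#' @inheritParams count_combinations
#' @return Sorted integer vector of length `k` with values in `1:n`.
#' @export
unrank_combination <- function(rank, n, k) {
  total <- count_combinations(n, k)
  if (rank < 0 || rank >= total) {
    abort(paste0("rank must lie in [0, ", format(total, scientific = FALSE),
                 "); got ", rank))
  }
  out <- integer(k)
  x <- 1L
  r <- rank
  for (i in seq_len(k)) {
    repeat {
      block <- count_combinations(n - x, k - i)
      if (r < block) break
      r <- r - block
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

#' Systematic stride sampling of combination ranks
#'
#' The 0-based ranks `offset, offset + stride, ...` below `total` — the
#' systematic column sampling of the (never materialized) combination matrix.
#' For `total = C(30, 20) = 30,045,015` and `stride = 1287` this yields
#' exactly 23,345 ranks (1287 divides the total).
#'
#' @param total Number of combinations.
#' @param stride Sampling stride, >= 1.
#' @param offset First rank (default 0).
#' @return Numeric vector of ranks, length `ceiling((total - offset) / stride)`.
#' @export
stride_indices <- function(total, stride, offset = 0) {
  if (total < 1 || stride < 1) abort("total and stride must be >= 1")
  if (offset >= total) {
    warn("offset is at or beyond total; no ranks sampled")
    return(numeric(0))
  }
  seq(from = offset, to = total - 1, by = stride)
}
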