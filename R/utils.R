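#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), ~0 for independent ones.
#' Used to score recovery of planted trends.
#'
#' @param x,y label vectors of equal length.
#' @return numeric scalar in (-1, 1\].
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(x)
  expected <- sum_i * sum_j / comb2(n)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
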