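#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value: with the margins fixed, sums the hypergeometric
#' probabilities of every table whose point probability does not exceed
#' that of the observed table (within a relative tolerance of 1e-7, so
#' equiprobable tables on the far tail are included despite floating-point
#' rounding).
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return The two-tailed p-value in (0, 1].
#' @export
#' @examples
#' fisher_two_tailed(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
fisher_two_tailed <- function(table) {
  if (is.vector(table) && length(table) == 4) {
    table <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (!is.matrix(table) || !all(dim(table) == 2)) abort("`table` must be 2x2.")
  x <- as.vector(t(table))
  if (any(x < 0) || any(x != round(x))) abort("counts must be non-negative integers.")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  m <- a + b          # row-1 margin
  n <- c + d          # row-2 margin
  k <- a + c          # column-1 margin
  if (m + n == 0) return(1)
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}
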