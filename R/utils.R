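## Small internal numeric helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif setNames
#' @importFrom utils write.table read.table combn
NULL

vnorm <- function(x) sqrt(sum(x * x))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## All residue-pair Euclidean distances between two coordinate matrices (n x 3, m x 3).
distMatrix <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3L)
  b <- matrix(as.numeric(b), ncol = 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## x * log2(x) with the 0 log 0 := 0 convention.
xlog2x <- function(x) ifelse(x <= 0, 0, x * log2(x))

## Shannon entropy (bits) of a discrete distribution given as probabilities.
entropyBitsVec <- function(p) -sum(xlog2x(p))

## Mutual information (bits) of a joint probability table.
miBitsTable <- function(joint) {
  joint <- as.matrix(joint)
  pm1 <- rowSums(joint)
  pm2 <- colSums(joint)
  tot <- 0
  for (i in seq_along(pm1)) for (j in seq_along(pm2)) {
    p <- joint[i, j]
    if (p > 0) tot <- tot + p * log2(p / (pm1[i] * pm2[j]))
  }
  max(tot, 0)
}

## All binary vectors of length n as a (2^n x n) 0/1 matrix, row order = binary counting.
enumerateBits <- function(n) {
  stopifnot(n >= 0)
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  if (n > 20L) stop("refusing to enumerate 2^", n, " binary vectors (cap is 2^20)")
  m <- matrix(0L, nrow = 2L^n, ncol = n)
  for (j in seq_len(n)) {
    m[, j] <- rep(rep(c(0L, 1L), each = 2L^(n - j)), length.out = 2L^n)
  }
  m
}

## Agreement-weight function of the probability model: q if x == y else 1 - q.
qWeight <- function(x, y, q) ifelse(x == y, q, 1 - q)

logistic <- function(z) 1 / (1 + exp(-z))

`%||%` <- function(a, b) if (is.null(a)) b else a

## Canonical label for an SSE pair, e.g. "1-3".
pairLabel <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))
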