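## Stage 1: probabilistic contact model over the ensemble, entropy / mutual
## information scoring, and greedy mRMR fingerprint selection.

#' Estimate q-smoothed contact probabilities from contact graphs
#'
#' For each SSE pair c, Pr(c = x) is the model-frequency estimate smoothed by
#' the agreement weight q: each model whose contact state y agrees with x
#' contributes q, a disagreeing one 1 - q, so that experimental uncertainty in
#' evaluating an SSE contact is built into the distribution (a unanimous pair
#' gets Pr = q, not 1). Joint probabilities over two pairs use the product of
#' the two weights on the models' co-occurring states.
#'
#' @param graphs list of \linkS4class{SSEContactGraph}, one per model.
#' @param q agreement weight in (0.5, 1], default 0.8.
#' @param pairs SSE-pair universe as a k x 2 matrix (default: all pairs of the
#'   graphs' common SSE set).
#' @return a \linkS4class{ContactProbModel}.
#' @export
estimateContactProbs <- function(graphs, q = 0.8, pairs = NULL) {
  if (length(graphs) < 1L) stop("need at least one contact graph")
  if (q <= 0.5 || q > 1)
    stop("q must be in (0.5, 1]: relevance and redundancy are degenerate at q <= 0.5")
  if (is.null(pairs)) pairs <- t(combn(graphs[[1L]]@sseIds, 2L))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  states <- signatureMatrix(graphs, pairs)
  pr1 <- colMeans(q * states + (1 - q) * (1 - states))
  marg <- cbind(1 - pr1, pr1)
  colnames(marg) <- c("Pr0", "Pr1")
  new("ContactProbModel", q = q, pairs = pairs, states = states, marginals = marg)
}

pairIndex <- function(model, pair) {
  idx <- which(model@pairs[, 1L] == min(pair) & model@pairs[, 2L] == max(pair))
  if (length(idx) != 1L)
    stop("SSE pair ", pairLabel(pair[1L], pair[2L]), " is not in the universe")
  idx
}

#' Marginal contact distribution of one SSE pair
#'
#' @param model a \linkS4class{ContactProbModel}.
#' @param pair SSE pair c(a, b).
#' @return numeric c(Pr0, Pr1).
#' @export
contactMarginal <- function(model, pair) {
  model@marginals[pairIndex(model, pair), ]
}

#' Joint contact distribution of two SSE pairs
#'
#' @param model a \linkS4class{ContactProbModel}.
#' @param pair1,pair2 SSE pairs c(a, b).
#' @return 2 x 2 table, rows = state of pair1 (0, 1), columns = state of pair2.
#' @export
contactJointProb <- function(model, pair1, pair2) {
  i <- pairIndex(model, pair1); j <- pairIndex(model, pair2)
  if (i == j) {
    ## same edge = same random variable: degenerate diagonal joint, so that
    ## I(c, c) = H(c)
    m <- contactMarginal(model, pair1)
    return(matrix(c(m[1L], 0, 0, m[2L]), 2L, 2L,
                  dimnames = list(c("0", "1"), c("0", "1"))))
  }
  s1 <- model@states[, i]; s2 <- model@states[, j]
  q <- model@q
  jt <- matrix(0, 2L, 2L, dimnames = list(c("0", "1"), c("0", "1")))
  for (x in 0:1) for (x2 in 0:1)
    jt[x + 1L, x2 + 1L] <- mean(qWeight(x, s1, q) * qWeight(x2, s2, q))
  jt
}

#' Entropy (bits) of an SSE pair's contact state
#'
#' The relevance term of the mRMR objective: a high-entropy pair varies across
#' the models and helps differentiate them.
#'
#' @inheritParams contactMarginal
#' @return entropy in bits, in [0, 1].
#' @export
pairEntropy <- function(model, pair) {
  entropyBitsVec(contactMarginal(model, pair))
}

#' Mutual information (bits) between two SSE pairs' contact states
#'
#' The redundancy term of the mRMR objective: a high-MI pair of edges carries
#' overlapping information.
#'
#' @inheritParams contactJointProb
#' @return mutual information in bits, >= 0; I(c, c) = H(c).
#' @export
pairMutualInformation <- function(model, pair1, pair2) {
  miBitsTable(contactJointProb(model, pair1, pair2))
}

#' Greedy mRMR selection of a topological fingerprint
#'
#' First-order incremental search: starting from the empty set, each step adds
#' the SSE pair maximizing relevance minus mean redundancy with the already
#' selected pairs, H(c) - (1/|F|) sum I(c, c'); the first pick maximizes H(c)
#' alone. The search stops when the best incremental score (bits) drops below
#' \code{stopThreshold}, or when \code{maxPairs} pairs have been selected.
#' Argmax ties are broken by lexicographic SSE-pair order for determinism.
#'
#' @param model a \linkS4class{ContactProbModel}.
#' @param universe optional k x 2 matrix restricting the candidate pairs
#'   (default: the model's full universe).
#' @param stopThreshold score threshold in bits (default 0.01).
#' @param maxPairs optional cap on fingerprint size.
#' @return a \linkS4class{Fingerprint} (assessment slots NA; see
#'   [assessFingerprint()]).
#' @export
selectFingerprint <- function(model, universe = NULL, stopThreshold = 0.01,
                              maxPairs = NULL) {
  if (is.null(universe)) universe <- model@pairs
  universe <- matrix(as.integer(universe), ncol = 2L)
  if (nrow(universe) == 0L) stop("empty SSE-pair universe")
  if (is.null(maxPairs)) maxPairs <- nrow(universe)
  H <- apply(universe, 1L, function(p) pairEntropy(model, p))
  selected <- integer(0)
  scores <- numeric(0)
  avail <- rep(TRUE, nrow(universe))
  while (length(selected) < maxPairs && any(avail)) {
    cand <- which(avail)
    if (length(selected) == 0L) {
      sc <- H[cand]
    } else {
      red <- vapply(cand, function(ci) {
        mean(vapply(selected, function(si)
          pairMutualInformation(model, universe[ci, ], universe[si, ]), numeric(1)))
      }, numeric(1))
      sc <- H[cand] - red
    }
    best <- cand[which.max(sc)]          # which.max: first index wins ties (lexicographic)
    bestScore <- max(sc)
    if (bestScore < stopThreshold) break
    selected <- c(selected, best)
    scores <- c(scores, bestScore)
    avail[best] <- FALSE
  }
  new("Fingerprint", pairs = universe[selected, , drop = FALSE], scores = scores,
      epsilon = NA_real_, tieRatio = NA_real_, notaRatio = NA_real_)
}

#' Likelihood of an observed contact-state vector given a fold signature
#'
#' Naive conditional-independence likelihood over the fingerprint pairs: each
#' agreeing bit contributes q, each disagreeing one 1 - q, i.e.
#' q^(agreements) (1-q)^(disagreements).
#'
#' @param X observed binary vector (1 = SSE pair found in contact).
#' @param signature the fold's binary contact states on the same pairs.
#' @param q agreement weight.
#' @return the likelihood Pr(X | fold).
#' @export
foldLikelihood <- function(X, signature, q = 0.8) {
  X <- as.integer(X); signature <- as.integer(signature)
  if (length(X) != length(signature))
    stop("data vector and signature differ in length (", length(X), " vs ",
         length(signature), ")")
  d <- sum(X != signature)
  q^(length(X) - d) * (1 - q)^d
}
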