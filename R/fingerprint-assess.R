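## Plan assessment for a topological fingerprint (Bayes error, expected tie
## ratio, none-of-the-above ratio) and fold-level data interpretation.

FP_ENUM_CAP <- 20L  # refuse exponential enumeration beyond 2^20 datasets

## Likelihood of every enumerated dataset (rows) against unique signatures
## (columns), as a function of Hamming distance. q = 1 degenerates cleanly
## because 0^0 == 1 in R.
likFromDistance <- function(D, L, q) q^(L - D) * (1 - q)^D

hamming <- function(X, S) {
  X <- matrix(as.numeric(X), ncol = ncol(S))
  X %*% t(1 - S) + (1 - X) %*% t(S)
}

checkEnumCap <- function(L, what) {
  if (L > FP_ENUM_CAP)
    stop(what, ": |F| = ", L, " exceeds the enumeration cap of ", FP_ENUM_CAP,
         " (2^|F| datasets must be enumerated)")
}

uniqueSignatures <- function(signatures, priors = NULL) {
  signatures <- matrix(as.integer(signatures), ncol = ncol(signatures))
  M <- nrow(signatures)
  if (is.null(priors)) priors <- rep(1 / M, M)
  if (abs(sum(priors) - 1) > 1e-9) stop("model priors must sum to 1")
  key <- apply(signatures, 1L, paste, collapse = "")
  uk <- unique(key)
  U <- signatures[match(uk, key), , drop = FALSE]
  w <- vapply(uk, function(k) sum(priors[key == k]), numeric(1))
  list(U = U, w = unname(w))
}

#' Bayes error of a fingerprint by exact enumeration
#'
#' The probability of selecting a wrong fold: sums over every (model, dataset)
#' possibility, weighting by the model prior and the dataset likelihood, and
#' counts the cases where a fold with a different signature on F strictly beats
#' the correct model's fold. Models sharing the correct model's restricted
#' signature are the same fold, so being "beaten" by one is a tie, not an
#' error; ties contribute zero here and are tracked by [tieRatio()].
#'
#' @param signatures M x |F| binary matrix of the models' contact states on the
#'   fingerprint pairs.
#' @param q agreement weight of the probability model.
#' @param priors per-model prior probabilities (default uniform).
#' @return the Bayes error, in [0, 1].
#' @export
bayesError <- function(signatures, q = 0.8, priors = NULL) {
  L <- ncol(signatures)
  checkEnumCap(L, "bayesError")
  us <- uniqueSignatures(signatures, priors)
  X <- enumerateBits(L)
  Lik <- likFromDistance(hamming(X, us$U), L, q)
  nu <- ncol(Lik)
  if (nu == 1L) return(0)
  eps <- 0
  for (u in seq_len(nu)) {
    maxOther <- do.call(pmax, as.data.frame(Lik[, -u, drop = FALSE]))
    err <- maxOther > Lik[, u]
    eps <- eps + us$w[u] * sum(Lik[, u] * err)
  }
  eps
}

#' Expected tie ratio of a fingerprint by exact enumeration
#'
#' Mirrors the Bayes error sum but, instead of counting wrong decisions,
#' counts the probability mass of datasets for which the correct model is tied
#' for maximum likelihood with at least one model of a different fold, so no
#' single winner can be declared. Models whose restricted signatures on F
#' coincide have identical likelihoods, so folds that the fingerprint has not
#' yet separated tie permanently and τ starts high, dropping as discriminating
#' pairs are added; ties among models of the same fold are not ties in the
#' fold-determination sense and are excluded, which keeps the error and tie
#' events disjoint (ε + τ <= 1).
#'
#' @inheritParams bayesError
#' @param folds optional per-model fold identifiers (e.g. full-universe
#'   signature classes); two models tie only when their folds differ. Default:
#'   each distinct restricted signature is its own fold.
#' @return the expected tie ratio, in [0, 1].
#' @export
tieRatio <- function(signatures, q = 0.8, priors = NULL, folds = NULL) {
  signatures <- matrix(as.integer(signatures), ncol = ncol(signatures))
  L <- ncol(signatures)
  checkEnumCap(L, "tieRatio")
  M <- nrow(signatures)
  if (is.null(priors)) priors <- rep(1 / M, M)
  if (is.null(folds)) folds <- apply(signatures, 1L, paste, collapse = "")
  key <- apply(signatures, 1L, paste, collapse = "")
  uk <- unique(key)
  U <- signatures[match(uk, key), , drop = FALSE]
  w <- vapply(uk, function(k) sum(priors[key == k]), numeric(1))
  ## distinct folds represented within each restricted-signature group
  foldCount <- vapply(uk, function(k) length(unique(folds[key == k])), integer(1))
  X <- enumerateBits(L)
  Lik <- likFromDistance(hamming(X, U), L, q)
  rowMax <- do.call(pmax, as.data.frame(Lik))
  atMax <- Lik == rowMax
  nFoldsAtMax <- as.numeric(atMax %*% foldCount)
  tau <- 0
  for (u in seq_along(uk)) {
    tie <- atMax[, u] & nFoldsAtMax >= 2
    tau <- tau + w[[u]] * sum(Lik[, u] * tie)
  }
  unname(tau)
}

## Minimum Hamming distance from each enumerated dataset to the uncovered set,
## using ball counting: a vector at distance d from X is uncovered unless all
## choose(L, d) vectors at that distance are covered.
distToUncovered <- function(X, covered, L) {
  Dc <- hamming(X, covered)
  nCovTotal <- nrow(covered)
  if (nCovTotal >= 2^L) return(rep(Inf, nrow(X)))
  out <- numeric(nrow(X))
  minD <- apply(Dc, 1L, min)
  for (r in seq_len(nrow(X))) {
    if (minD[r] > 0) { out[r] <- 0; next }      # X itself is uncovered
    d <- 0
    repeat {
      if (sum(Dc[r, ] == d) < choose(L, d)) { out[r] <- d; break }
      d <- d + 1
    }
  }
  out
}

#' Expected none-of-the-above ratio of a fingerprint by exact enumeration
#'
#' The fraction of the 2^|F| possible datasets for which some uncovered fold
#' (a binary vector over F not matching any model's signature) has strictly
#' greater likelihood than the best covered fold. No prior is placed on the
#' datasets and uncovered folds are treated uniformly, giving a direct count of
#' how many experimental outcomes would force a none-of-the-above call.
#'
#' @param signatures M x |F| binary matrix of model signatures on the
#'   fingerprint pairs (only the set of distinct signatures matters).
#' @param q agreement weight.
#' @return the expected none-of-the-above ratio, in [0, 1].
#' @export
notaRatio <- function(signatures, q = 0.8) {
  L <- ncol(signatures)
  checkEnumCap(L, "notaRatio")
  if (L == 0L) return(0)
  us <- uniqueSignatures(signatures)
  X <- enumerateBits(L)
  dCov <- apply(hamming(X, us$U), 1L, min)
  dUnc <- distToUncovered(X, us$U, L)
  likCov <- likFromDistance(dCov, L, q)
  likUnc <- ifelse(is.infinite(dUnc), 0, likFromDistance(dUnc, L, q))
  mean(likUnc > likCov)
}

#' Assess a fingerprint, filling its epsilon / tieRatio / notaRatio slots
#'
#' @param fingerprint a \linkS4class{Fingerprint}.
#' @param graphs list of \linkS4class{SSEContactGraph} (one per model).
#' @param q agreement weight.
#' @param priors per-model priors (default uniform).
#' @return the fingerprint with assessment slots filled.
#' @export
assessFingerprint <- function(fingerprint, graphs, q = 0.8, priors = NULL) {
  sig <- signatureMatrix(graphs, fingerprint@pairs)
  folds <- modelFolds(graphs)
  fingerprint@epsilon <- bayesError(sig, q, priors)
  fingerprint@tieRatio <- tieRatio(sig, q, priors, folds = folds)
  fingerprint@notaRatio <- notaRatio(sig, q)
  fingerprint
}

## Fold identity of each model: its full-universe contact signature.
modelFolds <- function(graphs) {
  univ <- t(combn(graphs[[1L]]@sseIds, 2L))
  apply(signatureMatrix(graphs, univ), 1L, paste, collapse = "")
}

#' Per-step assessment trajectory of a fingerprint
#'
#' Re-evaluates Bayes error, tie ratio and none-of-the-above ratio for every
#' prefix of the greedy selection, producing the per-step table used to plot
#' the planning trend curves.
#'
#' @inheritParams assessFingerprint
#' @return data.frame (step, sse_a, sse_b, incremental_score, epsilon, tau, nu).
#' @export
fingerprintTrajectory <- function(fingerprint, graphs, q = 0.8, priors = NULL) {
  k <- nrow(fingerprint@pairs)
  out <- data.frame(step = seq_len(k),
                    sse_a = fingerprint@pairs[, 1L], sse_b = fingerprint@pairs[, 2L],
                    incremental_score = fingerprint@scores,
                    epsilon = NA_real_, tau = NA_real_, nu = NA_real_)
  folds <- modelFolds(graphs)
  for (s in seq_len(k)) {
    sig <- signatureMatrix(graphs, fingerprint@pairs[seq_len(s), , drop = FALSE])
    out$epsilon[s] <- bayesError(sig, q, priors)
    out$tau[s] <- tieRatio(sig, q, priors, folds = folds)
    out$nu[s] <- notaRatio(sig, q)
  }
  out
}

#' @rdname fingerprintTrajectory
#' @param trajectory the data.frame returned by [fingerprintTrajectory()].
#' @param file output path for the tab-separated report.
#' @export
writeFingerprintReport <- function(trajectory, file) {
  write.table(trajectory, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Interpret fold-level data: maximum-likelihood models and none-of-the-above
#'
#' Computes the likelihood of the observed fingerprint data X for every model,
#' returns the tied-for-optimal set, and flags none-of-the-above when some
#' uncovered fold (a contact-state vector not represented by any model) has
#' strictly greater likelihood than the best covered fold.
#'
#' @param X observed binary data vector, one bit per fingerprint pair.
#' @param signatures M x |F| binary matrix of model signatures on the
#'   fingerprint pairs.
#' @param q agreement weight.
#' @param modelIds optional model identifiers (default 1..M).
#' @return list with elements \code{bestModels}, \code{likelihoods},
#'   \code{noneOfTheAbove}, and (when flagged) \code{bestUncovered}.
#' @export
interpretFoldData <- function(X, signatures, q = 0.8, modelIds = NULL) {
  signatures <- matrix(as.integer(signatures), ncol = length(X))
  M <- nrow(signatures)
  if (is.null(modelIds)) modelIds <- as.character(seq_len(M))
  lik <- vapply(seq_len(M), function(m) foldLikelihood(X, signatures[m, ], q), numeric(1))
  names(lik) <- modelIds
  best <- modelIds[lik >= max(lik) - 0]
  L <- length(X)
  us <- uniqueSignatures(signatures)
  dCov <- min(hamming(matrix(X, nrow = 1L), us$U))
  dUnc <- distToUncovered(matrix(X, nrow = 1L), us$U, L)
  likCov <- likFromDistance(dCov, L, q)
  likUnc <- if (is.infinite(dUnc)) 0 else likFromDistance(dUnc, L, q)
  nota <- likUnc > likCov
  out <- list(bestModels = best, likelihoods = lik, noneOfTheAbove = nota)
  if (nota) out$bestUncovered <- nearestUncovered(X, us$U)
  out
}

## Lexicographically first uncovered vector at minimal Hamming distance from X.
nearestUncovered <- function(X, covered) {
  L <- length(X)
  key <- apply(covered, 1L, paste, collapse = "")
  for (d in 0:L) {
    flips <- if (d == 0L) list(integer(0)) else
      lapply(asplit(combn(L, d), 2L), as.integer)
    cands <- t(vapply(flips, function(f) { v <- X; v[f] <- 1L - v[f]; v }, integer(L)))
    cands <- cands[order(apply(cands, 1L, paste, collapse = "")), , drop = FALSE]
    for (r in seq_len(nrow(cands))) {
      if (!(paste(cands[r, ], collapse = "") %in% key)) return(as.integer(cands[r, ]))
    }
  }
  NULL  # covered set spans everything
}
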