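## Stage 2: residue cross-link graphs, noise-marginalized link probabilities,
## greedy mRMR cross-link selection, sigmoidal interpretation, and the
## cross-link Bayes error.

XL_ENUM_CAP <- 20L

#' Common residues of an SSE pair usable for cross-link planning
#'
#' Different models may place an SSE at somewhat different residues; planning
#' focuses on residues that appear inside the SSE's matched annotation interval
#' in at least half of the models possessing that SSE.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param ssePair SSE id pair c(a, b).
#' @return list with integer vectors \code{a} and \code{b}.
#' @export
commonResidues <- function(ensemble, ssePair) {
  one <- function(sid) {
    iv <- ensemble@matched[, sid, , drop = FALSE]
    has <- which(!is.na(iv[, 1L, 1L]))
    if (length(has) == 0L)
      stop("SSE ", sid, " has no matched annotation in any model")
    lo <- min(iv[has, 1L, 1L]); hi <- max(iv[has, 1L, 2L])
    pos <- seq.int(lo, hi)
    cnt <- vapply(pos, function(p)
      sum(iv[has, 1L, 1L] <= p & iv[has, 1L, 2L] >= p), integer(1))
    res <- pos[2L * cnt >= length(has)]
    if (length(res) == 0L)
      stop("SSE ", sid, ": no residue is common to half of the models possessing it")
    as.integer(res)
  }
  list(a = one(ssePair[1L]), b = one(ssePair[2L]))
}

#' Residue cross-link graph of one model for an SSE pair
#'
#' Edges are the cross-SSE residue pairs whose C-beta-C-beta distance is at
#' most \code{maxDistance} (19 Angstrom by default, the cross-linkable window
#' for engineered disulfides).
#'
#' @param model a \linkS4class{StructuralModel}.
#' @param R common residues as returned by [commonResidues()].
#' @param maxDistance cross-linkable distance cap in Angstrom (default 19).
#' @return data.frame (res_i, res_j, distance); possibly empty.
#' @export
buildXlinkGraph <- function(model, R, maxDistance = 19.0) {
  ia <- match(R$a, model@resno); ib <- match(R$b, model@resno)
  ra <- R$a[!is.na(ia)]; rb <- R$b[!is.na(ib)]
  if (length(ra) == 0L || length(rb) == 0L)
    return(data.frame(res_i = integer(0), res_j = integer(0), distance = numeric(0)))
  d <- distMatrix(model@cb[ia[!is.na(ia)], , drop = FALSE],
                  model@cb[ib[!is.na(ib)], , drop = FALSE])
  hit <- which(d <= maxDistance, arr.ind = TRUE)
  out <- data.frame(res_i = ra[hit[, 1L]], res_j = rb[hit[, 2L]],
                    distance = d[hit])
  out[order(out$res_i, out$res_j), , drop = FALSE]
}

## Candidate pool for planning: union over all models of cross-linkable pairs.
candidateLinks <- function(ensemble, R, maxDistance = 19.0) {
  keys <- unique(unlist(lapply(ensemble@models, function(m) {
    g <- buildXlinkGraph(m, R, maxDistance)
    paste(g$res_i, g$res_j)
  })))
  if (length(keys) == 0L) return(matrix(integer(0), ncol = 2L))
  m <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

## Per-(latent combo) link probabilities for a set of candidate residue pairs.
## Latent combos enumerate (model in class) x (delta_a) x (delta_b) x (backbone);
## weights multiply the uniform model weight, the two independent per-SSE offset
## probabilities, and the backbone probability. Returns list(w, P) with
## P[combo, candidate].
linkProbTable <- function(models, classIdx, candidates, noise, tiers) {
  offs <- noise$offsets
  dvals <- as.integer(names(offs))
  nC <- nrow(candidates)
  nD <- length(dvals)
  nB <- vapply(noise$backbones[classIdx], function(b) length(b$probs), integer(1))
  P <- matrix(NA_real_, sum(nB) * nD * nD, nC)
  w <- numeric(nrow(P))
  ## unique shifted residue ids per SSE side; each (offset, candidate) indexes them
  uA <- sort(unique(as.integer(outer(candidates[, 1L], dvals, "+"))))
  uB <- sort(unique(as.integer(outer(candidates[, 2L], dvals, "+"))))
  iA <- lapply(dvals, function(da) match(candidates[, 1L] + da, uA))
  iB <- lapply(dvals, function(db) match(candidates[, 2L] + db, uB))
  r <- 0L
  for (m in classIdx) {
    mod <- models[[m]]
    bb <- noise$backbones[[m]]
    rA <- match(uA, mod@resno); okA <- !is.na(rA)
    rB <- match(uB, mod@resno); okB <- !is.na(rB)
    for (b in seq_along(bb$probs)) {
      cb <- bb$cbList[[b]]
      D <- matrix(NA_real_, length(uA), length(uB))  # NA = residue absent -> pFar
      if (any(okA) && any(okB))
        D[okA, okB] <- distMatrix(cb[rA[okA], , drop = FALSE],
                                  cb[rB[okB], , drop = FALSE])
      Tm <- tierProb(D, tiers)                       # tier once per backbone
      dim(Tm) <- dim(D)
      for (a in seq_len(nD)) {
        for (bo in seq_len(nD)) {
          r <- r + 1L
          P[r, ] <- Tm[cbind(iA[[a]], iB[[bo]])]
          w[r] <- bb$probs[b] * offs[a] * offs[bo] / length(classIdx)
        }
      }
    }
  }
  list(w = w, P = P)
}

#' Noise-marginalized cross-link probability
#'
#' Averages the tiered link probability over the in-contact models and over the
#' misalignment offsets (one independent offset per SSE) and backbone
#' alternatives; the cross-links are conditionally independent given the
#' offsets and backbone, so joints of several links marginalize the product of
#' conditionals over the shared latent variables.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param classIdx indices of the models in the conditioning class.
#' @param i,j residue pair.
#' @param noise a noise model from [makeNoiseModel()] / [noNoiseModel()].
#' @param tiers a [linkProbTiers()] object.
#' @return marginal probability of observing the cross-link.
#' @export
marginalLinkProb <- function(ensemble, classIdx, i, j, noise = NULL,
                             tiers = linkProbTiers()) {
  if (length(classIdx) == 0L) stop("empty model class")
  if (is.null(noise)) noise <- noNoiseModel(ensemble)
  tab <- linkProbTable(ensemble@models, classIdx, cbind(i, j), noise, tiers)
  sum(tab$w * tab$P[, 1L])
}

## Vectorized mutual information (bits) of 2x2 joints given cell probabilities
## (Pr(l=0,c=0), Pr(l=0,c=1), Pr(l=1,c=0), Pr(l=1,c=1)), renormalized.
miBits4 <- function(p00, p01, p10, p11) {
  p00 <- pmax(p00, 0); p01 <- pmax(p01, 0); p10 <- pmax(p10, 0); p11 <- pmax(p11, 0)
  tot <- p00 + p01 + p10 + p11
  p00 <- p00 / tot; p01 <- p01 / tot; p10 <- p10 / tot; p11 <- p11 / tot
  r0 <- p00 + p01; r1 <- p10 + p11; c0 <- p00 + p10; c1 <- p01 + p11
  term <- function(p, a, b) ifelse(p > 0, p * log2(p / (a * b)), 0)
  pmax(term(p00, r0, c0) + term(p01, r0, c1) +
       term(p10, r1, c0) + term(p11, r1, c1), 0)
}

## Relevance I(l, c) of each candidate from its in-contact marginal and the
## background rate, weighted by the stage-1 contact probability.
linkRelevance <- function(marg, pc1, pFar) {
  pc0 <- 1 - pc1
  miBits4(pc0 * (1 - pFar), pc1 * (1 - marg), pc0 * pFar, pc1 * marg)
}

## Redundancy I(l, l') of candidates `ls` against one link `l2`, with joints
## marginalized over the shared latents (model, offsets, backbone) and over c.
linkRedundancy <- function(tab, ls, l2, marg, pc1, pFar) {
  e11 <- as.numeric((tab$w * tab$P[, l2]) %*% tab$P[, ls, drop = FALSE])
  pc0 <- 1 - pc1
  j11 <- pc1 * e11 + pc0 * pFar^2
  j10 <- pc1 * pmax(marg[ls] - e11, 0) + pc0 * pFar * (1 - pFar)
  j01 <- pc1 * pmax(marg[l2] - e11, 0) + pc0 * (1 - pFar) * pFar
  j00 <- pmax(1 - j11 - j10 - j01, 0)
  miBits4(j00, j01, j10, j11)
}

#' Greedy mRMR selection of a cross-link plan for one SSE pair
#'
#' Candidates are the union over models of cross-linkable residue pairs
#' (<= \code{maxDistance}). Each step adds the candidate maximizing relevance
#' I(l, c) — the mutual information between the link outcome and the contact
#' state, with in-contact link probabilities marginalized over the noise model
#' and the no-contact class at the background rate pFar — minus the mean
#' redundancy I(l, l') with the already selected links; ties break
#' lexicographically. Selection stops at \code{planSize} links or when the
#' candidates are exhausted.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param ssePair SSE id pair c(a, b).
#' @param contactStates per-model 0/1 contact states of the pair.
#' @param noise noise model (default [makeNoiseModel()] defaults via NULL ->
#'   no noise; pass an explicit model for misalignment/flexibility handling).
#' @param tiers a [linkProbTiers()] object.
#' @param planSize number of experiments to plan (default 10).
#' @param k0 sigmoid decision midpoint (default 3; reduced to fit small plans).
#' @param pContact stage-1 Pr(c = 1); default NULL uses the q-smoothed
#'   frequency of \code{contactStates}.
#' @param q agreement weight for the default \code{pContact}.
#' @param maxDistance cross-linkable window in Angstrom (default 19).
#' @return a \linkS4class{CrossLinkPlan} (epsilonXlink NA; see
#'   [xlinkBayesError()]).
#' @export
selectLinks <- function(ensemble, ssePair, contactStates, noise = NULL,
                        tiers = linkProbTiers(), planSize = 10L, k0 = 3L,
                        pContact = NULL, q = 0.8, maxDistance = 19.0) {
  if (is.null(noise)) noise <- noNoiseModel(ensemble)
  if (is.null(pContact))
    pContact <- mean(q * contactStates + (1 - q) * (1 - contactStates))
  R <- commonResidues(ensemble, ssePair)
  cand <- candidateLinks(ensemble, R, maxDistance)
  if (nrow(cand) == 0L)
    stop("SSE pair ", pairLabel(ssePair[1L], ssePair[2L]),
         " cannot be probed: no candidate cross-links within ", maxDistance, " Angstrom")
  classIdx <- which(contactStates == 1L)
  if (length(classIdx) == 0L) classIdx <- seq_along(ensemble@models)
  tab <- linkProbTable(ensemble@models, classIdx, cand, noise, tiers)
  marg <- as.numeric(tab$w %*% tab$P)
  rel <- linkRelevance(marg, pContact, tiers$pFar)
  nSel <- min(planSize, nrow(cand))
  selected <- integer(0)
  scores <- numeric(0)
  redSum <- numeric(nrow(cand))
  avail <- rep(TRUE, nrow(cand))
  while (length(selected) < nSel) {
    candIdx <- which(avail)
    sc <- rel[candIdx] -
      if (length(selected)) redSum[candIdx] / length(selected) else 0
    pick <- candIdx[which.max(sc)]
    selected <- c(selected, pick)
    scores <- c(scores, max(sc))
    avail[pick] <- FALSE
    if (length(selected) < nSel) {
      upd <- which(avail)
      redSum[upd] <- redSum[upd] +
        linkRedundancy(tab, upd, pick, marg, pContact, tiers$pFar)
    }
  }
  k0eff <- min(as.integer(k0), length(selected) - 1L)
  new("CrossLinkPlan", ssePair = as.integer(ssePair),
      links = cand[selected, , drop = FALSE], scores = scores,
      linkProbs = marg[selected], k0 = as.numeric(max(k0eff, 0L)),
      planSize = as.numeric(length(selected)), epsilonXlink = NA_real_)
}

#' Sigmoidal likelihood of cross-link data given contact
#'
#' The likelihood of observing k detected cross-links out of \code{planSize}
#' given the SSE pair is in contact: a logistic in k centered at the
#' minimum-belief count \code{k0}, Pr = 1 / (1 + exp(-slope (k - k0))). With
#' the default slope log(19)/k0 and k0 = 3 the anchors are 0.05, 0.5 and 0.95
#' at k = 0, 3, 6. The no-contact likelihood is the mirrored logistic,
#' 1 - Pr(k | c = 1), so the contact decision reduces to comparing k with k0.
#'
#' @param k number of detected cross-links (0..planSize).
#' @param planSize number of planned experiments (default 10).
#' @param k0 minimum count to start believing in contact (default 3).
#' @param slope logistic steepness (default log(19)/k0).
#' @return Pr(data | c = 1).
#' @export
contactLikelihood <- function(k, planSize = 10L, k0 = 3L, slope = NULL) {
  if (any(k < 0 | k > planSize))
    stop("k must be between 0 and planSize = ", planSize)
  if (is.null(slope)) slope <- if (k0 > 0) log(19) / k0 else log(19)
  if (slope <= 0) stop("slope must be > 0")
  logistic(slope * (k - k0))
}

#' Decide SSE contact from observed cross-link outcomes
#'
#' Compares Pr(Y | c = 1) and Pr(Y | c = 0) under the sigmoidal likelihood and
#' returns the more likely contact state; the midpoint tie k = k0 resolves
#' conservatively to "not in contact" and is flagged.
#'
#' @param Y binary outcome vector, one entry per planned link.
#' @param plan the \linkS4class{CrossLinkPlan} the data belong to.
#' @param slope optional logistic steepness override.
#' @return list(contact, lik1, lik0, tie, k).
#' @export
interpretXlinkData <- function(Y, plan, slope = NULL) {
  Y <- as.integer(Y)
  if (length(Y) != nrow(plan@links))
    stop("outcome vector length ", length(Y), " does not match plan size ",
         nrow(plan@links))
  if (!all(Y %in% c(0L, 1L))) stop("outcomes must be 0/1")
  k <- sum(Y)
  l1 <- contactLikelihood(k, planSize = length(Y), k0 = plan@k0, slope = slope)
  l0 <- 1 - l1
  list(contact = as.integer(l1 > l0), lik1 = l1, lik0 = l0, tie = l1 == l0, k = k)
}

#' Cross-link Bayes error of a plan by exact enumeration
#'
#' Probability of a wrong contact decision: with uninformative prior
#' Pr(c=1) = Pr(c=0) = 0.5, sums over all 2^|L| outcome vectors the generative
#' probability of those leading to the wrong decision. Given contact, outcomes
#' are conditionally independent given the shared latent (model, offsets,
#' backbone) and the generative law marginalizes the product of per-link
#' tiered probabilities over the noise model; given no contact each link fires
#' independently at the background rate pFar.
#'
#' @param plan a \linkS4class{CrossLinkPlan}.
#' @param ensemble the \linkS4class{ModelEnsemble}.
#' @param contactStates per-model 0/1 contact states of the plan's SSE pair.
#' @param noise noise model (NULL -> no noise).
#' @param tiers a [linkProbTiers()] object.
#' @param slope optional logistic steepness override for the decision rule.
#' @return the Bayes error, in [0, 1].
#' @export
xlinkBayesError <- function(plan, ensemble, contactStates, noise = NULL,
                            tiers = linkProbTiers(), slope = NULL) {
  L <- nrow(plan@links)
  if (L > XL_ENUM_CAP)
    stop("xlinkBayesError: plan of ", L, " links exceeds the enumeration cap of ",
         XL_ENUM_CAP)
  if (is.null(noise)) noise <- noNoiseModel(ensemble)
  classIdx <- which(contactStates == 1L)
  if (length(classIdx) == 0L) classIdx <- seq_along(ensemble@models)
  tab <- linkProbTable(ensemble@models, classIdx, plan@links, noise, tiers)
  P <- pmin(pmax(tab$P, 1e-12), 1 - 1e-12)
  Y <- enumerateBits(L)
  logP <- log(P); log1P <- log1p(-P)
  lik1 <- as.numeric(exp(Y %*% t(logP) + (1 - Y) %*% t(log1P)) %*% tab$w)
  pf <- min(max(tiers$pFar, 1e-12), 1 - 1e-12)
  k <- rowSums(Y)
  lik0 <- pf^k * (1 - pf)^(L - k)
  l1 <- contactLikelihood(k, planSize = L, k0 = plan@k0, slope = slope)
  decide1 <- l1 > 1 - l1
  0.5 * sum(lik1[!decide1]) + 0.5 * sum(lik0[decide1])
}

#' Plan cross-links for every SSE pair of a fingerprint
#'
#' Runs [selectLinks()] (and optionally [xlinkBayesError()]) for each
#' fingerprint SSE pair; an unprobeable pair produces a named warning and is
#' skipped so the remaining pairs are still planned. The overall experimental
#' plan is the union (concatenation) of the per-pair plans.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param fingerprint a \linkS4class{Fingerprint}.
#' @param graphs the models' contact graphs (for per-pair contact states).
#' @param probModel optional \linkS4class{ContactProbModel} supplying the
#'   stage-1 Pr(c) used as relevance weight (NULL -> q-smoothed frequency).
#' @param noise noise model (NULL -> no noise).
#' @param tiers,planSize,k0,q,maxDistance see [selectLinks()].
#' @param assess compute each plan's Bayes error (default TRUE).
#' @return named list of \linkS4class{CrossLinkPlan} (names "a-b").
#' @export
planCrossLinks <- function(ensemble, fingerprint, graphs, probModel = NULL,
                           noise = NULL, tiers = linkProbTiers(), planSize = 10L,
                           k0 = 3L, q = 0.8, maxDistance = 19.0, assess = TRUE) {
  plans <- list()
  for (r in seq_len(nrow(fingerprint@pairs))) {
    pr <- fingerprint@pairs[r, ]
    states <- as.integer(signatureMatrix(graphs, matrix(pr, ncol = 2L)))
    pc1 <- if (!is.null(probModel)) contactMarginal(probModel, pr)[["Pr1"]] else NULL
    plan <- tryCatch(
      selectLinks(ensemble, pr, states, noise = noise, tiers = tiers,
                  planSize = planSize, k0 = k0, pContact = pc1, q = q,
                  maxDistance = maxDistance),
      error = function(e) { warning(conditionMessage(e)); NULL })
    if (is.null(plan)) next
    if (assess)
      plan@epsilonXlink <- xlinkBayesError(plan, ensemble, states, noise, tiers)
    plans[[pairLabel(pr[1L], pr[2L])]] <- plan
  }
  plans
}

#' Write / read a combined cross-link plan file
#'
#' Tab-separated with one row per planned link: sse_a, sse_b, step, res_i,
#' res_j, incremental_score, marginal_link_prob, k0, plan_size, epsilon_xlink
#' (the per-pair summary columns repeat on each of the pair's rows).
#'
#' @param plans named list of \linkS4class{CrossLinkPlan}.
#' @param file output path.
#' @export
writeCrossLinkPlans <- function(plans, file) {
  rows <- do.call(rbind, lapply(plans, function(p) {
    data.frame(sse_a = p@ssePair[1L], sse_b = p@ssePair[2L],
               step = seq_len(nrow(p@links)),
               res_i = p@links[, 1L], res_j = p@links[, 2L],
               incremental_score = p@scores, marginal_link_prob = p@linkProbs,
               k0 = p@k0, plan_size = p@planSize, epsilon_xlink = p@epsilonXlink)
  }))
  write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCrossLinkPlans
#' @export
readCrossLinkPlans <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t")
  plans <- list()
  for (key in unique(paste(tab$sse_a, tab$sse_b))) {
    sub <- tab[paste(tab$sse_a, tab$sse_b) == key, , drop = FALSE]
    sub <- sub[order(sub$step), , drop = FALSE]
    plans[[pairLabel(sub$sse_a[1L], sub$sse_b[1L])]] <-
      new("CrossLinkPlan", ssePair = c(sub$sse_a[1L], sub$sse_b[1L]),
          links = cbind(sub$res_i, sub$res_j), scores = sub$incremental_score,
          linkProbs = sub$marginal_link_prob, k0 = sub$k0[1L],
          planSize = sub$plan_size[1L], epsilonXlink = sub$epsilon_xlink[1L])
  }
  plans
}

#' Read experimental cross-link outcomes
#'
#' Tab-separated: res_i, res_j, outcome (0/1); a header line is optional.
#'
#' @param file input path.
#' @return data.frame (res_i, res_j, outcome).
#' @export
readXlinkData <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  start <- if (length(lines) && grepl("res_i", lines[1L])) 2L else 1L
  out <- data.frame(res_i = integer(0), res_j = integer(0), outcome = integer(0))
  for (ln in seq.int(start, length.out = max(0L, length(lines) - start + 1L))) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    v <- suppressWarnings(as.integer(f))
    if (length(f) != 3L || any(is.na(v)) || !(v[3L] %in% c(0L, 1L)))
      stop("malformed cross-link data at line ", ln, ": '", lines[ln], "'")
    out[nrow(out) + 1L, ] <- v
  }
  out
}
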