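## Independent oracles: brute-force enumerations, naive greedy
## re-implementations, and seeded Monte-Carlo samplers. These deliberately
## avoid the package's internal code paths.

## Marginal Pr(c = x) by the literal double sum over models and y.
oracleMarginal <- function(states, q) {
  M <- length(states)
  pr <- c(0, 0)
  for (x in 0:1) for (i in seq_len(M)) for (y in 0:1) {
    if (states[i] == y) pr[x + 1] <- pr[x + 1] + (if (x == y) q else 1 - q) / M
  }
  pr
}

## Joint Pr(c = x, c' = x') by the literal quadruple sum.
oracleJoint <- function(s1, s2, q) {
  M <- length(s1)
  jt <- matrix(0, 2, 2)
  for (x in 0:1) for (x2 in 0:1) for (i in seq_len(M)) for (y in 0:1) for (y2 in 0:1) {
    if (s1[i] == y && s2[i] == y2)
      jt[x + 1, x2 + 1] <- jt[x + 1, x2 + 1] +
        (if (x == y) q else 1 - q) * (if (x2 == y2) q else 1 - q) / M
  }
  jt
}

oracleEntropy <- function(p) -sum(ifelse(p > 0, p * log2(p), 0))

oracleMI <- function(jt) {
  pm1 <- rowSums(jt); pm2 <- colSums(jt)
  s <- 0
  for (i in 1:2) for (j in 1:2) if (jt[i, j] > 0)
    s <- s + jt[i, j] * log2(jt[i, j] / (pm1[i] * pm2[j]))
  s
}

## Naive first-order mRMR over SSE pairs, recomputed from scratch each step.
oracleGreedyFingerprint <- function(states, universe, q, stopThreshold = 0.01,
                                    maxPairs = nrow(universe)) {
  sel <- integer(0); scores <- numeric(0)
  repeat {
    if (length(sel) >= maxPairs) break
    best <- -Inf; bestIdx <- NA
    for (ci in setdiff(seq_len(nrow(universe)), sel)) {
      h <- oracleEntropy(oracleMarginal(states[, ci], q))
      red <- 0
      if (length(sel) > 0) {
        for (si in sel) red <- red + oracleMI(oracleJoint(states[, ci], states[, si], q))
        red <- red / length(sel)
      }
      sc <- h - red
      if (sc > best + 1e-12) { best <- sc; bestIdx <- ci }
    }
    if (best < stopThreshold) break
    sel <- c(sel, bestIdx); scores <- c(scores, best)
  }
  list(idx = sel, scores = scores)
}

likOf <- function(X, sig, q) q^sum(X == sig) * (1 - q)^sum(X != sig)

## Monte-Carlo Bayes error: sample the correct model and its dataset, count
## strict beats by a different restricted signature.
oracleEpsMC <- function(signatures, q, n, seed) {
  set.seed(seed)
  M <- nrow(signatures); L <- ncol(signatures)
  key <- apply(signatures, 1, paste, collapse = "")
  U <- signatures[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  err <- logical(n)
  for (t in seq_len(n)) {
    m <- sample.int(M, 1)
    X <- ifelse(runif(L) < q, signatures[m, ], 1 - signatures[m, ])
    likm <- likOf(X, signatures[m, ], q)
    others <- which(ukey != key[m])
    err[t] <- any(vapply(others, function(u) likOf(X, U[u, ], q), numeric(1)) > likm)
  }
  list(est = mean(err), se = sd(err) / sqrt(n))
}

## Monte-Carlo tie ratio: the correct model ties for the maximum with a model
## of a different fold.
oracleTauMC <- function(signatures, q, folds, n, seed) {
  set.seed(seed)
  M <- nrow(signatures); L <- ncol(signatures)
  tie <- logical(n)
  for (t in seq_len(n)) {
    m <- sample.int(M, 1)
    X <- ifelse(runif(L) < q, signatures[m, ], 1 - signatures[m, ])
    lik <- vapply(seq_len(M), function(i) likOf(X, signatures[i, ], q), numeric(1))
    winners <- which(lik >= max(lik) - 1e-12)
    tie[t] <- (m %in% winners) && length(unique(folds[winners])) >= 2
  }
  list(est = mean(tie), se = sd(tie) / sqrt(n))
}

## Monte-Carlo none-of-the-above ratio: X uniform; best uncovered vs best
## covered likelihood found by scanning all binary vectors.
oracleNuMC <- function(signatures, q, n, seed) {
  set.seed(seed)
  L <- ncol(signatures)
  key <- apply(signatures, 1, paste, collapse = "")
  allV <- as.matrix(expand.grid(rep(list(0:1), L)))
  covered <- apply(allV, 1, paste, collapse = "") %in% key
  hit <- logical(n)
  for (t in seq_len(n)) {
    X <- sample(0:1, L, replace = TRUE)
    lik <- apply(allV, 1, function(v) likOf(X, v, q))
    hit[t] <- max(lik[!covered]) > max(lik[covered])
  }
  list(est = mean(hit), se = sd(hit) / sqrt(n))
}

## Exhaustive none-of-the-above ratio by scanning datasets and fold vectors.
oracleNuExact <- function(signatures, q) {
  L <- ncol(signatures)
  key <- apply(signatures, 1, paste, collapse = "")
  allV <- as.matrix(expand.grid(rep(list(0:1), L)))
  covered <- apply(allV, 1, paste, collapse = "") %in% key
  mean(apply(allV, 1, function(X) {
    lik <- apply(allV, 1, function(v) likOf(X, v, q))
    if (!any(!covered)) return(FALSE)
    max(lik[!covered]) > max(lik[covered])
  }))
}

## Naive stage-2 greedy mRMR, with marginals and joints from explicit loops
## over (model, delta_a, delta_b, backbone) and exported linkProb().
oracleGreedyLinks <- function(ensemble, classIdx, candidates, noise, tiers,
                              planSize, pc1) {
  models <- ensembleModels(ensemble)
  offs <- noise$offsets
  dvals <- as.integer(names(offs))
  combos <- list()
  for (m in classIdx) {
    bb <- noise$backbones[[m]]
    for (b in seq_along(bb$probs)) for (da in dvals) for (db in dvals)
      combos[[length(combos) + 1]] <- list(
        m = m, cb = bb$cbList[[b]], da = da, db = db,
        w = bb$probs[b] * offs[as.character(da)] * offs[as.character(db)] /
          length(classIdx))
  }
  pOf <- function(cand) vapply(combos, function(co)
    linkProb(models[[co$m]], cand[1], cand[2], co$da, co$db, co$cb, tiers), numeric(1))
  W <- vapply(combos, function(co) co$w, numeric(1))
  Pmat <- vapply(seq_len(nrow(candidates)), function(k) pOf(candidates[k, ]),
                 numeric(length(combos)))
  marg <- as.numeric(W %*% Pmat)
  pf <- tiers$pFar; pc0 <- 1 - pc1
  miFrom <- function(j00, j01, j10, j11) {
    jt <- matrix(pmax(c(j00, j10, j01, j11), 0), 2, 2)
    oracleMI(jt / sum(jt))
  }
  relOf <- function(k) miFrom(pc0 * (1 - pf), pc1 * (1 - marg[k]), pc0 * pf, pc1 * marg[k])
  redOf <- function(k, k2) {
    e11 <- sum(W * Pmat[, k] * Pmat[, k2])
    miFrom(1 - (pc1 * e11 + pc0 * pf^2) -
             (pc1 * max(marg[k] - e11, 0) + pc0 * pf * (1 - pf)) -
             (pc1 * max(marg[k2] - e11, 0) + pc0 * (1 - pf) * pf),
           pc1 * max(marg[k2] - e11, 0) + pc0 * (1 - pf) * pf,
           pc1 * max(marg[k] - e11, 0) + pc0 * pf * (1 - pf),
           pc1 * e11 + pc0 * pf^2)
  }
  sel <- integer(0); scores <- numeric(0)
  while (length(sel) < min(planSize, nrow(candidates))) {
    best <- -Inf; bestIdx <- NA
    for (k in setdiff(seq_len(nrow(candidates)), sel)) {
      sc <- relOf(k)
      if (length(sel)) sc <- sc - mean(vapply(sel, function(s) redOf(k, s), numeric(1)))
      if (sc > best + 1e-12) { best <- sc; bestIdx <- k }
    }
    sel <- c(sel, bestIdx); scores <- c(scores, best)
  }
  list(links = candidates[sel, , drop = FALSE], scores = scores, marg = marg[sel])
}

## Monte-Carlo cross-link Bayes error: simulate c, latents and outcomes.
oracleXlinkEpsMC <- function(plan, ensemble, classIdx, noise, tiers, n, seed) {
  set.seed(seed)
  models <- ensembleModels(ensemble)
  offs <- noise$offsets
  dvals <- as.integer(names(offs))
  L <- nrow(planLinks(plan))
  err <- logical(n)
  for (t in seq_len(n)) {
    c1 <- runif(1) < 0.5
    if (c1) {
      m <- classIdx[sample.int(length(classIdx), 1)]
      bb <- noise$backbones[[m]]
      b <- sample.int(length(bb$probs), 1, prob = bb$probs)
      da <- sample(dvals, 1, prob = offs)
      db <- sample(dvals, 1, prob = offs)
      p <- vapply(seq_len(L), function(k)
        linkProb(models[[m]], planLinks(plan)[k, 1], planLinks(plan)[k, 2],
                 da, db, bb$cbList[[b]], tiers), numeric(1))
    } else {
      p <- rep(tiers$pFar, L)
    }
    k <- sum(runif(L) < p)
    decision <- k > plan@k0
    err[t] <- decision != c1
  }
  list(est = mean(err), se = sd(err) / sqrt(n))
}

## Pairwise Mann-Whitney AUC with midrank tie handling.
oracleAuc <- function(lik, labels) {
  pos <- lik[labels]; neg <- lik[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
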