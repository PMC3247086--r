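## Probability model, entropy/MI, mRMR selection, plan assessment and fold
## interpretation — checked against closed forms and independent oracles.

graphFromStates <- function(states, pairs, sseIds = sort(unique(as.integer(pairs)))) {
  ## one SSEContactGraph per row of a model x pair state matrix
  lapply(seq_len(nrow(states)), function(m)
    new("SSEContactGraph", modelId = paste0("m", m), sseIds = as.integer(sseIds),
        contacts = pairs[states[m, ] == 1L, , drop = FALSE]))
}

toyPairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))

test_that("q-smoothed marginals follow the counting formula", {
  st <- cbind(c(1L, 1L, 1L, 1L), c(1L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L))
  pm <- estimateContactProbs(graphFromStates(st, toyPairs), q = 0.8)
  expect_equal(unname(contactMarginal(pm, c(1, 2))), c(0.2, 0.8))
  expect_equal(unname(contactMarginal(pm, c(1, 3))), c(0.5, 0.5))
  expect_equal(unname(contactMarginal(pm, c(2, 3))), c(0.65, 0.35))
  expect_error(estimateContactProbs(graphFromStates(st, toyPairs), q = 0.5),
               "degenerate")
})

test_that("joint tables equal the brute-force double sum over models and y", {
  set.seed(42)
  st <- matrix(rbinom(9, 1, 0.5), 3, 3)
  pm <- estimateContactProbs(graphFromStates(st, toyPairs), q = 0.8)
  for (i in 1:3) for (j in 1:3) {
    jt <- contactJointProb(pm, toyPairs[i, ], toyPairs[j, ])
    if (i != j)
      expect_equal(unname(jt), oracleJoint(st[, i], st[, j], 0.8), tolerance = 1e-12)
    ## normalization and marginal consistency
    expect_equal(sum(jt), 1, tolerance = 1e-9)
    expect_equal(unname(rowSums(jt)), unname(contactMarginal(pm, toyPairs[i, ])),
                 tolerance = 1e-9)
  }
})

test_that("entropy matches closed forms", {
  st <- cbind(c(1L, 0L, 1L, 0L), c(1L, 1L, 1L, 1L), c(1L, 1L, 1L, 0L))
  pm1 <- estimateContactProbs(graphFromStates(st, toyPairs), q = 1)
  expect_equal(pairEntropy(pm1, c(1, 2)), 1)                 # 50/50
  expect_equal(pairEntropy(pm1, c(1, 3)), 0)                 # unanimous at q = 1
  pm8 <- estimateContactProbs(graphFromStates(st, toyPairs), q = 0.8)
  expect_equal(pairEntropy(pm8, c(1, 3)),
               -0.2 * log2(0.2) - 0.8 * log2(0.8), tolerance = 1e-9)
  expect_equal(pairEntropy(pm8, c(1, 3)), 0.7219, tolerance = 1e-4)
})

test_that("mutual information: independence, self-information, oracle", {
  ## independent pattern across 4 models
  st <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L))
  pm <- estimateContactProbs(graphFromStates(st, toyPairs), q = 0.8)
  expect_equal(pairMutualInformation(pm, c(1, 2), c(1, 3)), 0, tolerance = 1e-12)
  ## the same edge carries its full entropy: I(c, c) = H(c)
  expect_equal(pairMutualInformation(pm, c(1, 2), c(1, 2)),
               pairEntropy(pm, c(1, 2)), tolerance = 1e-12)
  ## at q = 1, a pair with identical states across models is fully redundant
  pmq1 <- estimateContactProbs(graphFromStates(st, toyPairs), q = 1)
  expect_equal(pairMutualInformation(pmq1, c(1, 2), c(2, 3)),
               pairEntropy(pmq1, c(1, 2)), tolerance = 1e-12)
  set.seed(7)
  st2 <- matrix(rbinom(12, 1, 0.4), 4, 3)
  pm2 <- estimateContactProbs(graphFromStates(st2, toyPairs), q = 0.7)
  for (i in 1:3) for (j in 1:3)
    if (i != j)
      expect_equal(pairMutualInformation(pm2, toyPairs[i, ], toyPairs[j, ]),
                   oracleMI(oracleJoint(st2[, i], st2[, j], 0.7)), tolerance = 1e-12)
})

test_that("mRMR selection handles dominant, redundant and threshold cases", {
  ## q = 1 so unanimous pairs carry zero entropy
  st <- cbind(c(1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
              rep(1L, 10), rep(0L, 10))
  pm <- estimateContactProbs(graphFromStates(st, toyPairs), q = 1)
  fp <- selectFingerprint(pm)
  expect_equal(fingerprintPairs(fp), toyPairs[1, , drop = FALSE])
  ## two perfectly correlated pairs with equal entropy: only one survives
  st2 <- cbind(c(1L, 0L, 1L, 0L), c(1L, 0L, 1L, 0L), rep(1L, 4))
  pm2 <- estimateContactProbs(graphFromStates(st2, toyPairs), q = 1)
  fp2 <- selectFingerprint(pm2)
  expect_equal(nrow(fingerprintPairs(fp2)), 1L)
  expect_equal(fp2@scores, 1)
})

test_that("greedy trajectory equals the from-scratch first-order oracle", {
  fx <- mixedFixture(seed = 11, nModels = 12L)
  gs <- buildContactGraphs(fx$ensemble)
  univ <- ssePairUniverse(fx$ensemble)
  pm <- estimateContactProbs(gs, q = 0.8)
  fp <- selectFingerprint(pm, stopThreshold = 0, maxPairs = nrow(univ))
  states <- topofold:::signatureMatrix(gs, univ)
  orc <- oracleGreedyFingerprint(states, univ, q = 0.8, stopThreshold = 0)
  expect_equal(fingerprintPairs(fp), univ[orc$idx, , drop = FALSE])
  expect_equal(fp@scores, orc$scores, tolerance = 1e-9)
})

test_that("fold likelihood is the q-agreement product and ranks by Hamming distance", {
  expect_equal(foldLikelihood(rep(1, 5), rep(1, 5), q = 0.8), 0.8^5)
  expect_equal(foldLikelihood(c(1, 0, 1), c(0, 1, 0), q = 0.8), 0.2^3)
  expect_error(foldLikelihood(c(1, 0), c(1, 0, 1)), "length")
  sig <- c(1L, 0L, 1L, 1L, 0L, 0L)
  X <- topofold:::enumerateBits(6)
  lik <- apply(X, 1, foldLikelihood, signature = sig, q = 0.8)
  d <- apply(X, 1, function(x) sum(x != sig))
  expect_equal(order(lik, decreasing = TRUE), order(d, -lik * 0, decreasing = FALSE))
})

test_that("Bayes error: degenerate, hand-enumerated and Monte-Carlo cases", {
  expect_equal(bayesError(rbind(c(1L, 0L), c(1L, 0L), c(1L, 0L)), q = 0.8), 0)
  ## 2 models differing in the single fingerprint pair: error iff the bit flips
  expect_equal(bayesError(rbind(1L, 0L), q = 0.8), 0.2, tolerance = 1e-12)
  ## q -> 1 with distinct signatures drives the error to zero
  sig <- rbind(c(1L, 0L, 1L), c(0L, 1L, 1L), c(0L, 0L, 0L))
  expect_lt(bayesError(sig, q = 0.999), 1e-2)
  expect_equal(bayesError(sig, q = 1), 0)
  ## enumeration vs seeded Monte-Carlo on a 4-model toy
  set.seed(3)
  sig4 <- matrix(rbinom(16, 1, 0.5), 4, 4)
  mc <- oracleEpsMC(sig4, q = 0.8, n = 40000, seed = 1)
  expect_lt(abs(bayesError(sig4, q = 0.8) - mc$est), 3 * mc$se + 1e-9)
})

test_that("tie ratio separates permanent ties, single models and fold classes", {
  ## same restricted signature but different full folds: permanent tie
  expect_equal(tieRatio(rbind(c(1L, 0L), c(1L, 0L)), q = 0.8, folds = c("a", "b")), 1)
  ## same restricted signature, same fold: no tie at all
  expect_equal(tieRatio(rbind(c(1L, 0L), c(1L, 0L)), q = 0.8, folds = c("a", "a")), 0)
  ## a single model never ties
  expect_equal(tieRatio(rbind(c(1L, 0L, 1L)), q = 0.8), 0)
  ## Monte-Carlo agreement with fold classes
  set.seed(8)
  full <- matrix(rbinom(30, 1, 0.5), 6, 5)
  folds <- apply(full, 1, paste, collapse = "")
  sub <- full[, 1:3, drop = FALSE]
  mc <- oracleTauMC(sub, q = 0.8, folds = folds, n = 40000, seed = 2)
  expect_lt(abs(tieRatio(sub, q = 0.8, folds = folds) - mc$est), 3 * mc$se + 1e-9)
})

test_that("error and tie events stay disjoint and bounded", {
  set.seed(13)
  for (rep in 1:12) {
    L <- sample(2:5, 1)
    full <- matrix(rbinom(6 * 6, 1, 0.5), 6, 6)
    folds <- apply(full, 1, paste, collapse = "")
    sig <- full[, seq_len(L), drop = FALSE]
    q <- runif(1, 0.6, 0.95)
    eps <- bayesError(sig, q = q)
    tau <- tieRatio(sig, q = q, folds = folds)
    nu <- notaRatio(sig, q = q)
    expect_gte(eps, 0); expect_gte(tau, 0); expect_gte(nu, 0)
    expect_lte(nu, 1)
    expect_lte(eps + tau, 1 + 1e-12)
  }
})

test_that("none-of-the-above ratio: coverage, enumeration oracle, duplication", {
  ## covered set spans all vectors -> nothing uncovered
  expect_equal(notaRatio(rbind(0L, 1L), q = 0.8), 0)
  ## |F| = 2, single covered fold (0,0): value frozen from the enumeration
  ## oracle — every uncovered dataset is strictly closer to an uncovered fold
  sigCov <- rbind(c(0L, 0L))
  expect_equal(oracleNuExact(sigCov, q = 0.8), 0.75)
  expect_equal(notaRatio(sigCov, q = 0.8), 0.75)
  ## invariant to duplicating a model (covered set is a set, not a multiset)
  sig <- rbind(c(1L, 0L, 1L), c(0L, 1L, 1L))
  expect_equal(notaRatio(sig, q = 0.8), notaRatio(sig[c(1, 1, 2, 2), ], q = 0.8))
  ## Monte-Carlo agreement
  mc <- oracleNuMC(sig, q = 0.8, n = 40000, seed = 4)
  expect_lt(abs(notaRatio(sig, q = 0.8) - mc$est), 3 * mc$se + 1e-9)
})

test_that("fold data interpretation returns ties and none-of-the-above", {
  sig <- rbind(c(1L, 0L, 1L), c(0L, 1L, 1L), c(1L, 1L, 0L))
  d1 <- interpretFoldData(c(1L, 0L, 1L), sig, q = 0.8, modelIds = c("a", "b", "c"))
  expect_equal(d1$bestModels, "a")
  expect_false(d1$noneOfTheAbove)
  ## equidistant between two covered folds -> both returned
  d2 <- interpretFoldData(c(0L, 0L, 1L), sig, q = 0.8, modelIds = c("a", "b", "c"))
  expect_setequal(d2$bestModels, c("a", "b"))
  ## an uncovered dataset is its own best uncovered fold
  d3 <- interpretFoldData(c(0L, 0L, 0L), sig, q = 0.8, modelIds = c("a", "b", "c"))
  expect_true(d3$noneOfTheAbove)
  expect_equal(d3$bestUncovered, c(0L, 0L, 0L))
})

test_that("assessment trajectory reports per-step epsilon/tau/nu", {
  fx <- generateFixture(fixtureSpec(nSses = 4, sseLength = 12, nModels = 12,
                                    topologyVariants = 2, boundaryJitter = 0L,
                                    coordinateNoise = 0, seed = 21))
  gs <- buildContactGraphs(fx$ensemble)
  pm <- estimateContactProbs(gs, q = 0.8)
  fp <- selectFingerprint(pm, stopThreshold = 0)
  traj <- fingerprintTrajectory(fp, gs, q = 0.8)
  expect_equal(nrow(traj), nrow(fingerprintPairs(fp)))
  expect_true(all(traj$epsilon >= 0 & traj$epsilon <= 1))
  expect_true(all(traj$epsilon + traj$tau <= 1 + 1e-12))
  ## on this two-fold fixture the greedy scores are weakly decreasing
  expect_true(all(diff(fp@scores) <= 1e-9))
  fpA <- assessFingerprint(fp, gs, q = 0.8)
  expect_equal(fpA@epsilon, traj$epsilon[nrow(traj)])
  expect_equal(fpA@tieRatio, traj$tau[nrow(traj)])
  expect_equal(fpA@notaRatio, traj$nu[nrow(traj)])
})

test_that("the enumeration cap refuses exponential fingerprints", {
  sig <- matrix(rbinom(2 * 21, 1, 0.5), 2, 21)
  expect_error(bayesError(sig, q = 0.8), "cap")
})
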