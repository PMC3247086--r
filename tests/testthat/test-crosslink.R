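## Stage-2 planner: residue pools, cross-link graphs, noise models,
## noise-marginalized probabilities, mRMR selection, sigmoid interpretation
## and the cross-link Bayes error.

twoHelix <- twoHelixEnsemble(nModels = 6, separation = 8, seed = 1)

test_that("common residues require presence in half of the possessing models", {
  R <- commonResidues(twoHelix, c(1L, 2L))
  expect_equal(R$a, 1:12)
  expect_equal(R$b, 17:28)
  ## jitter the annotation intervals: brute-force per-residue count oracle
  fx <- mixedFixture(seed = 14, nModels = 8L)
  ens <- fx$ensemble
  for (sid in commonSses(ens)$sseId) {
    got <- commonResidues(ens, c(sid, commonSses(ens)$sseId[1]))$a
    iv <- ens@matched[, sid, , drop = FALSE]
    has <- which(!is.na(iv[, 1, 1]))
    pos <- seq(min(iv[has, 1, 1]), max(iv[has, 1, 2]))
    cnt <- sapply(pos, function(p) sum(iv[has, 1, 1] <= p & iv[has, 1, 2] >= p))
    expect_equal(got, pos[2 * cnt >= length(has)])
  }
})

test_that("cross-link graphs hold exactly the <= 19 A residue pairs", {
  m <- ensembleModels(twoHelix)[[1]]
  R <- commonResidues(twoHelix, c(1L, 2L))
  g <- buildXlinkGraph(m, R)
  expect_gt(nrow(g), 0)
  expect_true(all(g$distance <= 19))
  ## brute force over all cross pairs
  for (k in seq_len(nrow(g)))
    expect_equal(g$distance[k], cbDistance(m, g$res_i[k], g$res_j[k]))
  nBrute <- sum(outer(R$a, R$b, Vectorize(function(i, j) cbDistance(m, i, j))) <= 19)
  expect_equal(nrow(g), nBrute)
  ## swapping SSE roles transposes the edge set
  gSwap <- buildXlinkGraph(m, list(a = R$b, b = R$a))
  expect_equal(sort(paste(gSwap$res_j, gSwap$res_i)), sort(paste(g$res_i, g$res_j)))
  ## helices 40 A apart cannot be probed
  far <- blockPairEnsemble(idealSseCoords(8, "H")$cb,
                           idealSseCoords(8, "H", center = c(40, 0))$cb, 1:8, 20:27)
  expect_equal(nrow(buildXlinkGraph(ensembleModels(far)[[1]],
                                    commonResidues(far, c(1L, 2L)))), 0L)
})

test_that("misalignment offsets follow the half-mass-at-zero exponential law", {
  expect_equal(offsetDistribution(0), c("0" = 1.0))
  p <- offsetDistribution(2, decay = 1)
  z <- 2 * exp(-1) + 2 * exp(-2)
  expect_equal(unname(p["0"]), 0.5)
  expect_equal(unname(p["1"]), 0.5 * exp(-1) / z)
  expect_equal(unname(p["-1"]), unname(p["1"]))
  expect_equal(unname(p["2"]), 0.5 * exp(-2) / z)
  for (dm in 0:3) for (dec in c(0.5, 1, 2))
    expect_equal(sum(offsetDistribution(dm, dec)), 1, tolerance = 1e-12)
})

test_that("the elastic-network sampler is anchored at the input structure", {
  m <- ensembleModels(twoHelix)[[1]]
  be <- backboneEnsemble(m)
  expect_equal(be$amplitudes[3], 0)
  expect_equal(be$cbList[[3]], cbCoords(m))          # amplitude 0 = input
  expect_equal(be$probs, rev(be$probs))              # even potential
  expect_equal(which.max(be$probs), 3L)
  expect_equal(sum(be$probs), 1, tolerance = 1e-12)
  ## extreme samples carry ~5% of the central probability by default
  expect_equal(be$probs[1] / be$probs[3], 0.05, tolerance = 1e-9)
  ## a connected C-alpha network has exactly 6 rigid-body modes
  H <- topofold:::anmHessian(caCoords(m), 10)
  vals <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(vals) < max(vals) * 1e-8), 6L)
})

test_that("the internal ANM agrees with an independent normal-mode analysis", {
  m <- ensembleModels(twoHelix)[[1]]
  ca <- caCoords(m)
  dir <- withr_tempdir()
  f <- file.path(dir, "m.pdb")
  bio3d::write.pdb(file = f, xyz = as.numeric(t(ca)), resno = residueIndices(m),
                   resid = rep("ALA", nrow(ca)), elety = rep("CA", nrow(ca)),
                   chain = rep("A", nrow(ca)))
  nm <- suppressWarnings(bio3d::nma(bio3d::read.pdb(f), ff = "anm", cutoff = 10,
                                    mass = FALSE, temp = NULL))
  eg <- eigen(topofold:::anmHessian(ca, 10), symmetric = TRUE)
  idx <- length(eg$values) - 6L
  expect_gt(abs(cor(eg$vectors[, idx], nm$modes[, 7])), 0.999)
  expect_equal(eg$values[idx], nm$L[7], tolerance = 1e-3)
})

test_that("link probabilities follow the distance tiers exactly", {
  m <- structuralModel("t", 1:4,
                       ca = rbind(c(0, 0, 0), c(5, 0, 0), c(12, 0, 0), c(25, 0, 0)),
                       cb = rbind(c(0, 0, 0), c(5, 0, 0), c(12, 0, 0), c(25, 0, 0)))
  expect_identical(linkProb(m, 1, 2), 0.95)
  expect_identical(linkProb(m, 1, 3), 0.5)
  expect_identical(linkProb(m, 1, 4), 0.05)
  ## offset out of the residue range is treated as far
  expect_identical(linkProb(m, 1, 4, deltaJ = 3L), 0.05)
})

test_that("noise marginalization collapses and factorizes correctly", {
  ens <- twoHelix
  none <- noNoiseModel(ens)
  ## degenerate noise reduces to the plain tiered probability for every pair
  m1 <- ensembleModels(ens)[[1]]
  for (cand in list(c(1, 20), c(5, 22), c(12, 17)))
    expect_equal(marginalLinkProb(ens, 1L, cand[1], cand[2], none),
                 linkProb(m1, cand[1], cand[2]))
  ## joint of two links = product of marginals when nothing is shared
  tab <- topofold:::linkProbTable(ensembleModels(ens), 1L,
                                  rbind(c(1L, 20L), c(5L, 22L)), none, linkProbTiers())
  expect_equal(sum(tab$w), 1, tolerance = 1e-9)
  e11 <- sum(tab$w * tab$P[, 1] * tab$P[, 2])
  expect_equal(e11, sum(tab$w * tab$P[, 1]) * sum(tab$w * tab$P[, 2]))
  ## exhaustive (delta, backbone) oracle on a noisy model
  noise <- makeNoiseModel(ens, deltaMax = 1L, nBackbones = 3L)
  for (cand in list(c(3, 21), c(8, 25))) {
    brute <- 0
    for (mi in 1:2) {
      bb <- noise$backbones[[mi]]
      for (b in seq_along(bb$probs)) for (da in -1:1) for (db in -1:1)
        brute <- brute + bb$probs[b] * noise$offsets[as.character(da)] *
          noise$offsets[as.character(db)] *
          linkProb(ensembleModels(ens)[[mi]], cand[1], cand[2], da, db,
                   bb$cbList[[b]]) / 2
    }
    expect_equal(marginalLinkProb(ens, 1:2, cand[1], cand[2], noise),
                 unname(brute), tolerance = 1e-12)
  }
})

test_that("greedy link selection matches the from-scratch oracle on a small toy", {
  ## two short helices: 2 x 4 = 8 candidate pairs
  A <- idealSseCoords(2, "H")
  B <- idealSseCoords(4, "H", center = c(8, 0))
  ens <- blockPairEnsemble(A$cb, B$cb, 1:2, 10:13, nModels = 3L)
  noise <- makeNoiseModel(ens, deltaMax = 1L, nBackbones = 3L)
  states <- rep(1L, 3)
  plan <- selectLinks(ens, c(1L, 2L), states, noise = noise, planSize = 5L,
                      pContact = 0.8)
  R <- commonResidues(ens, c(1L, 2L))
  cand <- topofold:::candidateLinks(ens, R)
  expect_lte(nrow(cand), 8L)
  orc <- oracleGreedyLinks(ens, 1:3, cand, noise, linkProbTiers(), 5L, 0.8)
  expect_equal(unname(planLinks(plan)), unname(orc$links))
  expect_equal(plan@scores, orc$scores, tolerance = 1e-9)
  expect_equal(plan@linkProbs, orc$marg, tolerance = 1e-9)
})

test_that("selection never repeats a residue pair and ranks duplicates last", {
  ## two geometrically identical candidates (mirror-symmetric residues)
  A <- rbind(c(0, 0, 0), c(0, 0, 2))
  B <- rbind(c(8, 0, 1))
  ens <- blockPairEnsemble(A, B, 1:2, 10, nModels = 2L)
  plan <- selectLinks(ens, c(1L, 2L), rep(1L, 2), planSize = 5L, pContact = 0.8)
  expect_equal(nrow(planLinks(plan)), 2L)   # only 2 candidates exist
  expect_false(any(duplicated(paste(planLinks(plan)[, 1], planLinks(plan)[, 2]))))
  ## the duplicate adds strictly less than the first pick
  expect_lt(plan@scores[2], plan@scores[1])
  ## single-candidate plan
  ens1 <- blockPairEnsemble(rbind(c(0, 0, 0)), rbind(c(8, 0, 0)), 1, 10, nModels = 2L)
  plan1 <- selectLinks(ens1, c(1L, 2L), rep(1L, 2), planSize = 10L, pContact = 0.8)
  expect_equal(nrow(planLinks(plan1)), 1L)
  expect_equal(plan1@k0, 0)
})

test_that("the sigmoidal contact likelihood hits its anchors and midpoint", {
  expect_equal(contactLikelihood(0), 0.05, tolerance = 1e-9)
  expect_identical(contactLikelihood(3), 0.5)
  expect_equal(contactLikelihood(6), 0.95, tolerance = 1e-9)
  k <- 0:10
  expect_true(all(diff(contactLikelihood(k)) > 0))   # strictly increasing
  expect_error(contactLikelihood(11), "between 0 and")
})

test_that("cross-link data interpretation compares the two likelihoods", {
  plan <- selectLinks(twoHelix, c(1L, 2L), rep(1L, 6), planSize = 10L)
  expect_equal(interpretXlinkData(rep(1L, 10), plan)$contact, 1L)
  expect_equal(interpretXlinkData(rep(0L, 10), plan)$contact, 0L)
  atK0 <- interpretXlinkData(c(rep(1L, 3), rep(0L, 7)), plan)
  expect_equal(atK0$contact, 0L)            # conservative tie resolution
  expect_true(atK0$tie)
  expect_equal(atK0$lik1, 0.5)
  expect_error(interpretXlinkData(c(1L, 0L), plan), "does not match")
})

test_that("cross-link Bayes error: hand enumeration, growth, Monte-Carlo", {
  ## plan_size = 1, k0 = 0 degenerate: 4-term enumeration by hand.
  ## decision(k=0) resolves to 0 (tie), decision(k=1) = 1, link at 5 A so
  ## p = 0.95: eps = 0.5 (1 - 0.95) + 0.5 * 0.05 = 0.05
  ens1 <- blockPairEnsemble(rbind(c(0, 0, 0)), rbind(c(5, 0, 0)), 1, 10, nModels = 2L)
  plan1 <- selectLinks(ens1, c(1L, 2L), rep(1L, 2), planSize = 1L, pContact = 0.8)
  expect_equal(xlinkBayesError(plan1, ens1, rep(1L, 2)), 0.05, tolerance = 1e-12)

  ## error decreases weakly with plan size on a fixed fixture (fixed decision
  ## midpoint k0 = 3, so the plans are directly comparable)
  noise <- makeNoiseModel(twoHelix)
  states <- rep(1L, nModels(twoHelix))
  eps <- sapply(c(4, 6, 8, 10, 12), function(ps) {
    plan <- selectLinks(twoHelix, c(1L, 2L), states, noise = noise, planSize = ps)
    xlinkBayesError(plan, twoHelix, states, noise)
  })
  expect_true(all(diff(eps) <= 1e-9))

  ## enumeration matches seeded Monte-Carlo simulation of outcomes
  plan8 <- selectLinks(twoHelix, c(1L, 2L), states, noise = noise, planSize = 8L)
  epsEnum <- xlinkBayesError(plan8, twoHelix, states, noise)
  mc <- oracleXlinkEpsMC(plan8, twoHelix, which(states == 1L), noise,
                         linkProbTiers(), n = 20000, seed = 9)
  expect_lt(abs(epsEnum - mc$est), 3 * mc$se + 1e-9)
  ## generative law normalizes
  tab <- topofold:::linkProbTable(ensembleModels(twoHelix), 1:6,
                                  planLinks(plan8), noise, linkProbTiers())
  Y <- topofold:::enumerateBits(8)
  lik1 <- as.numeric(exp(Y %*% t(log(tab$P)) + (1 - Y) %*% t(log1p(-tab$P))) %*% tab$w)
  expect_equal(sum(lik1), 1, tolerance = 1e-9)
})

test_that("plans for a fingerprint are written, read back and survive a round trip", {
  fx <- generateFixture(fixtureSpec(nSses = 4, sseLength = 12, nModels = 8,
                                    topologyVariants = 2, boundaryJitter = 0L,
                                    coordinateNoise = 0, seed = 31))
  gs <- buildContactGraphs(fx$ensemble)
  pm <- estimateContactProbs(gs, q = 0.8)
  fp <- selectFingerprint(pm, maxPairs = 3L)
  plans <- planCrossLinks(fx$ensemble, fp, gs, probModel = pm, planSize = 6L,
                          assess = TRUE)
  expect_gt(length(plans), 0)
  for (p in plans) {
    expect_lte(nrow(planLinks(p)), 6L)
    expect_false(is.na(p@epsilonXlink))
  }
  f <- file.path(withr_tempdir(), "plan.tsv")
  writeCrossLinkPlans(plans, f)
  back <- readCrossLinkPlans(f)
  expect_setequal(names(back), names(plans))
  for (nm in names(plans)) {
    expect_equal(unname(planLinks(back[[nm]])), unname(planLinks(plans[[nm]])))
    expect_equal(back[[nm]]@k0, plans[[nm]]@k0)
    expect_equal(back[[nm]]@epsilonXlink, plans[[nm]]@epsilonXlink, tolerance = 1e-9)
  }
})
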