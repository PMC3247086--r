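## Shared fixture builders (all generated in code at test time).

withr_tempdir <- function() {
  d <- tempfile("tfx")
  dir.create(d)
  d
}

pdbAtomLine <- function(eleno, elety, resid, resno, xyz, chain = "A") {
  sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          eleno, elety, resid, chain, resno, xyz[1], xyz[2], xyz[3],
          substr(elety, 1, 1))
}

## PDB text for a model given residue-level geometry; optionally HELIX records.
writeTinyPdb <- function(path, resno, ca, cb = NULL, resid = "ALA",
                         helixRanges = NULL) {
  lines <- character(0)
  if (!is.null(helixRanges)) {
    for (k in seq_len(nrow(helixRanges))) {
      lines <- c(lines, sprintf(
        "HELIX  %3d %3s ALA A %4d  ALA A %4d  1                               %5d",
        k, paste0("H", k), helixRanges[k, 1], helixRanges[k, 2],
        helixRanges[k, 2] - helixRanges[k, 1] + 1L))
    }
  }
  resid <- rep(resid, length.out = length(resno))
  el <- 0L
  for (i in seq_along(resno)) {
    el <- el + 1L
    lines <- c(lines, pdbAtomLine(el, "CA", resid[i], resno[i], ca[i, ]))
    if (!is.null(cb)) {
      el <- el + 1L
      lines <- c(lines, pdbAtomLine(el, "CB", resid[i], resno[i], cb[i, ]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

## Two-helix geometry written as PDB files with HELIX records.
writeHelixRecordModels <- function(dir, nModels = 2L) {
  dir.create(dir, showWarnings = FALSE)
  paths <- character(nModels)
  for (m in seq_len(nModels)) {
    g1 <- idealSseCoords(12, "H", center = c(0, 0))
    g2 <- idealSseCoords(12, "H", center = c(9, 0), zdir = -1)
    ca <- rbind(g1$ca, g2$ca); cb <- rbind(g1$cb, g2$cb)
    resno <- c(1:12, 20:31)
    paths[m] <- writeTinyPdb(file.path(dir, sprintf("mod%d.pdb", m)), resno, ca, cb,
                             helixRanges = rbind(c(1L, 12L), c(20L, 31L)))
  }
  paths
}

## Seeded self-avoiding random walk (coil-like C-alpha trace).
randomCoilCa <- function(n, seed, step = 3.8, clash = 4.0) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    ca <- matrix(0, n, 3)
    for (i in 2:n) {
      for (try in 1:500) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- ca[i - 1, ] + step * u
        ok <- i <= 2
        if (!ok) {
          prev <- ca[seq_len(i - 2), , drop = FALSE]
          d <- sqrt(rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2))
          ok <- all(d >= clash)
        }
        if (ok) { ca[i, ] <- cand; break }
        if (try == 500) stop("coil generation stuck")
      }
    }
    ca
  })
}

## StructuralModel with cb defaulting to ca (geometry-only tests).
caModel <- function(id, resno, ca, sses = emptySseTable()) {
  structuralModel(id, resno, ca, cb = ca, sses = sses)
}

rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  outer(a, a) * (1 - c) + diag(3) * c +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s
}

rigidTransformModel <- function(model, R, t) {
  structuralModel(modelId(model), residueIndices(model),
                  caCoords(model) %*% t(R) + matrix(t, nResidues(model), 3, byrow = TRUE),
                  cbCoords(model) %*% t(R) + matrix(t, nResidues(model), 3, byrow = TRUE),
                  sses = sseTable(model))
}

## Small ensemble of manually placed SSE pairs: two SSE "blocks" of given
## residue C-beta coordinate matrices, duplicated into nModels identical models.
blockPairEnsemble <- function(coordsA, coordsB, resA, resB, nModels = 2L,
                              kind = c("H", "H")) {
  sses <- data.frame(kind = kind, start = c(min(resA), min(resB)),
                     end = c(max(resA), max(resB)), stringsAsFactors = FALSE)
  models <- lapply(seq_len(nModels), function(i)
    structuralModel(paste0("b", i), c(resA, resB), rbind(coordsA, coordsB),
                    rbind(coordsA, coordsB), sses = sses))
  matchCommonSses(models, targetId = "blocks")
}

pairLabelled <- function(pairs) {
  if (nrow(pairs) == 0) return(character(0))
  paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
}

## The standard mixed fixture for oracle checks: 4 SSEs, 3 variants, jitter+noise.
mixedFixture <- function(seed = 11, nModels = 12L) {
  generateFixture(fixtureSpec(nSses = 4, sseLength = 12, nModels = nModels,
                              topologyVariants = 3, boundaryJitter = 1L,
                              coordinateNoise = 0.5, seed = seed))
}
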