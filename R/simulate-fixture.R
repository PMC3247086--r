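## Synthetic model-ensemble generator: idealized SSE backbones placed on a
## packing lattice, with alternative packing topologies, threading jitter and
## coordinate noise emulating a CASP-like decoy ensemble.

HELIX_RISE <- 1.5      # Angstrom per residue
HELIX_TWIST <- 100     # degrees per residue
HELIX_RADIUS <- 2.3    # Angstrom
STRAND_RISE <- 3.3     # Angstrom per residue

## Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Ideal SSE coordinates (C-alpha and radially placed C-beta)
#'
#' Helices use 1.5 Angstrom rise and 100 degrees twist per residue on a 2.3
#' Angstrom radius; strands are extended traces with 3.3 Angstrom rise.
#' C-betas sit 1.53 Angstrom from their C-alpha, pointing away from the SSE
#' axis (helix) or alternating sides (strand).
#'
#' @param n number of residues.
#' @param kind "H" or "E".
#' @param center c(x, y) position of the SSE axis.
#' @param zdir +1 or -1, direction of the chain along z.
#' @param phase starting twist angle in degrees (helix only).
#' @return list of n x 3 matrices \code{ca} and \code{cb}.
#' @export
idealSseCoords <- function(n, kind = "H", center = c(0, 0), zdir = 1, phase = 0) {
  t <- seq_len(n) - 1L
  ## both chain directions span the same z range so laterally adjacent SSEs pack
  zs <- function(rise) if (zdir >= 0) rise * t else rise * (n - 1L - t)
  if (kind == "H") {
    th <- (phase + HELIX_TWIST * t) * pi / 180
    ca <- cbind(center[1L] + HELIX_RADIUS * cos(th),
                center[2L] + HELIX_RADIUS * sin(th),
                zs(HELIX_RISE))
    cb <- cbind(center[1L] + (HELIX_RADIUS + IDEAL_CB_BOND) * cos(th),
                center[2L] + (HELIX_RADIUS + IDEAL_CB_BOND) * sin(th),
                zs(HELIX_RISE))
  } else {
    ca <- cbind(rep(center[1L], n), rep(center[2L], n), zs(STRAND_RISE))
    cb <- ca + cbind(IDEAL_CB_BOND * (-1)^t, 0, 0)
  }
  list(ca = ca, cb = cb)
}

## All permutations of 1..n in lexicographic order (n <= 8).
permutationsLex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsLex(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

## Adjacency edge set (sorted labels) of a slot permutation on a line.
permAdjacency <- function(perm) {
  e <- pairLabel(perm[-length(perm)], perm[-1L])
  paste(sort(e), collapse = ";")
}

## First `count` slot permutations with pairwise distinct adjacency structures.
topologyPermutations <- function(nSses, count) {
  perms <- permutationsLex(nSses)
  seen <- character(0)
  out <- list()
  for (r in seq_len(nrow(perms))) {
    adj <- permAdjacency(perms[r, ])
    if (adj %in% seen) next
    seen <- c(seen, adj)
    out[[length(out) + 1L]] <- perms[r, ]
    if (length(out) == count) return(out)
  }
  stop("only ", length(out), " distinct packing topologies exist for ", nSses,
       " SSEs on a line; requested ", count)
}

#' Specification for a synthetic model ensemble
#'
#' The defaults emulate a CASP-like decoy set at desk scale: five 12-residue
#' SSEs packed on a 10 Angstrom line lattice, three alternative packing
#' topologies, a one-residue threading register jitter and 0.5 Angstrom
#' smooth (per-residue) coordinate noise.
#'
#' @param nSses number of SSEs (>= 3).
#' @param kinds "H"/"E" per SSE (default all helix).
#' @param sseLength residues per SSE.
#' @param nModels number of models.
#' @param topologyVariants number of distinct packing arrangements (>= 2).
#' @param boundaryJitter maximum per-SSE residue-numbering offset per model.
#' @param coordinateNoise per-residue Gaussian displacement sd in Angstrom.
#' @param seed integer RNG seed; the fixture is deterministic given the seed.
#' @param spacing lattice spacing in Angstrom between adjacent SSE axes.
#' @param truthVariant which variant the ground-truth structure uses.
#' @param excludeTruthVariant when TRUE, no model is generated from the truth
#'   variant (the none-of-the-above scenario).
#' @return a list of class "fixtureSpec".
#' @export
fixtureSpec <- function(nSses = 5L, kinds = NULL, sseLength = 12L, nModels = 30L,
                        topologyVariants = 3L, boundaryJitter = 1L,
                        coordinateNoise = 0.5, seed = 1L, spacing = 10.0,
                        truthVariant = 1L, excludeTruthVariant = FALSE) {
  if (nSses < 3L) stop("nSses must be >= 3")
  if (topologyVariants < 2L) stop("topologyVariants must be >= 2")
  if (sseLength < 5L || nModels < 1L) stop("counts must be positive (sseLength >= 5)")
  if (boundaryJitter < 0L || coordinateNoise < 0) stop("noise terms must be >= 0")
  if (is.null(kinds)) kinds <- rep("H", nSses)
  if (length(kinds) != nSses || !all(kinds %in% c("H", "E")))
    stop("kinds must be H/E of length nSses")
  if (truthVariant < 1L || truthVariant > topologyVariants)
    stop("truthVariant out of range")
  structure(list(nSses = nSses, kinds = kinds, sseLength = sseLength,
                 nModels = nModels, topologyVariants = topologyVariants,
                 boundaryJitter = boundaryJitter, coordinateNoise = coordinateNoise,
                 seed = seed, spacing = spacing, truthVariant = truthVariant,
                 excludeTruthVariant = excludeTruthVariant),
            class = "fixtureSpec")
}

## Build one model's geometry for a given variant permutation.
## offsets: per-SSE residue-numbering shifts (threading jitter).
buildVariantModel <- function(spec, perm, modelIdx, offsets = NULL, noiseSd = 0) {
  nS <- spec$nSses
  len <- spec$sseLength
  gap <- 2L * spec$boundaryJitter + 3L
  if (is.null(offsets)) offsets <- rep(0L, nS)
  resno <- integer(0); ca <- NULL; cb <- NULL
  sses <- emptySseTable()
  slotOf <- match(seq_len(nS), perm)   # slot holding SSE k
  for (k in seq_len(nS)) {
    slot <- slotOf[k]
    geo <- idealSseCoords(len, spec$kinds[k], center = c((slot - 1L) * spec$spacing, 0),
                          zdir = if (slot %% 2L == 1L) 1 else -1)
    start <- (k - 1L) * (len + gap) + 1L + spec$boundaryJitter + offsets[k]
    rr <- seq.int(start, start + len - 1L)
    resno <- c(resno, rr)
    ca <- rbind(ca, geo$ca); cb <- rbind(cb, geo$cb)
    sses <- rbind(sses, data.frame(kind = spec$kinds[k], start = start,
                                   end = start + len - 1L, stringsAsFactors = FALSE))
  }
  if (noiseSd > 0) {
    shift <- matrix(rnorm(length(resno) * 3L, sd = noiseSd), ncol = 3L)
    ca <- ca + shift; cb <- cb + shift   # shared per-residue displacement: smooth
  }
  structuralModel(sprintf("model_%03d", modelIdx), resno, ca, cb, sses = sses)
}

writeFixturePdb <- function(model, dir) {
  n <- nResidues(model)
  xyz <- as.numeric(t(do.call(rbind, lapply(seq_len(n), function(i)
    rbind(model@ca[i, ], model@cb[i, ])))))
  file <- file.path(dir, paste0(model@modelId, ".pdb"))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = rep(model@resno, each = 2L),
                   resid = rep("ALA", 2L * n),
                   elety = rep(c("CA", "CB"), n),
                   chain = rep("A", 2L * n))
  file
}

#' Generate a synthetic model ensemble and its ground-truth structure
#'
#' Builds idealized SSE backbones placed on a line lattice; each topology
#' variant is a slot permutation with a distinct adjacency structure, so
#' different variants differ in which SSE pairs are spatially adjacent (hence
#' in contact). Models are assigned to variants round-robin, given per-SSE
#' threading register offsets up to \code{boundaryJitter} and smooth Gaussian
#' coordinate noise; the ground truth is the noise-free structure of
#' \code{truthVariant}. Every generated model is written to PDB (with a
#' sidecar SSE annotation file) and read back through [readModels()], so the
#' fixture exercises the full input path.
#'
#' @param spec a [fixtureSpec()].
#' @param dir directory for the PDB files (default: a fresh temp directory).
#' @return list with \code{ensemble} (\linkS4class{ModelEnsemble}),
#'   \code{truth} (\linkS4class{StructuralModel}), \code{modelVariants}
#'   (integer per model), \code{perms}, and \code{dir}.
#' @export
generateFixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  perms <- topologyPermutations(spec$nSses, spec$topologyVariants)
  pool <- seq_len(spec$topologyVariants)
  if (spec$excludeTruthVariant) pool <- setdiff(pool, spec$truthVariant)
  if (length(pool) == 0L) stop("no variants left for the models")
  withSeed(spec$seed, {
    models <- vector("list", spec$nModels)
    variants <- integer(spec$nModels)
    annLines <- character(0)
    for (i in seq_len(spec$nModels)) {
      v <- pool[(i - 1L) %% length(pool) + 1L]
      variants[i] <- v
      offsets <- if (spec$boundaryJitter > 0)
        sample(seq.int(-spec$boundaryJitter, spec$boundaryJitter), spec$nSses,
               replace = TRUE) else rep(0L, spec$nSses)
      m <- buildVariantModel(spec, perms[[v]], i, offsets, spec$coordinateNoise)
      models[[i]] <- m
      writeFixturePdb(m, dir)
      annLines <- c(annLines, sprintf("%s\t%s\t%d\t%d", m@modelId,
                                      m@sses$kind, m@sses$start, m@sses$end))
    }
    annFile <- file.path(dir, "sses.txt")
    writeLines(annLines, annFile)
    truth <- buildVariantModel(spec, perms[[spec$truthVariant]], 0L)
    truth@modelId <- "truth"
    ensemble <- readModels(file.path(dir, paste0(sprintf("model_%03d",
                                                         seq_len(spec$nModels)), ".pdb")),
                           annotations = annFile, targetId = "fixture")
    list(ensemble = ensemble, truth = truth, modelVariants = variants,
         perms = perms, dir = dir)
  })
}

#' Two-helix fixture ensemble
#'
#' A minimal ensemble of models each containing two parallel ideal helices a
#' fixed axis distance apart, with optional per-residue Gaussian noise — the
#' standard fixture for exercising cross-link planning on an SSE pair that is
#' in contact (or not) in every model.
#'
#' @param nModels number of models (default 10).
#' @param separation helix axis distance in Angstrom (default 8).
#' @param sseLength residues per helix (default 12).
#' @param noise per-residue Gaussian displacement sd (default 0.3).
#' @param seed RNG seed.
#' @return a \linkS4class{ModelEnsemble} with two common helices.
#' @export
twoHelixEnsemble <- function(nModels = 10L, separation = 8.0, sseLength = 12L,
                             noise = 0.3, seed = 1L) {
  len <- sseLength
  sses <- data.frame(kind = "H", start = c(1L, len + 5L),
                     end = c(len, 2L * len + 4L), stringsAsFactors = FALSE)
  resno <- c(seq_len(len), seq.int(len + 5L, 2L * len + 4L))
  withSeed(seed, {
    models <- lapply(seq_len(nModels), function(i) {
      g1 <- idealSseCoords(len, "H", center = c(0, 0), zdir = 1)
      g2 <- idealSseCoords(len, "H", center = c(separation, 0), zdir = -1)
      ca <- rbind(g1$ca, g2$ca); cb <- rbind(g1$cb, g2$cb)
      if (noise > 0) {
        shift <- matrix(rnorm(length(resno) * 3L, sd = noise), ncol = 3L)
        ca <- ca + shift; cb <- cb + shift
      }
      structuralModel(sprintf("m%02d", i), resno, ca, cb, sses = sses)
    })
    matchCommonSses(models, targetId = "two_helix")
  })
}
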