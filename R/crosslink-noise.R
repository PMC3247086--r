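## Noise models for cross-link planning: threading-misalignment offsets and
## backbone flexibility sampled along the lowest elastic-network normal mode.

#' Threading-misalignment offset distribution
#'
#' A model's SSE may be registered off by delta residues relative to the true
#' protein, so a cross-link at residue r + delta really probes residue r. The
#' distribution puts probability 0.5 at zero offset and decays exponentially on
#' both sides up to \code{deltaMax}, the +-delta mass normalized to total 0.5;
#' it is symmetric in +-delta.
#'
#' @param deltaMax maximum absolute offset (default 2); 0 gives the degenerate
#'   distribution Pr(0) = 1.
#' @param decay exponential decay rate per residue (default 1).
#' @return named numeric vector Pr(delta) for delta in -deltaMax..deltaMax.
#' @export
offsetDistribution <- function(deltaMax = 2L, decay = 1.0) {
  if (deltaMax < 0L) stop("deltaMax must be >= 0")
  if (decay <= 0) stop("decay must be > 0")
  if (deltaMax == 0L) return(c("0" = 1.0))
  d <- seq.int(-deltaMax, deltaMax)
  w <- exp(-decay * abs(d))
  p <- numeric(length(d))
  side <- d != 0L
  p[!side] <- 0.5
  p[side] <- 0.5 * w[side] / sum(w[side])
  names(p) <- as.character(d)
  p
}

## Anisotropic elastic-network Hessian on C-alpha coordinates: unit springs
## between residues within the cutoff, 3x3 projection blocks along the
## inter-residue direction.
anmHessian <- function(ca, cutoff = 10) {
  n <- nrow(ca)
  H <- matrix(0, 3L * n, 3L * n)
  d <- distMatrix(ca, ca)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (d[i, j] > cutoff || d[i, j] < 1e-6) next
      r <- ca[j, ] - ca[i, ]
      blk <- -outer(r, r) / sum(r * r)
      ii <- (3L * i - 2L):(3L * i); jj <- (3L * j - 2L):(3L * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  H
}

#' Sample alternative backbones along the lowest elastic normal mode
#'
#' Builds an anisotropic network model on the C-alpha trace (unit springs
#' within \code{enmCutoff}), takes the lowest non-trivial eigenmode after the
#' six rigid-body modes, and generates \code{nSamples} coordinate sets at
#' amplitudes evenly spaced in [-amplitudeMax, +amplitudeMax] (the mode shape
#' is scaled so the largest per-residue displacement at amplitude a is a
#' Angstrom). Each alternative gets probability proportional to
#' exp(-lambda a^2 / (2 kT)) from the Hookean mode potential; by default kT is
#' set so the extreme sample has about 5% of the central sample's probability.
#' C-beta positions follow their residue's displacement.
#'
#' A network without exactly six near-zero modes (tiny or disconnected chain)
#' falls back to the unperturbed structure with probability 1, with a warning.
#'
#' @param model a \linkS4class{StructuralModel} (>= 4 residues).
#' @param nSamples number of amplitude samples (default 5; use an odd number
#'   so the unperturbed structure is included).
#' @param amplitudeMax maximum C-alpha displacement in Angstrom (default 3).
#' @param enmCutoff spring cutoff in Angstrom (default 10).
#' @param kT energy scale of the Hookean weighting (default: see above).
#' @return list with \code{cbList}, \code{caList} (one matrix per sample),
#'   \code{probs}, \code{amplitudes}, \code{lambda}.
#' @export
backboneEnsemble <- function(model, nSamples = 5L, amplitudeMax = 3.0,
                             enmCutoff = 10.0, kT = NULL) {
  fallback <- function(msg) {
    warning("backboneEnsemble(", model@modelId, "): ", msg,
            "; using the unperturbed structure only")
    list(cbList = list(model@cb), caList = list(model@ca), probs = 1,
         amplitudes = 0, lambda = NA_real_)
  }
  n <- nResidues(model)
  if (n < 4L) return(fallback("fewer than 4 residues"))
  if (nSamples <= 1L)
    return(list(cbList = list(model@cb), caList = list(model@ca), probs = 1,
                amplitudes = 0, lambda = NA_real_))
  H <- anmHessian(model@ca, enmCutoff)
  eg <- eigen(H, symmetric = TRUE)
  vals <- eg$values                      # decreasing
  tol <- max(vals) * 1e-8
  nZero <- sum(abs(vals) < tol)
  if (nZero != 6L || length(vals) < 7L)
    return(fallback(paste0("expected 6 rigid-body modes, found ", nZero)))
  idx <- length(vals) - 6L               # 7th-smallest eigenvalue
  lambda <- vals[idx]
  V <- matrix(eg$vectors[, idx], ncol = 3L, byrow = TRUE)
  V <- V / max(sqrt(rowSums(V^2)))       # unit maximum C-alpha displacement
  amps <- seq(-amplitudeMax, amplitudeMax, length.out = nSamples)
  if (is.null(kT)) kT <- lambda * amplitudeMax^2 / (2 * log(20))
  probs <- exp(-lambda * amps^2 / (2 * kT))
  probs <- probs / sum(probs)
  list(cbList = lapply(amps, function(a) model@cb + a * V),
       caList = lapply(amps, function(a) model@ca + a * V),
       probs = probs, amplitudes = amps, lambda = lambda)
}

#' Combined noise model for an ensemble
#'
#' Bundles the misalignment offset distribution (one independent offset per
#' SSE of a probed pair) with the per-model backbone flexibility ensembles.
#' Misalignment and flexibility are treated as independent.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param deltaMax,decay see [offsetDistribution()].
#' @param nBackbones,amplitudeMax,enmCutoff,kT see [backboneEnsemble()].
#' @return list with \code{offsets} and \code{backbones} (one ensemble per model).
#' @export
makeNoiseModel <- function(ensemble, deltaMax = 2L, decay = 1.0, nBackbones = 5L,
                           amplitudeMax = 3.0, enmCutoff = 10.0, kT = NULL) {
  list(offsets = offsetDistribution(deltaMax, decay),
       backbones = lapply(ensemble@models, backboneEnsemble, nSamples = nBackbones,
                          amplitudeMax = amplitudeMax, enmCutoff = enmCutoff, kT = kT))
}

#' Noise-free noise model (no misalignment, single backbone)
#'
#' @inheritParams makeNoiseModel
#' @export
noNoiseModel <- function(ensemble) {
  list(offsets = offsetDistribution(0L),
       backbones = lapply(ensemble@models, function(m)
         list(cbList = list(m@cb), caList = list(m@ca), probs = 1,
              amplitudes = 0, lambda = NA_real_)))
}

#' Tiered prior probability of disulfide formation by C-beta distance
#'
#' @param pNear probability for d <= dNear (default 0.95).
#' @param pMid probability for dNear < d <= dFar (default 0.5).
#' @param pFar probability for d > dFar (default 0.05).
#' @param dNear,dFar tier boundaries in Angstrom (defaults 9 and 19).
#' @return a list of class "linkProbTiers".
#' @export
linkProbTiers <- function(pNear = 0.95, pMid = 0.5, pFar = 0.05,
                          dNear = 9.0, dFar = 19.0) {
  if (!(pNear > pMid && pMid > pFar && pNear <= 1 && pFar >= 0))
    stop("tiers must satisfy 1 >= pNear > pMid > pFar >= 0")
  structure(list(pNear = pNear, pMid = pMid, pFar = pFar, dNear = dNear, dFar = dFar),
            class = "linkProbTiers")
}

## Vectorized tier lookup; NA distances (offset out of range) get pFar.
tierProb <- function(d, tiers) {
  out <- rep(tiers$pFar, length(d))
  ok <- !is.na(d)
  out[ok & d <= tiers$dNear] <- tiers$pNear
  out[ok & d > tiers$dNear & d <= tiers$dFar] <- tiers$pMid
  out
}

#' Cross-link probability for one residue pair under given offsets and backbone
#'
#' Applies the distance tiers to the C-beta distance between the offset-shifted
#' residues in the chosen backbone; a shifted residue absent from the model is
#' treated as far (tier pFar).
#'
#' @param model a \linkS4class{StructuralModel}.
#' @param i,j residue indices (one per SSE of the probed pair).
#' @param deltaI,deltaJ per-SSE misalignment offsets (rigid shift of each SSE).
#' @param cb optional perturbed C-beta coordinate matrix (default: the model's).
#' @param tiers a [linkProbTiers()] object.
#' @return probability of observing the cross-link.
#' @export
linkProb <- function(model, i, j, deltaI = 0L, deltaJ = 0L, cb = NULL,
                     tiers = linkProbTiers()) {
  if (is.null(cb)) cb <- model@cb
  pi_ <- match(i + deltaI, model@resno)
  pj <- match(j + deltaJ, model@resno)
  if (is.na(pi_) || is.na(pj)) return(tiers$pFar)
  tierProb(vnorm(cb[pi_, ] - cb[pj, ]), tiers)
}
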