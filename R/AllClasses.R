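## S4 classes for the central data objects.

#' StructuralModel: one candidate 3-D model of the target protein
#'
#' Holds the per-residue backbone geometry actually consumed by the planner:
#' residue indices (1-based target sequence numbering), one-letter amino-acid
#' codes, C-alpha coordinates, and C-beta coordinates (a virtual C-beta built
#' from ideal tetrahedral N/CA/C geometry for glycine or when the atom is
#' absent), plus the model's secondary-structure annotations.
#'
#' @slot modelId single string identifying the model.
#' @slot resno integer vector of residue indices, strictly increasing, >= 1.
#' @slot aa character vector of one-letter amino-acid codes.
#' @slot ca numeric n x 3 matrix of C-alpha coordinates (Angstrom).
#' @slot cb numeric n x 3 matrix of C-beta coordinates (Angstrom).
#' @slot sses data.frame with columns \code{kind} ("H" or "E"), \code{start},
#'   \code{end} (residue indices, inclusive).
#' @export
setClass("StructuralModel",
  representation(modelId = "character", resno = "integer", aa = "character",
                 ca = "matrix", cb = "matrix", sses = "data.frame"))

setValidity("StructuralModel", function(object) {
  n <- length(object@resno)
  msg <- character(0)
  if (length(object@modelId) != 1L) msg <- c(msg, "modelId must be a single string")
  if (n > 0 && any(diff(object@resno) <= 0)) msg <- c(msg, "residue indices must be strictly increasing")
  if (n > 0 && object@resno[1L] < 1L) msg <- c(msg, "residue indices must be >= 1")
  if (length(object@aa) != n) msg <- c(msg, "aa length must match resno")
  if (!all(dim(object@ca) == c(n, 3L))) msg <- c(msg, "ca must be n x 3")
  if (!all(dim(object@cb) == c(n, 3L))) msg <- c(msg, "cb must be n x 3")
  if (n > 0 && (!all(is.finite(object@ca)) || !all(is.finite(object@cb))))
    msg <- c(msg, "coordinates must be finite")
  if (n > 0) {
    dcb <- sqrt(rowSums((object@cb - object@ca)^2))
    if (any(dcb >= 2.5)) msg <- c(msg, "|cb - ca| must be < 2.5 Angstrom for every residue")
  }
  s <- object@sses
  if (nrow(s) > 0) {
    if (!all(c("kind", "start", "end") %in% names(s))) msg <- c(msg, "sses needs kind/start/end columns")
    else {
      if (!all(s$kind %in% c("H", "E"))) msg <- c(msg, "sse kind must be 'H' or 'E'")
      if (any(s$start > s$end)) msg <- c(msg, "sse start must be <= end")
      if (n > 0 && (any(s$start < min(object@resno)) || any(s$end > max(object@resno))))
        msg <- c(msg, "sse intervals must lie within the residue range")
      if (nrow(s) > 1) {
        o <- order(s$start)
        if (any(s$start[o][-1L] <= s$end[o][-nrow(s)]))
          msg <- c(msg, "sse intervals of one model must not overlap")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ModelEnsemble: aligned candidate models with their common SSE complement
#'
#' @slot targetId single string naming the target.
#' @slot models list of \linkS4class{StructuralModel}.
#' @slot commonSses data.frame (sseId, kind, start, end) of consensus intervals,
#'   numbered in sequence order of consensus start.
#' @slot matched integer array n_models x n_sses x 2 giving each model's own
#'   matched interval for each common SSE (NA where the model lacks it).
#' @slot presenceFraction fraction of models an SSE cluster must appear in.
#' @slot overlapFraction minimum interval Jaccard used when clustering SSEs.
#' @export
setClass("ModelEnsemble",
  representation(targetId = "character", models = "list", commonSses = "data.frame",
                 matched = "array", presenceFraction = "numeric",
                 overlapFraction = "numeric"))

setValidity("ModelEnsemble", function(object) {
  msg <- character(0)
  if (!all(vapply(object@models, is, logical(1), "StructuralModel")))
    msg <- c(msg, "models must all be StructuralModel")
  cs <- object@commonSses
  if (nrow(cs) == 0) msg <- c(msg, "no common SSEs: ensemble is unusable")
  if (nrow(cs) > 0 && !identical(cs$sseId, seq_len(nrow(cs))))
    msg <- c(msg, "common SSE ids must be 1..n in consensus start order")
  if (nrow(cs) > 1 && any(diff(cs$start) < 0)) msg <- c(msg, "common SSEs must be ordered by consensus start")
  if (!all(dim(object@matched) == c(length(object@models), nrow(cs), 2L)))
    msg <- c(msg, "matched must be n_models x n_sses x 2")
  if (object@presenceFraction < 0 || object@presenceFraction > 1)
    msg <- c(msg, "presenceFraction must be in [0,1]")
  if (nrow(cs) > 0 && length(object@models) > 0) {
    present <- colMeans(!is.na(object@matched[, , 1L, drop = FALSE]))
    if (any(present < object@presenceFraction - 1e-9))
      msg <- c(msg, "every common SSE must appear in >= presenceFraction of models")
  }
  if (length(msg)) msg else TRUE
})

#' SSEContactGraph: binary SSE-pair contact states of one model
#'
#' @slot modelId model the graph belongs to.
#' @slot sseIds the common SSE id set the contacts are defined over.
#' @slot contacts integer k x 2 matrix of unordered contacting SSE pairs (a < b).
#' @export
setClass("SSEContactGraph",
  representation(modelId = "character", sseIds = "integer", contacts = "matrix"))

setValidity("SSEContactGraph", function(object) {
  msg <- character(0)
  ct <- object@contacts
  if (ncol(ct) != 2L) msg <- c(msg, "contacts must have two columns")
  if (nrow(ct) > 0) {
    if (!all(ct %in% object@sseIds)) msg <- c(msg, "contacts may only reference common SSE ids")
    if (any(ct[, 1L] >= ct[, 2L])) msg <- c(msg, "contacts must be stored as a < b (no self pairs)")
    if (anyDuplicated(paste(ct[, 1L], ct[, 2L]))) msg <- c(msg, "duplicate contact pairs")
  }
  if (length(msg)) msg else TRUE
})

#' ContactProbModel: q-smoothed contact probabilities over the ensemble
#'
#' Marginal and joint contact probabilities for every SSE pair of the planning
#' universe, estimated from the models' contact graphs with agreement weight q:
#' a graph whose state agrees with the evaluated value contributes q, a
#' disagreeing one 1-q, so unanimity yields Pr = q rather than 1.
#'
#' @slot q agreement weight in (0.5, 1].
#' @slot pairs integer P x 2 matrix of SSE pairs (universe, a < b, lexicographic).
#' @slot states integer M x P matrix of raw per-model contact states (0/1).
#' @slot marginals numeric P x 2 matrix, columns Pr(c=0), Pr(c=1).
#' @export
setClass("ContactProbModel",
  representation(q = "numeric", pairs = "matrix", states = "matrix",
                 marginals = "matrix"))

setValidity("ContactProbModel", function(object) {
  msg <- character(0)
  if (object@q <= 0.5 || object@q > 1)
    msg <- c(msg, "q must be in (0.5, 1]: at q <= 0.5 relevance/redundancy degenerate")
  P <- nrow(object@pairs)
  if (ncol(object@pairs) != 2L) msg <- c(msg, "pairs must have two columns")
  if (ncol(object@states) != P) msg <- c(msg, "states must have one column per pair")
  if (!all(object@states %in% c(0L, 1L))) msg <- c(msg, "states must be 0/1")
  if (!all(dim(object@marginals) == c(P, 2L))) msg <- c(msg, "marginals must be P x 2")
  if (P > 0 && any(abs(rowSums(object@marginals) - 1) > 1e-9))
    msg <- c(msg, "each marginal must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Fingerprint: an ordered topological fingerprint with its plan assessment
#'
#' @slot pairs integer k x 2 matrix of selected SSE pairs, in greedy order.
#' @slot scores per-step incremental mRMR objective values (bits).
#' @slot epsilon Bayes error of the fingerprint (NA until assessed).
#' @slot tieRatio expected tie ratio (NA until assessed).
#' @slot notaRatio expected none-of-the-above ratio (NA until assessed).
#' @export
setClass("Fingerprint",
  representation(pairs = "matrix", scores = "numeric", epsilon = "numeric",
                 tieRatio = "numeric", notaRatio = "numeric"))

setValidity("Fingerprint", function(object) {
  msg <- character(0)
  if (ncol(object@pairs) != 2L) msg <- c(msg, "pairs must have two columns")
  if (nrow(object@pairs) != length(object@scores)) msg <- c(msg, "one score per selected pair")
  if (anyDuplicated(paste(object@pairs[, 1L], object@pairs[, 2L]))) msg <- c(msg, "pairs must be distinct")
  for (nm in c("epsilon", "tieRatio", "notaRatio")) {
    v <- slot(object, nm)
    if (length(v) != 1L) msg <- c(msg, paste(nm, "must be a single value"))
    else if (!is.na(v) && (v < -1e-12 || v > 1 + 1e-12)) msg <- c(msg, paste(nm, "must be in [0,1]"))
  }
  if (length(msg)) msg else TRUE
})

#' CrossLinkPlan: planned disulfide probes for one fingerprint SSE pair
#'
#' @slot ssePair the SSE id pair being probed.
#' @slot links integer n x 2 matrix of residue pairs, in greedy selection order.
#' @slot scores per-step incremental mRMR objective values (bits).
#' @slot linkProbs noise-marginalized link probability of each selected pair
#'   under the in-contact class.
#' @slot k0 decision midpoint of the sigmoidal interpretation.
#' @slot planSize requested number of experiments.
#' @slot epsilonXlink Bayes error of the plan for the contact decision (NA until assessed).
#' @export
setClass("CrossLinkPlan",
  representation(ssePair = "integer", links = "matrix", scores = "numeric",
                 linkProbs = "numeric", k0 = "numeric", planSize = "numeric",
                 epsilonXlink = "numeric"))

setValidity("CrossLinkPlan", function(object) {
  msg <- character(0)
  if (length(object@ssePair) != 2L) msg <- c(msg, "ssePair must be two SSE ids")
  if (ncol(object@links) != 2L) msg <- c(msg, "links must have two columns")
  if (anyDuplicated(paste(object@links[, 1L], object@links[, 2L]))) msg <- c(msg, "links must be distinct")
  if (nrow(object@links) != length(object@scores)) msg <- c(msg, "one score per link")
  if (nrow(object@links) != length(object@linkProbs)) msg <- c(msg, "one linkProb per link")
  if (object@k0 >= object@planSize) msg <- c(msg, "k0 must be < planSize")
  e <- object@epsilonXlink
  if (!is.na(e) && (e < -1e-12 || e > 1 + 1e-12)) msg <- c(msg, "epsilonXlink must be in [0,1]")
  if (length(msg)) msg else TRUE
})
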