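## Per-model SSE contact graphs and fold-level comparison.

#' Build the SSE contact graph of one model
#'
#' An SSE pair (a, b) is deemed in contact when (i) at least \code{minContacts}
#' residue pairs (one residue in each SSE) lie closer than
#' \code{contactDistance} (C-beta-C-beta, strict inequality), and (ii) at least
#' a fraction \code{minResidueFraction} of each SSE's residues has at least one
#' contact partner in the other SSE (both SSEs must satisfy the fraction).
#' Residues of an SSE are those of the model's matched annotation interval; a
#' model lacking a matched annotation for a common SSE uses the consensus
#' interval so the contact universe stays identical across models.
#'
#' @param modelIndex index of the model within the ensemble.
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param minContacts minimum number of close residue pairs (default 5).
#' @param minResidueFraction minimum per-SSE contact-partner fraction (default 0.20).
#' @param contactDistance C-beta-C-beta cutoff in Angstrom (default 9.0).
#' @return an \linkS4class{SSEContactGraph}.
#' @export
buildContactGraph <- function(modelIndex, ensemble, minContacts = 5L,
                              minResidueFraction = 0.20, contactDistance = 9.0) {
  model <- ensemble@models[[modelIndex]]
  ids <- ensemble@commonSses$sseId
  ## C-beta coordinates per SSE (residues present in the model within the interval)
  sseCb <- lapply(ids, function(sid) {
    iv <- sseInterval(ensemble, modelIndex, sid)
    sel <- model@resno >= iv[1L] & model@resno <= iv[2L]
    model@cb[sel, , drop = FALSE]
  })
  univ <- ssePairUniverse(ensemble)
  inContact <- logical(nrow(univ))
  for (k in seq_len(nrow(univ))) {
    a <- univ[k, 1L]; b <- univ[k, 2L]
    ca_ <- sseCb[[a]]; cb_ <- sseCb[[b]]
    if (nrow(ca_) == 0L || nrow(cb_) == 0L) next
    d <- distMatrix(ca_, cb_)
    close <- d < contactDistance
    if (sum(close) < minContacts) next
    fracA <- mean(rowSums(close) > 0L)
    fracB <- mean(colSums(close) > 0L)
    inContact[k] <- fracA >= minResidueFraction && fracB >= minResidueFraction
  }
  new("SSEContactGraph", modelId = model@modelId, sseIds = as.integer(ids),
      contacts = univ[inContact, , drop = FALSE])
}

#' Contact graphs for every model of an ensemble
#'
#' @inheritParams buildContactGraph
#' @return list of \linkS4class{SSEContactGraph}, one per model.
#' @export
buildContactGraphs <- function(ensemble, minContacts = 5L, minResidueFraction = 0.20,
                               contactDistance = 9.0) {
  lapply(seq_along(ensemble@models), buildContactGraph, ensemble = ensemble,
         minContacts = minContacts, minResidueFraction = minResidueFraction,
         contactDistance = contactDistance)
}

#' Binary fold signature of a contact graph over given SSE pairs
#'
#' @param graph an \linkS4class{SSEContactGraph}.
#' @param pairs integer k x 2 matrix of SSE pairs.
#' @return integer 0/1 vector, one state per pair (1 = contact).
#' @export
foldSignature <- function(graph, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) return(integer(0))
  have <- pairLabel(graph@contacts[, 1L], graph@contacts[, 2L])
  as.integer(pairLabel(pairs[, 1L], pairs[, 2L]) %in% have)
}

## Signature matrix (models x pairs) from a list of contact graphs.
signatureMatrix <- function(graphs, pairs) {
  m <- t(vapply(graphs, foldSignature, integer(nrow(matrix(pairs, ncol = 2L))),
                pairs = pairs))
  matrix(m, nrow = length(graphs))
}

#' Compare the folds of two models at a contact-fraction threshold
#'
#' Two models have equal folds when their full-universe fold signatures —
#' contact graphs recomputed with \code{minResidueFraction = r} — are
#' identical. The threshold r is the per-SSE fraction of residues required to
#' be in contact; raising it removes weak contacts (and at high r no pair is in
#' contact in either model, making all folds trivially equal).
#'
#' @param i,j model indices within the ensemble.
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param r contact fraction threshold in [0,1].
#' @param minContacts,contactDistance as in [buildContactGraph()].
#' @return TRUE when the two models have identical SSE contact states.
#' @export
foldEqual <- function(i, j, ensemble, r = 0.2, minContacts = 5L, contactDistance = 9.0) {
  univ <- ssePairUniverse(ensemble)
  gi <- buildContactGraph(i, ensemble, minContacts, r, contactDistance)
  gj <- buildContactGraph(j, ensemble, minContacts, r, contactDistance)
  identical(foldSignature(gi, univ), foldSignature(gj, univ))
}

#' Export contact graphs as a tab-separated edge list
#'
#' @param graphs list of \linkS4class{SSEContactGraph}.
#' @param file output path.
#' @export
writeContactEdges <- function(graphs, file) {
  rows <- do.call(rbind, lapply(graphs, function(g) {
    if (nrow(g@contacts) == 0L) return(NULL)
    data.frame(model_id = g@modelId, sse_a = g@contacts[, 1L], sse_b = g@contacts[, 2L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(model_id = character(0), sse_a = integer(0),
                                        sse_b = integer(0))
  write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Model-by-pair binary contact matrix
#'
#' @param graphs list of \linkS4class{SSEContactGraph}.
#' @param pairs SSE pairs to report (default: all pairs over the graphs' SSE set).
#' @return 0/1 matrix, rows named by model id, columns by "a-b" pair labels.
#' @export
contactStateMatrix <- function(graphs, pairs = NULL) {
  if (is.null(pairs)) pairs <- t(combn(graphs[[1L]]@sseIds, 2L))
  m <- signatureMatrix(graphs, pairs)
  dimnames(m) <- list(vapply(graphs, modelId, character(1)),
                      pairLabel(pairs[, 1L], pairs[, 2L]))
  m
}
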