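## Geometric secondary-structure assignment and cross-model SSE matching.

## C-alpha i..i+k distance bands (Angstrom) for ideal secondary structure,
## P-SEA-style. An alpha-helix has ~1.5 A rise and ~100 deg twist per residue
## (d(i,i+2) ~ 5.4, d(i,i+3) ~ 5.1, d(i,i+4) ~ 6.2); an extended strand has
## ~3.3 A rise (d(i,i+2) ~ 6.6, d(i,i+3) ~ 9.9).
HELIX_D2 <- c(4.7, 6.1)
HELIX_D3 <- c(4.2, 5.8)
HELIX_D4 <- c(5.2, 7.2)
STRAND_D2 <- c(6.1, 7.2)
STRAND_D3 <- c(8.9, 10.9)

#' Assign helix/strand segments from C-alpha geometry
#'
#' Deterministic distance-criteria assigner in the spirit of P-SEA: a chain
#' position qualifies as helix-like or strand-like when its C-alpha
#' i..i+2/i+3/i+4 distances fall in ideal-geometry bands; runs of at least two
#' consecutive qualifying positions (within contiguous residue numbering)
#' become segments spanning the full distance windows. Helix segments shorter
#' than 4 residues and strand segments shorter than 3 are discarded.
#'
#' @param model a \linkS4class{StructuralModel} with C-alpha coordinates.
#' @return data.frame (kind, start, end); possibly empty.
#' @export
assignSses <- function(model) {
  ca <- model@ca
  resno <- model@resno
  n <- length(resno)
  if (n < 5L) return(emptySseTable())
  dk <- function(k) {
    d <- rep(NA_real_, n)
    idx <- seq_len(n - k)
    ok <- resno[idx + k] - resno[idx] == k   # windows must be contiguous in numbering
    d[idx[ok]] <- sqrt(rowSums((ca[idx[ok] + k, , drop = FALSE] -
                                ca[idx[ok], , drop = FALSE])^2))
    d
  }
  d2 <- dk(2L); d3 <- dk(3L); d4 <- dk(4L)
  inband <- function(d, b) !is.na(d) & d >= b[1L] & d <= b[2L]
  helixAt <- inband(d2, HELIX_D2) & inband(d3, HELIX_D3) & inband(d4, HELIX_D4)
  strandAt <- inband(d2, STRAND_D2) & inband(d3, STRAND_D3) & !helixAt
  segsFrom <- function(at, span, minLen, kind) {
    out <- emptySseTable()
    r <- rle(at)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      a <- starts[k]; b <- min(ends[k] + span, n)
      if (resno[b] - resno[a] + 1L >= minLen)
        out <- rbind(out, data.frame(kind = kind, start = resno[a], end = resno[b],
                                     stringsAsFactors = FALSE))
    }
    out
  }
  out <- rbind(segsFrom(helixAt, 4L, 4L, "H"), segsFrom(strandAt, 3L, 3L, "E"))
  if (nrow(out) == 0L) return(out)
  out <- out[order(out$start), , drop = FALSE]
  ## resolve any overlap between consecutive segments by truncating the later one
  for (k in seq_len(nrow(out))[-1L]) {
    if (out$start[k] <= out$end[k - 1L]) out$start[k] <- out$end[k - 1L] + 1L
  }
  out <- out[out$end - out$start + 1L >= ifelse(out$kind == "H", 4L, 3L), , drop = FALSE]
  rownames(out) <- NULL
  out
}

intervalJaccard <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  uni <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - inter
  inter / uni
}

## Per-position majority interval of a set of member intervals (2-col matrix).
consensusInterval <- function(members) {
  pos <- seq(min(members[, 1L]), max(members[, 2L]))
  cov <- vapply(pos, function(p) sum(members[, 1L] <= p & members[, 2L] >= p), integer(1))
  maj <- pos[2L * cov >= nrow(members)]
  c(min(maj), max(maj))
}

#' Match SSEs across models into a common SSE set
#'
#' Greedy clustering: models are processed in input order and each SSE joins
#' the existing cluster of the same kind with the highest interval Jaccard
#' overlap (at least \code{overlapFraction}) against the cluster's growing
#' consensus interval, ties broken by larger overlap then lower consensus
#' start; otherwise it seeds a new cluster. Clusters present in at least
#' \code{presenceFraction} of the models become the common SSEs, numbered in
#' sequence order of their consensus start (per-position majority interval).
#'
#' @param models list of \linkS4class{StructuralModel}.
#' @param presenceFraction minimum fraction of models (default 0.5).
#' @param overlapFraction minimum interval Jaccard (default 0.5).
#' @param targetId ensemble name.
#' @return a \linkS4class{ModelEnsemble}.
#' @export
matchCommonSses <- function(models, presenceFraction = 0.5, overlapFraction = 0.5,
                            targetId = "target") {
  if (length(models) < 2L) stop("need at least 2 models to match SSEs")
  clusters <- list()  # each: kind, members (model index, start, end), consensus
  for (mi in seq_along(models)) {
    ss <- models[[mi]]@sses
    for (k in seq_len(nrow(ss))) {
      s <- ss$start[k]; e <- ss$end[k]
      best <- 0; bestC <- NA_integer_
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        if (cl$kind != ss$kind[k]) next
        if (mi %in% cl$members[, 1L]) next   # one SSE per model per cluster
        j <- intervalJaccard(s, e, cl$consensus[1L], cl$consensus[2L])
        if (j >= overlapFraction &&
            (j > best + 1e-12 ||
             (abs(j - best) <= 1e-12 && !is.na(bestC) &&
              cl$consensus[1L] < clusters[[bestC]]$consensus[1L]))) {
          best <- j; bestC <- ci
        }
      }
      if (!is.na(bestC)) {
        cl <- clusters[[bestC]]
        cl$members <- rbind(cl$members, c(mi, s, e))
        cl$consensus <- consensusInterval(cl$members[, 2:3, drop = FALSE])
        clusters[[bestC]] <- cl
      } else {
        clusters[[length(clusters) + 1L]] <-
          list(kind = ss$kind[k], members = matrix(c(mi, s, e), nrow = 1L),
               consensus = c(s, e))
      }
    }
  }
  keep <- vapply(clusters, function(cl)
    nrow(cl$members) >= presenceFraction * length(models) - 1e-9, logical(1))
  clusters <- clusters[keep]
  if (length(clusters) == 0L)
    stop("no common SSEs across the models at presence fraction ", presenceFraction)
  ord <- order(vapply(clusters, function(cl) cl$consensus[1L], numeric(1)))
  clusters <- clusters[ord]
  cs <- data.frame(sseId = seq_along(clusters),
                   kind = vapply(clusters, `[[`, character(1), "kind"),
                   start = vapply(clusters, function(cl) as.integer(cl$consensus[1L]), integer(1)),
                   end = vapply(clusters, function(cl) as.integer(cl$consensus[2L]), integer(1)),
                   stringsAsFactors = FALSE)
  matched <- array(NA_integer_, dim = c(length(models), length(clusters), 2L))
  for (ci in seq_along(clusters)) {
    mem <- clusters[[ci]]$members
    matched[mem[, 1L], ci, 1L] <- as.integer(mem[, 2L])
    matched[mem[, 1L], ci, 2L] <- as.integer(mem[, 3L])
  }
  new("ModelEnsemble", targetId = targetId, models = models, commonSses = cs,
      matched = matched, presenceFraction = presenceFraction,
      overlapFraction = overlapFraction)
}

#' Residue interval of a common SSE within a given model
#'
#' Returns the model's own matched annotation interval, falling back to the
#' ensemble consensus interval when the model lacks a matched annotation (this
#' keeps the contact universe identical across models).
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param modelIndex index of the model in the ensemble.
#' @param sseId common SSE id.
#' @return integer c(start, end).
#' @export
sseInterval <- function(ensemble, modelIndex, sseId) {
  iv <- ensemble@matched[modelIndex, sseId, ]
  if (any(is.na(iv)))
    iv <- c(ensemble@commonSses$start[sseId], ensemble@commonSses$end[sseId])
  as.integer(iv)
}

#' All unordered SSE pairs of the ensemble's common SSE set
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @return integer P x 2 matrix, lexicographic order, a < b.
#' @export
ssePairUniverse <- function(ensemble) {
  ids <- ensemble@commonSses$sseId
  if (length(ids) < 2L) stop("need at least 2 common SSEs for an SSE-pair universe")
  t(combn(ids, 2L))
}
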