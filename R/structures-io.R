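## Reading candidate models from PDB files and the geometric primitives
## (virtual C-beta construction, C-beta distances) used throughout the planner.

IDEAL_CB_BOND <- 1.53          # Angstrom, ideal CA-CB bond length
IDEAL_TET_ANGLE <- 109.47      # degrees, ideal tetrahedral angle at CA

#' Construct a StructuralModel from raw geometry
#'
#' Low-level constructor; most users obtain models via [readModels()] or the
#' fixture generator. Missing \code{cb} rows are filled with the C-alpha
#' position (flagged by a warning in [readModels()] when it happens for real
#' input).
#'
#' @param modelId single string.
#' @param resno integer vector of 1-based residue indices, strictly increasing.
#' @param ca,cb numeric n x 3 coordinate matrices (Angstrom).
#' @param sses data.frame with columns kind ("H"/"E"), start, end.
#' @param aa one-letter amino-acid codes (default all "A").
#' @return a \linkS4class{StructuralModel}.
#' @export
structuralModel <- function(modelId, resno, ca, cb = NULL, sses = emptySseTable(),
                            aa = rep("A", length(resno))) {
  ca <- matrix(as.numeric(ca), ncol = 3L)
  if (is.null(cb)) cb <- ca else cb <- matrix(as.numeric(cb), ncol = 3L)
  new("StructuralModel", modelId = as.character(modelId), resno = as.integer(resno),
      aa = as.character(aa), ca = ca, cb = cb,
      sses = as.data.frame(sses, stringsAsFactors = FALSE))
}

#' @rdname structuralModel
#' @export
emptySseTable <- function() {
  data.frame(kind = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Ideal virtual C-beta position from backbone N/CA/C
#'
#' Places C-beta at the ideal tetrahedral position (bond length 1.53 Angstrom,
#' equal 109.47-degree angles to the N and C directions, L-chirality), used for
#' glycine and for residues whose C-beta atom is absent from the file. This
#' keeps the C-beta-C-beta distance definition uniform across residue types.
#'
#' @param n,ca,c numeric 3-vectors of backbone atom coordinates.
#' @return numeric 3-vector, the virtual C-beta position.
#' @export
virtualCb <- function(n, ca, c) {
  u <- unitv(n - ca)
  v <- unitv(c - ca)
  s <- u + v
  w <- cross3(u, v)
  if (vnorm(s) < 1e-9 || vnorm(w) < 1e-9)
    stop("degenerate backbone geometry: N, CA, C are collinear")
  s <- unitv(s); w <- unitv(w)
  ct <- cos(IDEAL_TET_ANGLE * pi / 180)
  alpha <- ct / sum(s * u)              # s.u == s.v by symmetry
  beta <- sqrt(max(0, 1 - alpha^2))     # +w side gives L-amino-acid chirality
  ca + IDEAL_CB_BOND * (alpha * s + beta * w)
}

## ---- PDB parsing (bio3d) ----------------------------------------------------

## Parse one PDB file into a list of per-model raw records.
parsePdbFile <- function(path) {
  if (!file.exists(path)) stop("cannot read model file (missing): ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("not a parseable PDB file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  nmod <- nrow(pdb$xyz)
  base <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  ids <- if (nmod > 1L) paste0(base, "_", seq_len(nmod)) else base
  lapply(seq_len(nmod), function(k) {
    at <- pdb$atom
    xyz <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)
    list(id = ids[k],
         atom = data.frame(resno = at$resno, elety = at$elety, resid = at$resid,
                           x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                           stringsAsFactors = FALSE),
         helix = pdb$helix, sheet = pdb$sheet)
  })
}

## Atom table of one model -> residue-level geometry with virtual CBs.
residueGeometry <- function(atom, id) {
  caAt <- atom[atom$elety == "CA", , drop = FALSE]
  if (nrow(caAt) == 0L) stop("model ", id, " has no C-alpha coordinates")
  caAt <- caAt[!duplicated(caAt$resno), , drop = FALSE]
  caAt <- caAt[order(caAt$resno), , drop = FALSE]
  resno <- as.integer(caAt$resno)
  getAtom <- function(elety) {
    t <- atom[atom$elety == elety, , drop = FALSE]
    t[match(resno, t$resno), c("x", "y", "z"), drop = FALSE]
  }
  ca <- as.matrix(caAt[, c("x", "y", "z")])
  cbT <- getAtom("CB"); nT <- getAtom("N"); cT <- getAtom("C")
  aa <- unname(vapply(caAt$resid, function(r) {
    a <- suppressWarnings(bio3d::aa321(r)); if (is.na(a)) "X" else a
  }, character(1)))
  cb <- matrix(NA_real_, nrow = length(resno), ncol = 3L)
  nFallback <- 0L
  for (i in seq_along(resno)) {
    hasCb <- all(is.finite(as.numeric(cbT[i, ])))
    if (hasCb && aa[i] != "G") {
      cb[i, ] <- as.numeric(cbT[i, ])
    } else if (all(is.finite(as.numeric(nT[i, ]))) && all(is.finite(as.numeric(cT[i, ])))) {
      cb[i, ] <- virtualCb(as.numeric(nT[i, ]), ca[i, ], as.numeric(cT[i, ]))
    } else {
      cb[i, ] <- ca[i, ]
      nFallback <- nFallback + 1L
    }
  }
  if (nFallback > 0L)
    warning("model ", id, ": ", nFallback,
            " residue(s) lack CB and full backbone; C-alpha used as C-beta proxy")
  list(resno = resno, aa = aa, ca = ca, cb = cb)
}

## HELIX/SHEET records of a bio3d pdb -> SSE table.
recordSses <- function(helix, sheet) {
  tab <- emptySseTable()
  if (length(helix$start))
    tab <- rbind(tab, data.frame(kind = "H", start = as.integer(helix$start),
                                 end = as.integer(helix$end), stringsAsFactors = FALSE))
  if (length(sheet$start))
    tab <- rbind(tab, data.frame(kind = "E", start = as.integer(sheet$start),
                                 end = as.integer(sheet$end), stringsAsFactors = FALSE))
  if (nrow(tab)) tab[order(tab$start), , drop = FALSE] else tab
}

#' Read a sidecar SSE annotation file
#'
#' Whitespace-delimited, one SSE per line: \code{model_id kind(H|E) start end}
#' with 1-based inclusive residue indices. Lines starting with \code{#} are
#' ignored.
#'
#' @param path file path.
#' @return data.frame with columns modelId, kind, start, end.
#' @export
readSseAnnotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file (missing): ", path)
  tab <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE, comment.char = "#",
               col.names = c("modelId", "kind", "start", "end")),
    error = function(e) stop("malformed annotation file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!all(tab$kind %in% c("H", "E")))
    stop("annotation file ", path, ": kind must be H or E")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  tab
}

clipSses <- function(sses, resno) {
  if (nrow(sses) == 0L) return(sses)
  sses$start <- pmax(sses$start, min(resno))
  sses$end <- pmin(sses$end, max(resno))
  sses <- sses[sses$start <= sses$end, , drop = FALSE]
  rownames(sses) <- NULL
  sses
}

#' Read candidate structural models into a ModelEnsemble
#'
#' Parses one PDB file per model (or a single multi-MODEL file), builds the
#' residue-level geometry with virtual C-betas where needed, attaches
#' secondary-structure annotations, and matches SSEs across models into the
#' common SSE set. Annotation source preference: sidecar file, then HELIX/SHEET
#' records in the PDB, then the internal geometric assigner [assignSses()] —
#' user-supplied secondary structure is never silently re-derived.
#'
#' Models ending up with fewer than two SSEs cannot contribute topology and are
#' excluded with a warning.
#'
#' @param paths character vector of PDB file paths.
#' @param annotations optional path to a sidecar annotation file
#'   (see [readSseAnnotations()]).
#' @param targetId name for the ensemble (default: common directory name).
#' @param presenceFraction fraction of models an SSE must appear in to be
#'   common (default 0.5).
#' @param overlapFraction minimum residue-interval Jaccard for two SSEs to be
#'   matched across models (default 0.5).
#' @return a \linkS4class{ModelEnsemble}.
#' @export
readModels <- function(paths, annotations = NULL, targetId = "target",
                       presenceFraction = 0.5, overlapFraction = 0.5) {
  ann <- if (!is.null(annotations)) readSseAnnotations(annotations) else NULL
  raws <- unlist(lapply(paths, parsePdbFile), recursive = FALSE)
  models <- list()
  for (raw in raws) {
    geo <- residueGeometry(raw$atom, raw$id)
    sses <- NULL
    if (!is.null(ann) && any(ann$modelId == raw$id)) {
      sub <- ann[ann$modelId == raw$id, c("kind", "start", "end"), drop = FALSE]
      sses <- sub[order(sub$start), , drop = FALSE]
    } else {
      sses <- recordSses(raw$helix, raw$sheet)
    }
    sses <- clipSses(sses, geo$resno)
    fromGeometry <- FALSE
    if (nrow(sses) == 0L) {
      m0 <- structuralModel(raw$id, geo$resno, geo$ca, geo$cb, aa = geo$aa)
      sses <- assignSses(m0)
      fromGeometry <- TRUE
    }
    if (nrow(sses) < 2L) {
      warning("model ", raw$id, " has fewer than 2 SSEs",
              if (fromGeometry) " (after geometric assignment)", "; excluded")
      next
    }
    models[[length(models) + 1L]] <-
      structuralModel(raw$id, geo$resno, geo$ca, geo$cb, sses = sses, aa = geo$aa)
  }
  if (length(models) < 2L)
    stop("need at least 2 usable models to build an ensemble (got ", length(models), ")")
  matchCommonSses(models, presenceFraction = presenceFraction,
                  overlapFraction = overlapFraction, targetId = targetId)
}

#' C-beta-C-beta distance between two residues of a model
#'
#' @param model a \linkS4class{StructuralModel}.
#' @param i,j residue indices (target sequence numbering).
#' @return distance in Angstrom; symmetric in i and j.
#' @export
cbDistance <- function(model, i, j) {
  pi_ <- match(i, model@resno)
  pj <- match(j, model@resno)
  if (is.na(pi_)) stop("model ", model@modelId, " has no residue ", i)
  if (is.na(pj)) stop("model ", model@modelId, " has no residue ", j)
  vnorm(model@cb[pi_, ] - model@cb[pj, ])
}

#' Per-model summary table of an ensemble
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @return data.frame (model_id, n_residues, n_sses, matched_common_sses).
#' @export
ensembleSummary <- function(ensemble) {
  data.frame(
    model_id = vapply(ensemble@models, modelId, character(1)),
    n_residues = vapply(ensemble@models, nResidues, integer(1)),
    n_sses = vapply(ensemble@models, function(m) nrow(m@sses), integer(1L)),
    matched_common_sses = rowSums(!is.na(ensemble@matched[, , 1L, drop = FALSE])),
    stringsAsFactors = FALSE)
}

#' @rdname ensembleSummary
#' @param file output path for the tab-separated summary.
#' @export
writeEnsembleSummary <- function(ensemble, file) {
  write.table(ensembleSummary(ensemble), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
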