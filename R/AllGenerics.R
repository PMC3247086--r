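## Generics, accessors and show methods.

#' @rdname StructuralModel-class
#' @param object,x a topofold S4 object
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))
#' @rdname StructuralModel-class
#' @export
setMethod("modelId", "StructuralModel", function(x) x@modelId)
#' @rdname SSEContactGraph-class
#' @export
setMethod("modelId", "SSEContactGraph", function(x) x@modelId)

#' @rdname StructuralModel-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname StructuralModel-class
#' @export
setMethod("nResidues", "StructuralModel", function(x) length(x@resno))

#' @rdname StructuralModel-class
#' @export
setGeneric("residueIndices", function(x) standardGeneric("residueIndices"))
#' @rdname StructuralModel-class
#' @export
setMethod("residueIndices", "StructuralModel", function(x) x@resno)

#' @rdname StructuralModel-class
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname StructuralModel-class
#' @export
setMethod("caCoords", "StructuralModel", function(x) x@ca)

#' @rdname StructuralModel-class
#' @export
setGeneric("cbCoords", function(x) standardGeneric("cbCoords"))
#' @rdname StructuralModel-class
#' @export
setMethod("cbCoords", "StructuralModel", function(x) x@cb)

#' @rdname StructuralModel-class
#' @export
setGeneric("sseTable", function(x) standardGeneric("sseTable"))
#' @rdname StructuralModel-class
#' @export
setMethod("sseTable", "StructuralModel", function(x) x@sses)

#' @rdname ModelEnsemble-class
#' @export
setGeneric("ensembleModels", function(x) standardGeneric("ensembleModels"))
#' @rdname ModelEnsemble-class
#' @export
setMethod("ensembleModels", "ModelEnsemble", function(x) x@models)

#' @rdname ModelEnsemble-class
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))
#' @rdname ModelEnsemble-class
#' @export
setMethod("nModels", "ModelEnsemble", function(x) length(x@models))

#' @rdname ModelEnsemble-class
#' @export
setGeneric("commonSses", function(x) standardGeneric("commonSses"))
#' @rdname ModelEnsemble-class
#' @export
setMethod("commonSses", "ModelEnsemble", function(x) x@commonSses)

#' @rdname SSEContactGraph-class
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))
#' @rdname SSEContactGraph-class
#' @export
setMethod("contacts", "SSEContactGraph", function(x) x@contacts)

#' @rdname Fingerprint-class
#' @export
setGeneric("fingerprintPairs", function(x) standardGeneric("fingerprintPairs"))
#' @rdname Fingerprint-class
#' @export
setMethod("fingerprintPairs", "Fingerprint", function(x) x@pairs)

#' @rdname CrossLinkPlan-class
#' @export
setGeneric("planLinks", function(x) standardGeneric("planLinks"))
#' @rdname CrossLinkPlan-class
#' @export
setMethod("planLinks", "CrossLinkPlan", function(x) x@links)

setMethod("show", "StructuralModel", function(object) {
  cat("StructuralModel", object@modelId, "\n",
      " residues:", length(object@resno),
      if (length(object@resno)) paste0("(", min(object@resno), "..", max(object@resno), ")") else "",
      "\n  SSEs:", nrow(object@sses),
      paste0("[", paste0(object@sses$kind, object@sses$start, "-", object@sses$end, collapse = " "), "]"),
      "\n")
})

setMethod("show", "ModelEnsemble", function(object) {
  cat("ModelEnsemble", object@targetId, "\n",
      " models:", length(object@models), "\n",
      " common SSEs:", nrow(object@commonSses),
      paste0("[", paste0(object@commonSses$kind, object@commonSses$start, "-",
                         object@commonSses$end, collapse = " "), "]"), "\n",
      " presence fraction:", object@presenceFraction, "\n")
})

setMethod("show", "SSEContactGraph", function(object) {
  cat("SSEContactGraph for model", object@modelId, "-",
      nrow(object@contacts), "contacts over", length(object@sseIds), "SSEs\n")
  if (nrow(object@contacts))
    cat(" ", paste(pairLabel(object@contacts[, 1], object@contacts[, 2]), collapse = " "), "\n")
})

setMethod("show", "ContactProbModel", function(object) {
  cat("ContactProbModel: q =", object@q, "|", nrow(object@pairs), "SSE pairs,",
      nrow(object@states), "models\n")
})

setMethod("show", "Fingerprint", function(object) {
  cat("Fingerprint:", nrow(object@pairs), "SSE pairs\n")
  if (nrow(object@pairs)) {
    cat("  pairs:", paste(pairLabel(object@pairs[, 1], object@pairs[, 2]), collapse = " "), "\n")
    cat("  scores (bits):", paste(signif(object@scores, 4), collapse = " "), "\n")
  }
  cat("  epsilon:", object@epsilon, " tau:", object@tieRatio, " nu:", object@notaRatio, "\n")
})

setMethod("show", "CrossLinkPlan", function(object) {
  cat("CrossLinkPlan for SSE pair", pairLabel(object@ssePair[1], object@ssePair[2]), ":",
      nrow(object@links), "cross-links (planSize", object@planSize, ", k0", object@k0, ")\n")
  cat("  epsilon_xlink:", object@epsilonXlink, "\n")
})
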