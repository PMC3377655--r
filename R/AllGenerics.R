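#' @rdname ProteinStructure-class
#' @param x,object a package object.
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname ProteinStructure-class
#' @export
setGeneric("metalIons", function(x) standardGeneric("metalIons"))

#' @rdname TemplateLibrary-class
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))

#' @rdname TemplateLibrary-class
#' @export
setGeneric("templateCounts", function(x) standardGeneric("templateCounts"))

#' @rdname MetalSiteTemplate-class
#' @export
setGeneric("metalType", function(x) standardGeneric("metalType"))

#' @rdname MetalSiteTemplate-class
#' @export
setGeneric("bindingResidues", function(x) standardGeneric("bindingResidues"))

#' @rdname PredictionResult-class
#' @export
setGeneric("scoresTable", function(x) standardGeneric("scoresTable"))

#' @rdname RigidTransform-class
#' @param transform a [RigidTransform-class].
#' @param coords numeric matrix of points, one per row.
#' @export
setGeneric("applyTransform",
           function(transform, coords) standardGeneric("applyTransform"))

setMethod("structureId", "ProteinStructure", function(x) x@structureId)
setMethod("structureId", "Chain", function(x) x@structureId)
setMethod("chainIds", "ProteinStructure",
          function(x) unique(x@atoms$chainId))
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)
setMethod("atomTable", "Chain", function(x) x@atoms)
setMethod("atomTable", "MetalSiteTemplate", function(x) x@atoms)
setMethod("metalIons", "ProteinStructure", function(x) x@metals)
setMethod("templates", "TemplateLibrary", function(x) x@templates)
setMethod("metalType", "MetalSiteTemplate", function(x) x@metalType)
setMethod("bindingResidues", "MetalSiteTemplate", function(x) x@residues)
setMethod("scoresTable", "PredictionResult", function(x) x@scores)

#' @rdname TemplateLibrary-class
setMethod("templateCounts", "TemplateLibrary", function(x) {
  tys <- vapply(x@templates, function(t) t@metalType, character(1))
  tab <- table(factor(tys, levels = SUPPORTED_METALS))
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname RigidTransform-class
setMethod("applyTransform", "RigidTransform", function(transform, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform@rotation), 2L, -transform@translation)
})

setMethod("show", "ProteinStructure", function(object) {
  nres <- nrow(unique(object@atoms[, c("chainId", "resNo", "insCode")]))
  cat(sprintf("ProteinStructure %s: %d chain(s), %d residue(s), %d atom(s), %d metal ion(s)\n",
              object@structureId, length(chainIds(object)), nres,
              nrow(object@atoms), nrow(object@metals)))
  if (nrow(object@metals))
    cat("  metals:", paste(object@metals$metalType, collapse = " "), "\n")
})

setMethod("show", "Chain", function(object) {
  cat(sprintf("Chain %s of %s: %d residue(s)\n", object@chainId,
              object@structureId, nrow(residueTable(object))))
})

setMethod("show", "MetalSiteTemplate", function(object) {
  cat(sprintf("MetalSiteTemplate %s [%s] from %s: %d binding residue(s)\n",
              object@templateId, object@metalType, object@sourceId,
              nrow(object@residues)))
})

setMethod("show", "TemplateLibrary", function(object) {
  cat(sprintf("TemplateLibrary: %d template(s)\n", length(object@templates)))
  cnt <- templateCounts(object)
  for (m in names(cnt))
    if (cnt[[m]] > 0) cat(sprintf("  %s: %d\n", m, cnt[[m]]))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult for %s [%s]: %d residue(s), %d called (Z >= %.2f), %d template(s) compared (%d excluded by LOO)\n",
              object@queryId, object@metalType, nrow(object@scores),
              sum(object@scores$call), object@threshold,
              object@templatesCompared, object@templatesExcluded))
})

setMethod("show", "EvalReport", function(object) {
  cat("Leave-one-out evaluation\n")
  print(object@perMetal, row.names = FALSE)
  ov <- object@overall
  cat(sprintf("overall (pooled): ACC %.3f TPR %.3f FPR %.3f\n",
              ov$ACC, ov$TPR, ov$FPR))
})
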