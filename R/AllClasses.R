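#' @import methods
NULL

SUPPORTED_METALS <- c("CA", "CU", "FE", "MG", "MN", "ZN")

# canonical atom-table columns used throughout the package
ATOM_COLS <- c("type", "atomName", "altLoc", "resName", "chainId",
               "resNo", "insCode", "x", "y", "z", "occ", "element")

#' ProteinStructure: a parsed PDB entry
#'
#' Holds the polypeptide atoms of a structure as a flat atom table plus the
#' bound metal ions recognised among its HETATM records.  Water and non-metal
#' hetero groups are retained in a separate table so the entry round-trips,
#' but they never enter the polypeptide chains.
#'
#' @slot structureId 4-character-style identifier.
#' @slot atoms data.frame of polypeptide ATOM records (one row per atom,
#'   columns \code{type, atomName, altLoc, resName, chainId, resNo, insCode,
#'   x, y, z, occ, element}).
#' @slot hetero data.frame of non-metal HETATM records (same columns).
#' @slot metals data.frame of metal ions: \code{metalType, x, y, z, sourceId}.
#' @exportClass ProteinStructure
setClass("ProteinStructure",
         representation(structureId = "character",
                        atoms = "data.frame",
                        hetero = "data.frame",
                        metals = "data.frame"))

setValidity("ProteinStructure", function(object) {
  msg <- character()
  if (length(object@structureId) != 1L)
    msg <- c(msg, "structureId must be a single string")
  if (nrow(object@atoms) > 0 && !all(ATOM_COLS %in% names(object@atoms)))
    msg <- c(msg, "atoms table lacks canonical columns")
  if (nrow(object@atoms) > 0 &&
      !all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
    msg <- c(msg, "non-finite atom coordinates")
  if (nrow(object@metals) > 0) {
    if (!all(object@metals$metalType %in% SUPPORTED_METALS))
      msg <- c(msg, "unsupported metal type")
    if (!all(is.finite(as.matrix(object@metals[, c("x", "y", "z")]))))
      msg <- c(msg, "non-finite metal coordinates")
  }
  if (length(msg)) msg else TRUE
})

#' Chain: one polypeptide chain of a structure
#'
#' @slot chainId single-character chain identifier.
#' @slot structureId identifier of the parent structure.
#' @slot atoms atom table restricted to this chain, ordered by
#'   (resNo, insCode).
#' @exportClass Chain
setClass("Chain",
         representation(chainId = "character",
                        structureId = "character",
                        atoms = "data.frame"))

setValidity("Chain", function(object) {
  if (length(object@chainId) != 1L) return("chainId must be a single string")
  if (nrow(object@atoms) == 0L) return("empty chain")
  TRUE
})

#' RigidTransform: a proper rigid-body motion
#'
#' Rotation (proper, det = +1) plus translation, applied to a point x as
#' \code{R x + t}.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector (Angstrom).
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
  if (det(R) <= 0) return("rotation is improper (det <= 0)")
  TRUE
})

#' MetalSiteTemplate: one metal ion and its binding residues
#'
#' The unit of the template library: a metal ion center together with every
#' residue having a non-hydrogen atom within the binding cutoff, stored with
#' full coordinates and the precomputed backbone N/CA/C triplets used for
#' alignment.
#'
#' @slot templateId unique identifier within a library.
#' @slot metalType one of CA, CU, FE, MG, MN, ZN.
#' @slot sourceId structure identifier the site was extracted from.
#' @slot chainIds chains contributing binding residues.
#' @slot metalCoords length-3 metal center (Angstrom).
#' @slot residues data.frame: \code{ref, resName, minDist} per binding residue.
#' @slot atoms atom table of all binding-residue atoms.
#' @slot triplets triplet set (see [buildTriplets()]) of the binding residues.
#' @exportClass MetalSiteTemplate
setClass("MetalSiteTemplate",
         representation(templateId = "character",
                        metalType = "character",
                        sourceId = "character",
                        chainIds = "character",
                        metalCoords = "numeric",
                        residues = "data.frame",
                        atoms = "data.frame",
                        triplets = "list"))

setValidity("MetalSiteTemplate", function(object) {
  msg <- character()
  if (!object@metalType %in% SUPPORTED_METALS)
    msg <- c(msg, "unsupported metal type")
  if (nrow(object@residues) < 3L)
    msg <- c(msg, "a template needs more than two binding residues")
  if (length(object@metalCoords) != 3L || !all(is.finite(object@metalCoords)))
    msg <- c(msg, "invalid metal coordinates")
  if (tripletCount(object@triplets) != nrow(object@residues))
    msg <- c(msg, "every binding residue needs a complete N/CA/C backbone")
  if (length(msg)) msg else TRUE
})

#' TemplateLibrary: per-metal collections of site templates
#'
#' @slot templates list of [MetalSiteTemplate-class] objects.
#' @slot params list of build parameters (cutoff, minResidues, metals, date).
#' @exportClass TemplateLibrary
setClass("TemplateLibrary",
         representation(templates = "list", params = "list"))

setValidity("TemplateLibrary", function(object) {
  ids <- vapply(object@templates, function(t) t@templateId, character(1))
  if (anyDuplicated(ids)) return("template ids must be unique")
  TRUE
})

#' PredictionResult: per-residue calls for one query and metal
#'
#' @slot queryId structure identifier of the query.
#' @slot metalType metal the prediction targets.
#' @slot scores data.frame with one row per residue: \code{chainId, resNo,
#'   insCode, resName, ref, raw, Z, call}.
#' @slot threshold z-score call threshold used.
#' @slot templatesCompared number of templates scanned.
#' @slot templatesExcluded number excluded by leave-one-out.
#' @exportClass PredictionResult
setClass("PredictionResult",
         representation(queryId = "character",
                        metalType = "character",
                        scores = "data.frame",
                        threshold = "numeric",
                        templatesCompared = "integer",
                        templatesExcluded = "integer"))

#' EvalReport: leave-one-out evaluation summary
#'
#' @slot perMetal data.frame with one row per metal: confusion counts,
#'   ACC/TPR/FPR, chosen threshold, AUC, template count.
#' @slot overall named list of pooled (micro-averaged) metrics.
#' @slot roc named list of per-metal ROC point data.frames.
#' @exportClass EvalReport
setClass("EvalReport",
         representation(perMetal = "data.frame",
                        overall = "list",
                        roc = "list"))
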