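#' Find metal ion-binding residues
#'
#' A residue binds a metal ion when any of its non-hydrogen atoms lies
#' within \code{cutoff} of the ion center (boundary included).
#'
#' @param chains list of [Chain-class] objects (or a single chain).
#' @param metal one row of a metal-ion table (data.frame or list with
#'   \code{metalType, x, y, z}).
#' @param cutoff binding distance in Angstrom (default 3.5).
#' @return data.frame with one row per binding residue: \code{ref, chainId,
#'   resNo, insCode, resName, minDist, contactAtom, contactElement}.
#' @export
findBindingResidues <- function(chains, metal, cutoff = 3.5) {
  if (is(chains, "Chain")) chains <- list(chains)
  mx <- as.numeric(metal$x); my <- as.numeric(metal$y); mz <- as.numeric(metal$z)
  out <- list()
  for (ch in chains) {
    a <- ch@atoms
    d <- sqrt((a$x - mx)^2 + (a$y - my)^2 + (a$z - mz)^2)
    ref <- residueRef(a$chainId, a$resNo, a$insCode)
    for (r in unique(ref[d <= cutoff])) {
      sel <- which(ref == r)
      k <- sel[which.min(d[sel])]
      out[[length(out) + 1L]] <- data.frame(
        ref = r, chainId = a$chainId[k], resNo = a$resNo[k],
        insCode = a$insCode[k], resName = a$resName[k], minDist = d[k],
        contactAtom = a$atomName[k], contactElement = a$element[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(ref = character(), chainId = character(),
                      resNo = integer(), insCode = character(),
                      resName = character(), minDist = numeric(),
                      contactAtom = character(), contactElement = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Build a metal-site template
#'
#' A site qualifies as a template only when it has more than two binding
#' residues, each with a complete N/CA/C backbone.  Rejection is a typed
#' outcome (\code{NULL} with a \code{"reason"} attribute), not an error.
#'
#' @param metal one row of a metal-ion table.
#' @param binding result of [findBindingResidues()] for that ion.
#' @param chains the chains the binding residues came from.
#' @param minResidues minimum number of binding residues (default 3).
#' @param templateId identifier to assign.
#' @return a [MetalSiteTemplate-class], or a \code{"templateRejection"}
#'   object (test with [isRejected()]; the reason is its \code{$reason}).
#' @export
buildTemplate <- function(metal, binding, chains, minResidues = 3L,
                          templateId = NULL) {
  if (is(chains, "Chain")) chains <- list(chains)
  reject <- function(why)
    structure(list(reason = why), class = "templateRejection")
  if (nrow(binding) < minResidues)
    return(reject(sprintf("only %d binding residue(s)", nrow(binding))))
  allAtoms <- do.call(rbind, lapply(chains, function(ch) ch@atoms))
  ref <- residueRef(allAtoms$chainId, allAtoms$resNo, allAtoms$insCode)
  atoms <- allAtoms[ref %in% binding$ref, , drop = FALSE]
  trip <- buildTriplets(atoms)
  if (tripletCount(trip) < nrow(binding))
    return(reject("binding residue with incomplete N/CA/C backbone"))
  srcId <- sub(":.*$", "", metal$sourceId)
  if (is.null(templateId))
    templateId <- paste0(metal$sourceId, ":", metal$metalType)
  new("MetalSiteTemplate",
      templateId = templateId, metalType = metal$metalType,
      sourceId = if (nzchar(srcId)) srcId else "UNK",
      chainIds = unique(binding$chainId),
      metalCoords = c(metal$x, metal$y, metal$z),
      residues = binding[, c("ref", "resName", "minDist"), drop = FALSE],
      atoms = atoms, triplets = trip)
}

#' @rdname buildTemplate
#' @param x object returned by [buildTemplate()].
#' @export
isRejected <- function(x) inherits(x, "templateRejection")

#' @export
print.templateRejection <- function(x, ...) {
  cat("template rejected:", x$reason, "\n")
  invisible(x)
}

#' Build a template library from structures
#'
#' Extracts curated polypeptide chains from every structure, finds the
#' binding residues of every supported metal ion, and keeps each qualifying
#' site as one template.  A structure with several ions contributes several
#' templates.
#'
#' @param structures list of [ProteinStructure-class] objects.
#' @param metals metal types to include (default all six).
#' @param cutoff binding distance cutoff in Angstrom (default 3.5).
#' @param minResidues minimum binding residues per template (default 3).
#' @param minLength minimum chain length for curation (default 51).
#' @param requireBinding drop chains without binding residues (default TRUE).
#' @return a [TemplateLibrary-class].
#' @export
buildLibrary <- function(structures, metals = SUPPORTED_METALS, cutoff = 3.5,
                         minResidues = 3L, minLength = 51L,
                         requireBinding = TRUE) {
  tpls <- list()
  if (!length(structures)) warning("no input structures: empty library")
  for (s in structures) {
    ions <- identifyMetalIons(s, metals)
    if (nrow(ions) == 0L) next
    chains <- extractPolypeptideChains(s, minLength = minLength,
                                       requireBinding = requireBinding,
                                       cutoff = cutoff)
    if (!length(chains)) next
    for (k in seq_len(nrow(ions))) {
      ion <- ions[k, , drop = FALSE]
      binding <- findBindingResidues(chains, ion, cutoff)
      tpl <- buildTemplate(ion, binding, chains, minResidues)
      if (!isRejected(tpl)) tpls[[length(tpls) + 1L]] <- tpl
    }
  }
  new("TemplateLibrary", templates = tpls,
      params = list(cutoff = cutoff, minResidues = as.integer(minResidues),
                    minLength = as.integer(minLength), metals = metals,
                    built = format(Sys.Date())))
}

#' Cluster sequences by pairwise identity
#'
#' Single-linkage clustering under global-alignment sequence identity
#' (matches / alignment length, Needleman-Wunsch with BLOSUM62 and standard
#' affine gap penalties); the first member of each cluster in input order is
#' returned as its representative.  Used to curate a non-redundant template
#' set.
#'
#' @param sequences named character vector (names are ids), or list of
#'   \code{c(id, sequence)} pairs.
#' @param threshold identity fraction linking two sequences (default 0.25).
#' @return character vector of representative ids, in input order; the full
#'   cluster membership is attached as attribute \code{"clusters"}.
#' @export
clusterByIdentity <- function(sequences, threshold = 0.25) {
  if (is.list(sequences)) {
    ids <- vapply(sequences, `[[`, "", 1L)
    seqs <- vapply(sequences, `[[`, "", 2L)
  } else {
    ids <- names(sequences)
    seqs <- unname(sequences)
  }
  stopifnot(length(seqs) >= 1L, !is.null(ids))
  n <- length(seqs)
  adj <- diag(n) > 0
  if (n > 1L) {
    B <- blosumMatrix()
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[a]), Biostrings::AAString(seqs[b]),
        substitutionMatrix = B, gapOpening = 10, gapExtension = 0.5,
        type = "global")
      ident <- Biostrings::pid(pa, type = "PID1") / 100
      adj[a, b] <- adj[b, a] <- ident >= threshold
    }
  }
  comps <- connectedComponents(adj)
  reps <- sort(vapply(comps, min, integer(1)))
  structure(ids[reps],
            clusters = lapply(comps, function(cc) ids[cc]))
}

#' Residue and contact-atom composition of a library
#'
#' For each metal type: the frequency of each of the 20 standard residues
#' among binding residues, and the frequency of contact atoms (the atom of
#' each binding residue nearest to its metal) split by backbone/side-chain
#' and element.  Each table sums to 1 per metal.
#'
#' @param library a non-empty [TemplateLibrary-class].
#' @return list with data.frames \code{residues} (metal, resName, freq) and
#'   \code{atoms} (metal, location, element, freq).
#' @export
compositionProfile <- function(library) {
  tpls <- library@templates
  if (!length(tpls)) stop("empty template library")
  backbone <- c("N", "CA", "C", "O", "OXT")
  resRows <- list(); atomRows <- list()
  for (m in unique(vapply(tpls, function(t) t@metalType, character(1)))) {
    sel <- Filter(function(t) t@metalType == m, tpls)
    resNames <- unlist(lapply(sel, function(t) t@residues$resName))
    resNames <- resNames[isStandardAA(resNames)]
    rtab <- table(factor(resNames, levels = names(AA3)))
    resRows[[m]] <- data.frame(metal = m, resName = names(rtab),
                               freq = as.numeric(rtab) / sum(rtab),
                               stringsAsFactors = FALSE)
    contacts <- do.call(rbind, lapply(sel, function(t) {
      b <- contactAtoms(t)
      data.frame(location = ifelse(b$contactAtom %in% backbone,
                                   "backbone", "sidechain"),
                 element = b$contactElement, stringsAsFactors = FALSE)
    }))
    atab <- table(paste(contacts$location, contacts$element))
    parts <- strsplit(names(atab), " ", fixed = TRUE)
    atomRows[[m]] <- data.frame(metal = m,
                                location = vapply(parts, `[`, "", 1L),
                                element = vapply(parts, `[`, "", 2L),
                                freq = as.numeric(atab) / sum(atab),
                                stringsAsFactors = FALSE)
  }
  list(residues = do.call(rbind, unname(resRows)),
       atoms = do.call(rbind, unname(atomRows)))
}

# nearest atom to the metal per binding residue, recomputed from the stored
# coordinates
contactAtoms <- function(template) {
  a <- template@atoms
  mc <- template@metalCoords
  d <- sqrt((a$x - mc[1])^2 + (a$y - mc[2])^2 + (a$z - mc[3])^2)
  ref <- residueRef(a$chainId, a$resNo, a$insCode)
  idx <- vapply(template@residues$ref, function(r) {
    sel <- which(ref == r); sel[which.min(d[sel])]
  }, integer(1))
  data.frame(ref = template@residues$ref, contactAtom = a$atomName[idx],
             contactElement = a$element[idx], minDist = d[idx],
             stringsAsFactors = FALSE)
}

#' Serialize a template library to JSON
#'
#' Coordinates are written at 3 decimals (PDB precision).
#'
#' @param library a [TemplateLibrary-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTemplateLibrary <- function(library, path) {
  tpls <- lapply(library@templates, function(t) list(
    templateId = t@templateId, metalType = t@metalType,
    sourceId = t@sourceId, chainIds = t@chainIds,
    metalCoords = round(t@metalCoords, 3),
    residues = t@residues,
    atoms = t@atoms))
  jsonlite::write_json(list(params = library@params, templates = tpls),
                       path, auto_unbox = TRUE, digits = 8, dataframe = "columns")
  invisible(path)
}

#' Read a template library from JSON
#'
#' @param path file written by [writeTemplateLibrary()].
#' @return a [TemplateLibrary-class].
#' @export
readTemplateLibrary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cols <- function(x) as.data.frame(lapply(x, function(v)
    unlist(lapply(v, function(e) if (is.null(e)) "" else e))),
    stringsAsFactors = FALSE)
  tpls <- lapply(obj$templates, function(t) {
    atoms <- cols(t$atoms)
    atoms$resNo <- as.integer(atoms$resNo)
    for (nm in c("x", "y", "z", "occ"))
      atoms[[nm]] <- as.numeric(atoms[[nm]])
    for (nm in c("altLoc", "insCode"))
      atoms[[nm]] <- as.character(atoms[[nm]])
    res <- cols(t$residues)
    res$minDist <- as.numeric(res$minDist)
    new("MetalSiteTemplate",
        templateId = t$templateId, metalType = t$metalType,
        sourceId = t$sourceId, chainIds = unlist(t$chainIds),
        metalCoords = as.numeric(unlist(t$metalCoords)),
        residues = res, atoms = atoms, triplets = buildTriplets(atoms))
  })
  new("TemplateLibrary", templates = tpls,
      params = lapply(obj$params, function(p)
        if (length(p) > 1L) unlist(p) else p))
}
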