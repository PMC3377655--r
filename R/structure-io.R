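#' Read a protein structure from PDB format
#'
#' Parses fixed-column ATOM/HETATM records into a [ProteinStructure-class].
#' Polypeptide ATOM records populate the atom table; monoatomic HETATM
#' species whose element is one of Ca/Cu/Fe/Mg/Mn/Zn become metal ions;
#' waters and other hetero groups are retained separately.  Only the first
#' MODEL of multi-model entries is used, hydrogens are discarded, and for
#' alternate locations the highest-occupancy conformer is kept (ties broken
#' in favour of altloc 'A').
#'
#' @param source path to a PDB file, or a character vector of PDB-format
#'   lines (detected by the presence of record names).
#' @param structureId identifier to assign; defaults to the file base name
#'   (or \code{"XXXX"} for literal text).
#' @return a [ProteinStructure-class].
#' @examples
#' pdb <- c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N")
#' readPDB(pdb)
#' @export
readPDB <- function(source, structureId = NULL) {
  if (length(source) > 1L || grepl("\n", source[1L]) ||
      grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK|TER|END)", source[1L])) {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(structureId)) structureId <- "XXXX"
  } else {
    path <- source
    if (!file.exists(path)) stop("cannot read PDB source: ", path)
    if (is.null(structureId))
      structureId <- toupper(sub("\\.(pdb|ent)$", "", basename(path),
                                 ignore.case = TRUE))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("no parsable ATOM/HETATM records in ", path,
                             " (", conditionMessage(e), ")"))
  a <- pdb$atom
  if (nrow(a) == 0L) stop("empty structure: no ATOM/HETATM records")

  atoms <- data.frame(
    type = a$type,
    atomName = trimws(a$elety),
    altLoc = ifelse(is.na(a$alt), "", a$alt),
    resName = trimws(a$resid),
    chainId = ifelse(is.na(a$chain), " ", a$chain),
    resNo = as.integer(a$resno),
    insCode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    element = resolveElement(a$elety, a$elesy, a$type),
    stringsAsFactors = FALSE)

  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  atoms <- selectAltLocs(atoms)

  isHet <- atoms$type == "HETATM"
  hetAtoms <- atoms[isHet, , drop = FALSE]
  polyAtoms <- atoms[!isHet, , drop = FALSE]

  # a metal ion is a monoatomic hetero species with a supported element
  metKey <- residueRef(hetAtoms$chainId, hetAtoms$resNo, hetAtoms$insCode)
  metKey <- paste(metKey, hetAtoms$resName)
  single <- metKey %in% names(which(table(metKey) == 1L))
  isMetal <- single & hetAtoms$element %in% SUPPORTED_METALS
  metals <- if (any(isMetal)) {
    m <- hetAtoms[isMetal, , drop = FALSE]
    data.frame(metalType = m$element, x = m$x, y = m$y, z = m$z,
               sourceId = sprintf("%s:%s:%d%s:%s", structureId, m$chainId,
                                  m$resNo, m$insCode, m$resName),
               stringsAsFactors = FALSE)
  } else emptyMetalTable()

  new("ProteinStructure", structureId = structureId,
      atoms = orderAtoms(polyAtoms),
      hetero = hetAtoms[!isMetal, , drop = FALSE],
      metals = metals)
}

# keep one conformer per (chain, residue, atom name): highest occupancy,
# ties resolved in favour of blank then 'A'
selectAltLocs <- function(atoms) {
  if (nrow(atoms) == 0L || all(atoms$altLoc == "")) return(atoms)
  key <- paste(atoms$chainId, atoms$resNo, atoms$insCode, atoms$resName,
               atoms$atomName, sep = "|")
  ord <- order(key, -atoms$occ, atoms$altLoc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' Write a structure in PDB format
#'
#' @param structure a [ProteinStructure-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePDB <- function(structure, path) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- rbind(structure@atoms, structure@hetero)
  m <- structure@metals
  if (nrow(m) > 0) {
    met <- emptyAtomTable()[rep(1L, 0), ]
    met <- data.frame(type = "HETATM", atomName = m$metalType, altLoc = "",
                      resName = m$metalType, chainId = "M",
                      resNo = seq_len(nrow(m)) + 900L, insCode = "",
                      x = m$x, y = m$y, z = m$z, occ = 1,
                      element = m$metalType, stringsAsFactors = FALSE)
    # recover original het identifiers when the ion came from a parsed file
    src <- strsplit(m$sourceId, ":", fixed = TRUE)
    ok <- lengths(src) == 4L
    if (any(ok)) {
      met$chainId[ok] <- vapply(src[ok], `[`, "", 2L)
      rno <- vapply(src[ok], `[`, "", 3L)
      met$insCode[ok] <- gsub("[-0-9]", "", rno)
      met$resNo[ok] <- as.integer(gsub("[^-0-9]", "", rno))
      met$resName[ok] <- vapply(src[ok], `[`, "", 4L)
    }
    a <- rbind(a, met)
  }
  if (nrow(a) == 0L) stop("empty structure")
  bio3d::write.pdb(file = path, type = a$type, eleno = seq_len(nrow(a)),
                   elety = a$atomName, resid = a$resName, chain = a$chainId,
                   resno = a$resNo,
                   insert = ifelse(a$insCode == "", NA, a$insCode),
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$occ, b = numeric(nrow(a)), elesy = a$element)
  invisible(path)
}

#' Identify bound metal ions
#'
#' Returns the metal-ion table of a structure restricted to the requested
#' metal types.  Identification is by element of monoatomic HETATM species,
#' so an ATOM record named \code{CA} (a C-alpha carbon) is never returned as
#' calcium.
#'
#' @param structure a [ProteinStructure-class].
#' @param metalTypes character vector of element symbols to keep
#'   (default: all six supported metals).
#' @return data.frame with columns \code{metalType, x, y, z, sourceId}.
#' @export
identifyMetalIons <- function(structure, metalTypes = SUPPORTED_METALS) {
  stopifnot(is(structure, "ProteinStructure"))
  m <- structure@metals
  m[m$metalType %in% toupper(metalTypes), , drop = FALSE]
}

#' Extract curated polypeptide chains
#'
#' Applies the dataset-curation rules: nucleic-acid residues are removed,
#' chains with fewer than \code{minLength} amino-acid residues are dropped,
#' and (optionally) chains without any metal ion-binding residue are dropped.
#'
#' @param structure a [ProteinStructure-class].
#' @param minLength minimum chain length kept (default 51, i.e. "more than
#'   50 residues").
#' @param requireBinding if TRUE, keep only chains with at least one residue
#'   within \code{cutoff} of any metal ion of the structure.
#' @param cutoff binding distance cutoff in Angstrom (default 3.5).
#' @return list of [Chain-class] objects (possibly empty).
#' @export
extractPolypeptideChains <- function(structure, minLength = 51L,
                                     requireBinding = FALSE, cutoff = 3.5) {
  stopifnot(is(structure, "ProteinStructure"))
  atoms <- structure@atoms
  atoms <- atoms[!(toupper(atoms$resName) %in% NUCLEIC_RES), , drop = FALSE]
  out <- list()
  for (cid in unique(atoms$chainId)) {
    ca <- orderAtoms(atoms[atoms$chainId == cid, , drop = FALSE])
    if (nrow(ca) == 0L) next
    nres <- nrow(residueTable(ca))
    if (nres < minLength) next
    if (requireBinding) {
      m <- structure@metals
      if (nrow(m) == 0L) next
      d2 <- outer(ca$x, m$x, "-")^2 + outer(ca$y, m$y, "-")^2 +
        outer(ca$z, m$z, "-")^2
      if (min(d2) > cutoff^2) next
    }
    out[[cid]] <- new("Chain", chainId = cid,
                      structureId = structure@structureId, atoms = ca)
  }
  unname(out)
}

#' One-letter sequence of a chain
#'
#' @param chain a [Chain-class].
#' @return single string; non-standard residues map to \code{"X"}.
#' @export
getSequence <- function(chain) {
  stopifnot(is(chain, "Chain"))
  rt <- residueTable(chain)
  if (nrow(rt) == 0L) stop("empty chain")
  paste(rt$aa, collapse = "")
}
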