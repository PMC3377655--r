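AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

NUCLEIC_RES <- c("DA", "DC", "DG", "DT", "DI", "DU", "A", "C", "G", "U", "I",
                 "N", "DN")

# two-letter element symbols that occur as monoatomic HETATM species; used
# when the element columns are absent and the atom name must be interpreted
TWO_LETTER_ELEMENTS <- c("ZN", "FE", "MG", "MN", "CU", "CA", "NA", "CL", "BR",
                         "NI", "CO", "CD", "HG", "SE", "AL", "SI", "LI", "RB",
                         "CS", "SR", "BA", "PB", "AG", "AU", "PT")

aa3to1 <- function(res) {
  out <- AA3[toupper(res)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa1to3 <- function(aa) {
  inv <- stats::setNames(names(AA3), AA3)
  out <- inv[toupper(aa)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

isStandardAA <- function(res) toupper(res) %in% names(AA3)

residueRef <- function(chainId, resNo, insCode) {
  ic <- ifelse(is.na(insCode) | insCode == " ", "", insCode)
  paste(chainId, resNo, ic, sep = ":")
}

# element from PDB columns when present, atom-name heuristic otherwise;
# metals are recognised by element, never by residue name, so an ATOM "CA"
# (the C-alpha carbon) is always carbon
resolveElement <- function(atomName, elesy, type) {
  elesy <- toupper(trimws(elesy))
  atomName <- toupper(trimws(atomName))
  out <- elesy
  miss <- is.na(out) | out == ""
  if (any(miss)) {
    nm <- gsub("[0-9']", "", atomName[miss])
    guess <- substr(nm, 1L, 1L)
    two <- type[miss] == "HETATM" & nm %in% TWO_LETTER_ELEMENTS
    guess[two] <- nm[two]
    out[miss] <- guess
  }
  out
}

#' Residue table of a chain or atom table
#'
#' One row per residue, in chain order: residue reference
#' (\code{chain:seqnum:icode}), name, numbering and one-letter code.
#'
#' @param x a [Chain-class] or an atom data.frame.
#' @return data.frame with columns \code{ref, chainId, resNo, insCode,
#'   resName, aa}.
#' @export
residueTable <- function(x) {
  atoms <- if (is(x, "Chain")) x@atoms else x
  if (nrow(atoms) == 0L)
    return(data.frame(ref = character(), chainId = character(),
                      resNo = integer(), insCode = character(),
                      resName = character(), aa = character()))
  ref <- residueRef(atoms$chainId, atoms$resNo, atoms$insCode)
  keep <- !duplicated(ref)
  data.frame(ref = ref[keep], chainId = atoms$chainId[keep],
             resNo = atoms$resNo[keep], insCode = atoms$insCode[keep],
             resName = atoms$resName[keep], aa = aa3to1(atoms$resName[keep]),
             stringsAsFactors = FALSE)
}

orderAtoms <- function(atoms) {
  atoms[order(atoms$chainId, atoms$resNo,
              ifelse(is.na(atoms$insCode), "", atoms$insCode)), , drop = FALSE]
}

emptyAtomTable <- function() {
  data.frame(type = character(), atomName = character(), altLoc = character(),
             resName = character(), chainId = character(), resNo = integer(),
             insCode = character(), x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), element = character(), stringsAsFactors = FALSE)
}

emptyMetalTable <- function() {
  data.frame(metalType = character(), x = numeric(), y = numeric(),
             z = numeric(), sourceId = character(), stringsAsFactors = FALSE)
}
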