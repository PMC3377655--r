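# Deterministic synthetic structures: ideal polypeptide backbones, planted
# metal sites, coordinate noise and rigid motions.  These emulate the one
# statistical property the predictor relies on -- >= 3 spatially clustered
# binding residues around a metal center, recurring across structures -- not
# physically realistic coordination chemistry.

IDEAL_GEOM <- list(bNCa = 1.458, bCaC = 1.525, bCN = 1.329, bCO = 1.231,
                   aNCaC = 111.0, aCaCN = 116.6, aCNCa = 121.9,
                   aCaCO = 120.8, omega = 180)

# residues preferred around each metal type; used for planted binders so the
# sequence term is exercised realistically
METAL_PREFERRED <- list(CA = c("ASP", "GLU", "ASN"), CU = c("HIS", "HIS", "MET"),
                        FE = c("HIS", "GLU", "CYS"), MG = c("ASP", "GLU", "ASP"),
                        MN = c("ASP", "HIS", "GLU"), ZN = c("CYS", "CYS", "HIS"))

DONOR_ATOM <- list(CYS = c("SG", "S"), HIS = c("NE2", "N"), ASP = c("OD2", "O"),
                   GLU = c("OE2", "O"), ASN = c("OD1", "O"), MET = c("SD", "S"))

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

# NeRF atom placement: D with |CD| = bond, angle(B,C,D) = ang (deg),
# dihedral(A,B,C,D) = tor (deg)
placeAtom <- function(A, B, C, bond, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  C + cbind(bc, m, n) %*% d2
}

#' Generate an ideal polypeptide backbone
#'
#' Builds an N/CA/C/O backbone with ideal bond lengths (N-CA 1.458, CA-C
#' 1.525, C-N 1.329 Angstrom), ideal bond angles, trans peptide bonds and
#' conformation-appropriate dihedrals: helix (phi -57, psi -47), strand
#' (phi -139, psi 135), or irregular (seeded random coil dihedrals).
#' Deterministic for a given seed.
#'
#' @param nResidues chain length (>= 1).
#' @param conformation \code{"helix"}, \code{"strand"} or \code{"irregular"}.
#' @param sequence one-letter sequence string (defaults to a seeded random
#'   sequence of the 20 standard residues).
#' @param seed integer seed controlling dihedrals and sequence.
#' @param chainId,structureId identifiers for the result.
#' @return a [Chain-class].
#' @export
makeBackbone <- function(nResidues, conformation = c("helix", "strand",
                                                     "irregular"),
                         sequence = NULL, seed = 1L, chainId = "A",
                         structureId = "SYNT") {
  stopifnot(nResidues >= 1L)
  conformation <- match.arg(conformation)
  g <- IDEAL_GEOM
  dih <- withSeed(seed, switch(conformation,
    helix = list(phi = rep(-57, nResidues), psi = rep(-47, nResidues)),
    strand = list(phi = rep(-139, nResidues), psi = rep(135, nResidues)),
    irregular = list(phi = stats::runif(nResidues, -160, -55),
                     psi = stats::runif(nResidues, -70, 160))))
  if (is.null(sequence))
    sequence <- withSeed(seed + 1L,
      paste(sample(names(AA3), nResidues, replace = TRUE) |> aa3to1(),
            collapse = ""))
  seq3 <- aa1to3(strsplit(sequence, "")[[1L]])
  stopifnot(length(seq3) == nResidues)

  N <- CA <- C <- O <- matrix(NA_real_, nResidues, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$bNCa, 0, 0)
  th <- (180 - g$aNCaC) * pi / 180
  C[1L, ] <- CA[1L, ] + g$bCaC * c(cos(th), sin(th), 0)
  for (i in seq_len(nResidues)) {
    if (i > 1L) {
      N[i, ] <- placeAtom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                          g$bCN, g$aCaCN, dih$psi[i - 1L])
      CA[i, ] <- placeAtom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                           g$bNCa, g$aCNCa, g$omega)
      C[i, ] <- placeAtom(C[i - 1L, ], N[i, ], CA[i, ],
                          g$bCaC, g$aNCaC, dih$phi[i])
    }
    O[i, ] <- placeAtom(N[i, ], CA[i, ], C[i, ],
                        g$bCO, g$aCaCO, dih$psi[i] + 180)
  }
  per <- function(name, coords, elem) data.frame(
    type = "ATOM", atomName = name, altLoc = "", resName = seq3,
    chainId = chainId, resNo = seq_len(nResidues), insCode = "",
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L], occ = 1,
    element = elem, stringsAsFactors = FALSE)
  atoms <- rbind(per("N", N, "N"), per("CA", CA, "C"),
                 per("C", C, "C"), per("O", O, "O"))
  atoms <- atoms[order(atoms$resNo,
                       match(atoms$atomName, c("N", "CA", "C", "O"))), ]
  rownames(atoms) <- NULL
  new("Chain", chainId = chainId, structureId = structureId, atoms = atoms)
}

#' Plant a metal-binding site on a chain
#'
#' Mutates the chosen residues to metal-preferred types, adds one
#' side-chain donor atom per chosen residue at \code{donorDist} from a
#' feasible metal position, and places the metal ion there.  The position is
#' searched so that every chosen residue has an atom within \code{cutoff}
#' while every other residue's nearest atom stays beyond
#' \code{cutoff + margin}; the construction is verified post hoc by a
#' brute-force distance scan and fails loudly if infeasible.
#'
#' @param x a [Chain-class] or a [ProteinStructure-class] from a previous
#'   planting (sites accumulate).
#' @param metalTypeP metal type to plant.
#' @param indices residue numbers of the binding residues (>= 3, matching
#'   the template rule).
#' @param cutoff binding cutoff in Angstrom (default 3.5).
#' @param margin decoy clearance beyond the cutoff (default 0.5 Angstrom).
#' @param donorDist donor-to-metal distance (default 2.2 Angstrom).
#' @return a [ProteinStructure-class] with the site planted.
#' @export
plantMetalSite <- function(x, metalTypeP, indices, cutoff = 3.5,
                           margin = 0.5, donorDist = 2.2) {
  metalTypeP <- toupper(metalTypeP)
  stopifnot(metalTypeP %in% SUPPORTED_METALS)
  if (length(indices) < 3L)
    stop("a planted site needs more than two binding residues (template rule)")
  if (is(x, "Chain")) {
    atoms <- x@atoms
    metals <- emptyMetalTable()
    sid <- x@structureId; cid <- x@chainId
  } else {
    atoms <- x@atoms
    metals <- x@metals
    sid <- x@structureId; cid <- atoms$chainId[1L]
  }
  if (!all(indices %in% atoms$resNo)) stop("planted residue index out of range")

  pref <- METAL_PREFERRED[[metalTypeP]]
  newRes <- pref[((seq_along(indices) - 1L) %% length(pref)) + 1L]
  for (k in seq_along(indices))
    atoms$resName[atoms$resNo == indices[k]] <- newRes[k]

  selAtoms <- atoms$resNo %in% indices
  caSel <- atoms[selAtoms & atoms$atomName == "CA", c("x", "y", "z")]
  caAll <- atoms[atoms$atomName == "CA", c("x", "y", "z")]
  center <- colMeans(as.matrix(caSel))
  dir0 <- center - colMeans(as.matrix(caAll))
  if (sqrt(sum(dir0^2)) < 1e-6) dir0 <- c(0, 0, 1)
  dir0 <- dir0 / sqrt(sum(dir0^2))
  dirs <- rbind(dir0, t(vapply(seq_len(26L), function(k) {
    v <- c((k %% 3) - 1, ((k %/% 3) %% 3) - 1, ((k %/% 9) %% 3) - 1)
    if (all(v == 0)) v <- c(0, 0, 1)
    v / sqrt(sum(v^2))
  }, numeric(3L))))
  other <- as.matrix(atoms[!selAtoms, c("x", "y", "z")])
  pos <- NULL
  for (d in seq(4, 16, by = 0.5)) {
    for (r in seq_len(nrow(dirs))) {
      cand <- center + d * dirs[r, ]
      clear <- min(sqrt(rowSums(sweep(other, 2L, cand)^2)))
      metClear <- if (nrow(metals)) min(sqrt((metals$x - cand[1])^2 +
                    (metals$y - cand[2])^2 + (metals$z - cand[3])^2)) else Inf
      if (clear > cutoff + margin && metClear > 2 * (cutoff + margin)) {
        pos <- cand; break
      }
    }
    if (!is.null(pos)) break
  }
  if (is.null(pos))
    stop("no feasible metal position: chosen residues too entangled with ",
         "the rest of the chain (clearance ", cutoff + margin, " A)")

  chainBefore <- new("Chain", chainId = cid, structureId = sid, atoms = atoms)
  bindBefore <- lapply(seq_len(nrow(metals)), function(k)
    sort(findBindingResidues(chainBefore, metals[k, , drop = FALSE],
                             cutoff)$ref))

  donors <- do.call(rbind, lapply(seq_along(indices), function(k) {
    i <- indices[k]
    ca <- as.numeric(atoms[atoms$resNo == i & atoms$atomName == "CA",
                           c("x", "y", "z")])
    u <- ca - pos; u <- u / sqrt(sum(u^2))
    dp <- pos + donorDist * u
    da <- DONOR_ATOM[[newRes[k]]]
    data.frame(type = "ATOM", atomName = da[1L], altLoc = "",
               resName = newRes[k], chainId = cid, resNo = i, insCode = "",
               x = dp[1L], y = dp[2L], z = dp[3L], occ = 1, element = da[2L],
               stringsAsFactors = FALSE)
  }))
  atoms <- orderAtoms(rbind(atoms, donors))
  metals <- rbind(metals, data.frame(
    metalType = metalTypeP, x = pos[1L], y = pos[2L], z = pos[3L],
    sourceId = sprintf("%s:M:%d:%s", sid, 900L + nrow(metals) + 1L,
                       metalTypeP),
    stringsAsFactors = FALSE))
  st <- new("ProteinStructure", structureId = sid, atoms = atoms,
            hetero = emptyAtomTable(), metals = metals)

  # brute-force verification: the new site binds exactly its residues and
  # no previously planted site gained or lost a residue
  chain <- new("Chain", chainId = cid, structureId = sid, atoms = atoms)
  bNew <- findBindingResidues(chain, metals[nrow(metals), , drop = FALSE],
                              cutoff)
  if (nrow(bNew) != length(indices) ||
      !setequal(bNew$resNo, as.integer(indices)))
    stop("planted site verification failed: bound residues {",
         paste(sort(bNew$resNo), collapse = ","), "} != requested {",
         paste(sort(indices), collapse = ","), "}")
  for (k in seq_along(bindBefore)) {
    bOld <- sort(findBindingResidues(chain, metals[k, , drop = FALSE],
                                     cutoff)$ref)
    if (!identical(bOld, bindBefore[[k]]))
      stop("planting disturbed a previously planted site (metal ", k, ")")
  }
  st
}

#' Perturb coordinates with Gaussian noise
#'
#' Adds i.i.d. N(0, sigma^2) displacement to every atom and metal
#' coordinate; deterministic for a given seed.
#'
#' @param structure a [ProteinStructure-class].
#' @param sigma noise level in Angstrom (>= 0).
#' @param seed integer seed.
#' @return the perturbed structure.
#' @export
perturbStructure <- function(structure, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(structure)
  withSeed(seed, {
    na <- nrow(structure@atoms); nm <- nrow(structure@metals)
    noise <- matrix(stats::rnorm(3L * (na + nm), sd = sigma), ncol = 3L)
    structure@atoms[, c("x", "y", "z")] <-
      structure@atoms[, c("x", "y", "z")] + noise[seq_len(na), , drop = FALSE]
    if (nm) structure@metals[, c("x", "y", "z")] <-
      structure@metals[, c("x", "y", "z")] +
      noise[na + seq_len(nm), , drop = FALSE]
  })
  validObject(structure)
  structure
}

#' Random proper rigid transform
#'
#' Rotation drawn from a seeded random unit quaternion (uniform on SO(3)),
#' translation uniform in \[-20, 20\] Angstrom per axis.
#'
#' @param seed integer seed.
#' @return a [RigidTransform-class].
#' @export
randomRigidTransform <- function(seed = 1L) {
  withSeed(seed, {
    q <- stats::rnorm(4L); q <- q / sqrt(sum(q^2))
    w <- q[1L]; xq <- q[2L]; yq <- q[3L]; zq <- q[4L]
    R <- matrix(c(1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
                  2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
                  2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)),
                3L, 3L, byrow = TRUE)
    rigidTransform(R, stats::runif(3L, -20, 20))
  })
}

#' Apply a rigid motion to a whole structure
#'
#' @param structure a [ProteinStructure-class].
#' @param transform a [RigidTransform-class]; if NULL, a random one drawn
#'   with \code{seed}.
#' @param seed seed for the random transform.
#' @return the moved structure.
#' @export
rigidMove <- function(structure, transform = NULL, seed = 1L) {
  if (is.null(transform)) transform <- randomRigidTransform(seed)
  validObject(transform)
  structure@atoms[, c("x", "y", "z")] <-
    applyTransform(transform, as.matrix(structure@atoms[, c("x", "y", "z")]))
  if (nrow(structure@metals))
    structure@metals[, c("x", "y", "z")] <-
      applyTransform(transform, as.matrix(structure@metals[, c("x", "y", "z")]))
  structure
}

renameStructure <- function(structure, id) {
  old <- structure@structureId
  structure@structureId <- id
  if (nrow(structure@metals))
    structure@metals$sourceId <- sub(paste0("^", old, ":"), paste0(id, ":"),
                                     structure@metals$sourceId)
  structure
}

#' Build a labelled synthetic benchmark
#'
#' Generates \code{nStructures} structures that are independently perturbed
#' (sigma \code{noiseSigma}) and rigidly moved copies of one base chain with
#' planted metal sites, so that templates built from one structure match the
#' sites of every other -- the setting leave-one-out evaluation requires.
#' Truth labels are recomputed from each structure's own perturbed geometry
#' by [findBindingResidues()], keeping labels and coordinates consistent by
#' construction.
#'
#' @param nStructures number of structures (>= 2 for leave-one-out).
#' @param nResidues chain length of the base structure (default 60).
#' @param sites named list: metal type -> residue indices (default one Zn
#'   site of 4 residues and one Ca site of 3).
#' @param noiseSigma coordinate noise in Angstrom (default 0.1).
#' @param seed master seed; every derived seed is a small offset of it.
#' @param margin decoy clearance passed to [plantMetalSite()] (default 1.5
#'   Angstrom, so the noise cannot move a decoy across the truth cutoff).
#' @return list with \code{structures} (list of [ProteinStructure-class]),
#'   \code{truth} (data.frame: structureId, metalType, ref, resNo) and
#'   \code{base}.
#' @export
makeBenchmark <- function(nStructures = 20L, nResidues = 60L,
                          sites = list(ZN = c(10L, 11L, 13L, 14L),
                                       CA = c(35L, 36L, 38L)),
                          noiseSigma = 0.1, seed = 42L, margin = 1.5) {
  stopifnot(nStructures >= 2L)
  base <- makeBackbone(nResidues, "irregular", seed = seed,
                       structureId = "BASE")
  st <- base
  for (m in names(sites))
    st <- plantMetalSite(st, m, sites[[m]], margin = margin)
  structures <- vector("list", nStructures)
  truthRows <- list()
  for (s in seq_len(nStructures)) {
    id <- sprintf("B%03d", s)
    cp <- renameStructure(st, id)
    cp <- perturbStructure(cp, noiseSigma, seed = seed + 1000L + s)
    cp <- rigidMove(cp, seed = seed + 2000L + s)
    structures[[s]] <- cp
    chains <- extractPolypeptideChains(cp, minLength = 1L)
    for (k in seq_len(nrow(cp@metals))) {
      b <- findBindingResidues(chains, cp@metals[k, , drop = FALSE])
      if (nrow(b))
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          structureId = id, metalType = cp@metals$metalType[k],
          ref = b$ref, resNo = b$resNo, stringsAsFactors = FALSE)
    }
  }
  list(structures = structures,
       truth = do.call(rbind, truthRows),
       base = st)
}

#' Write a benchmark to disk
#'
#' One PDB file per structure plus a \code{truth.tsv} label table.
#'
#' @param benchmark result of [makeBenchmark()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeBenchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in benchmark$structures)
    writePDB(s, file.path(dir, paste0(s@structureId, ".pdb")))
  utils::write.table(benchmark$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
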