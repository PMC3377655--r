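#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 translation (Angstrom).
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = translation)
}

#' Backbone triplets of a chain
#'
#' The alignment unit of the fragment transformation method: the ordered
#' N, C-alpha, C backbone atoms of a single residue.  Peptide-bond atoms of
#' the neighbouring residues are deliberately excluded, so a triplet carries
#' no backbone-torsion information.  Residues missing any of the three atoms
#' are skipped.
#'
#' @param x a [Chain-class], a [MetalSiteTemplate-class], or an atom
#'   data.frame.
#' @return a triplet set: list with \code{refs} (residue references),
#'   \code{resNames}, \code{aa} (one-letter codes) and \code{coords}, a
#'   \code{3 x 3 x k} array whose slice \code{[, , i]} holds the N/CA/C
#'   positions of residue \code{i} as columns (xyz by atom).
#' @export
buildTriplets <- function(x) {
  atoms <- if (is(x, "Chain") || is(x, "MetalSiteTemplate")) x@atoms else x
  rt <- residueTable(atoms)
  ref <- residueRef(atoms$chainId, atoms$resNo, atoms$insCode)
  refs <- character(0); resNames <- character(0)
  coords <- array(NA_real_, dim = c(3L, 3L, nrow(rt)))
  k <- 0L
  for (i in seq_len(nrow(rt))) {
    sel <- atoms[ref == rt$ref[i], , drop = FALSE]
    iN <- match("N", sel$atomName)
    iA <- match("CA", sel$atomName)
    iC <- match("C", sel$atomName)
    if (anyNA(c(iN, iA, iC))) next
    M <- t(as.matrix(sel[c(iN, iA, iC), c("x", "y", "z")]))  # 3 x 3, atoms as cols
    if (tripletArea(M) <= 1e-6) next
    k <- k + 1L
    coords[, , k] <- M
    refs[k] <- rt$ref[i]
    resNames[k] <- rt$resName[i]
  }
  list(refs = refs, resNames = resNames, aa = aa3to1(resNames),
       coords = if (k) coords[, , seq_len(k), drop = FALSE]
                else array(0, dim = c(3, 3, 0)))
}

tripletCount <- function(triplets) {
  if (is.null(triplets$coords)) 0L else dim(triplets$coords)[3L]
}

# area spanned by the three points (collinearity guard)
tripletArea <- function(M) {
  v1 <- M[, 2L] - M[, 1L]
  v2 <- M[, 3L] - M[, 1L]
  cr <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
          v1[3L] * v2[1L] - v1[1L] * v2[3L],
          v1[1L] * v2[2L] - v1[2L] * v2[1L])
  0.5 * sqrt(sum(cr^2))
}

# least-squares proper superposition of point set P onto Q (points as rows);
# reflections are excluded by construction
kabsch <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2L, cP); Q0 <- sweep(Q, 2L, cQ)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cQ - as.vector(R %*% cP)
  moved <- P %*% t(R)
  moved <- sweep(moved, 2L, -tr)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

#' Superpose one backbone triplet onto another
#'
#' Least-squares (Kabsch) proper rigid-body superposition of the three
#' N/CA/C points of \code{src} onto those of \code{dst}.
#'
#' @param src,dst 3x3 matrices with atom positions as columns (as stored in
#'   a triplet set slice), or single-triplet sets.
#' @return list with \code{transform} (a [RigidTransform-class]) and
#'   \code{fitRmsd}, the residual RMSD of the three points (Angstrom).
#' @export
superposeTriplet <- function(src, dst) {
  src <- asTripletMatrix(src); dst <- asTripletMatrix(dst)
  if (tripletArea(src) <= 1e-6 || tripletArea(dst) <= 1e-6)
    stop("degenerate (collinear) triplet geometry")
  k <- kabsch(t(src), t(dst))
  list(transform = rigidTransform(k$rotation, k$translation),
       fitRmsd = k$rmsd)
}

asTripletMatrix <- function(x) {
  if (is.list(x) && !is.null(x$coords)) x <- x$coords[, , 1L]
  stopifnot(is.matrix(x), all(dim(x) == c(3L, 3L)))
  x
}

#' Distance between a transformed triplet pair
#'
#' RMSD over the three corresponding points between triplet
#' \code{sigma} moved by \code{transform} and triplet \code{tau}; the
#' compatibility measure used for single-linkage clustering.
#'
#' @param transform a [RigidTransform-class].
#' @param sigma,tau 3x3 triplet matrices (columns = N/CA/C positions).
#' @return RMSD in Angstrom.
#' @export
pairDistance <- function(transform, sigma, tau) {
  sigma <- asTripletMatrix(sigma); tau <- asTripletMatrix(tau)
  moved <- transform@rotation %*% sigma + transform@translation
  sqrt(mean(colSums((moved - tau)^2)))
}

#' Enumerate all query/template triplet pairs
#'
#' Builds the m x n matrix of candidate correspondences: every query triplet
#' is superposed onto every template triplet and the rigid transform and
#' residual recorded.  An optional sequence prefilter drops pairs whose
#' BLOSUM62 score is negative.
#'
#' @param queryTriplets,templateTriplets triplet sets from [buildTriplets()].
#' @param prefilter if TRUE, skip pairs with BLOSUM62(query, template) < 0.
#'   Off by default: the method scans the full matrix.
#' @return a pair set: list with integer vectors \code{i} (query index) and
#'   \code{j} (template index), \code{fitRmsd}, rotation array \code{rot}
#'   (3x3xP) and translation matrix \code{trans} (P x 3), plus the two
#'   triplet sets.
#' @export
enumeratePairs <- function(queryTriplets, templateTriplets, prefilter = FALSE) {
  m <- tripletCount(queryTriplets); n <- tripletCount(templateTriplets)
  grid <- expand.grid(i = seq_len(m), j = seq_len(n))
  if (m && n && prefilter) {
    sc <- blosum62Score(queryTriplets$aa[grid$i], templateTriplets$aa[grid$j])
    grid <- grid[sc >= 0, , drop = FALSE]
  }
  P <- nrow(grid)
  rot <- array(NA_real_, dim = c(3L, 3L, P))
  trans <- matrix(NA_real_, P, 3L)
  fit <- numeric(P)
  for (p in seq_len(P)) {
    k <- kabsch(t(queryTriplets$coords[, , grid$i[p]]),
                t(templateTriplets$coords[, , grid$j[p]]))
    rot[, , p] <- k$rotation
    trans[p, ] <- k$translation
    fit[p] <- k$rmsd
  }
  list(i = grid$i, j = grid$j, fitRmsd = fit, rot = rot, trans = trans,
       query = queryTriplets, template = templateTriplets)
}

# P x P matrix of pair distances: entry [p, q] is the RMSD between
# transform p applied to query triplet i(q) and template triplet j(q)
pairDistanceMatrix <- function(pairs) {
  P <- length(pairs$i)
  qc <- pairs$query$coords; tc <- pairs$template$coords
  m <- dim(qc)[3L]; n <- dim(tc)[3L]
  Sflat <- matrix(qc, nrow = 3L)            # 3 x 3m, triplet k in cols 3k-2..3k
  Tflat <- matrix(tc, nrow = 3L)            # 3 x 3n
  idxQ <- as.vector(vapply(pairs$i, function(k) (3L * (k - 1L) + 1L):(3L * k),
                           integer(3L)))
  idxT <- as.vector(vapply(pairs$j, function(l) (3L * (l - 1L) + 1L):(3L * l),
                           integer(3L)))
  Tsel <- Tflat[, idxT, drop = FALSE]
  D <- matrix(NA_real_, P, P)
  sel3 <- seq_len(P) * 3L
  for (p in seq_len(P)) {
    A <- pairs$rot[, , p] %*% Sflat + pairs$trans[p, ]
    ss <- colSums((A[, idxQ, drop = FALSE] - Tsel)^2)
    D[p, ] <- sqrt((ss[sel3 - 2L] + ss[sel3 - 1L] + ss[sel3]) / 3)
  }
  D
}

#' Single-linkage clustering of compatible triplet pairs
#'
#' Two candidate pairs (i,j) and (k,l) are linked when each pair's transform
#' carries the other's query triplet to within \code{dC} (RMSD) of its
#' template triplet, in both directions.  Clusters are the transitive
#' closure of this symmetric relation (single linkage, iterated until no new
#' merges).  Within each cluster a one-to-one residue correspondence is
#' enforced greedily by ascending superposition residual (ties by query then
#' template index), and clusters whose correspondence is smaller than
#' \code{minClusterSize} are discarded.
#'
#' @param pairs a pair set from [enumeratePairs()].
#' @param dC linkage threshold in Angstrom (default 2.0).
#' @param minClusterSize minimum correspondence size kept (default 3,
#'   matching the template rule of more than two binding residues).
#' @return list of clusters; each has \code{pairIdx} (members before
#'   one-to-one reduction) and \code{corr}, a data.frame with columns
#'   \code{qIdx, tIdx, qRef, tRef, qRes, tRes, fitRmsd}.
#' @export
clusterPairs <- function(pairs, dC = 2.0, minClusterSize = 3L) {
  P <- length(pairs$i)
  if (P == 0L) return(list())
  D <- pairDistanceMatrix(pairs)
  adj <- (D <= dC) & (t(D) <= dC)
  comp <- connectedComponents(adj)
  out <- list()
  for (cc in comp) {
    corr <- oneToOne(pairs, cc)
    if (nrow(corr) < minClusterSize) next
    out[[length(out) + 1L]] <- list(pairIdx = cc, corr = corr)
  }
  out
}

# breadth-first connected components of a logical adjacency matrix
connectedComponents <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

oneToOne <- function(pairs, idx) {
  ord <- idx[order(pairs$fitRmsd[idx], pairs$i[idx], pairs$j[idx])]
  qUsed <- tUsed <- integer(0)
  keep <- integer(0)
  for (p in ord) {
    if (pairs$i[p] %in% qUsed || pairs$j[p] %in% tUsed) next
    keep <- c(keep, p)
    qUsed <- c(qUsed, pairs$i[p]); tUsed <- c(tUsed, pairs$j[p])
  }
  keep <- keep[order(pairs$i[keep])]
  data.frame(qIdx = pairs$i[keep], tIdx = pairs$j[keep],
             qRef = pairs$query$refs[pairs$i[keep]],
             tRef = pairs$template$refs[pairs$j[keep]],
             qRes = pairs$query$resNames[pairs$i[keep]],
             tRes = pairs$template$resNames[pairs$j[keep]],
             fitRmsd = pairs$fitRmsd[keep], stringsAsFactors = FALSE)
}

#' Aligned substructure of a cluster
#'
#' @param cluster one element of the [clusterPairs()] result.
#' @return list with equal-length \code{query} and \code{template} residue
#'   reference vectors, order-matched.
#' @export
alignedSubstructure <- function(cluster) {
  if (is.null(cluster$corr) || nrow(cluster$corr) == 0L)
    stop("empty cluster")
  list(query = cluster$corr$qRef, template = cluster$corr$tRef)
}
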