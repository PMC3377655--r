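.pkgCache <- new.env(parent = emptyenv())

# canonical BLOSUM62 from Biostrings, with the package policy that 'X'
# (and any unknown letter) scores 0 against everything
blosumMatrix <- function() {
  if (is.null(.pkgCache$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    B <- e$BLOSUM62
    B["X", ] <- 0L
    B[, "X"] <- 0L
    .pkgCache$blosum <- B
  }
  .pkgCache$blosum
}

#' BLOSUM62 substitution score
#'
#' Vectorized lookup; letters outside the matrix (including \code{"X"})
#' score 0 against everything.
#'
#' @param a,b one-letter amino-acid vectors (recycled to common length).
#' @return integer score vector.
#' @export
blosum62Score <- function(a, b) {
  B <- blosumMatrix()
  a <- toupper(a); b <- toupper(b)
  a[!a %in% rownames(B)] <- "X"
  b[!b %in% rownames(B)] <- "X"
  unname(B[cbind(a, b)])
}

#' Scoring parameters
#'
#' Bundles every tunable of the scoring and prediction stage.
#'
#' @param rmsdMax upper bound of the C-alpha RMSD filter in Angstrom
#'   (default 3.0; alignments at or above it are rejected).
#' @param thetaSeq sequence-conservation threshold: a cluster qualifies only
#'   if its normalized sequence score exceeds this value (strict).  A single
#'   number, or a named per-metal vector.
#' @param combineMode how structure and sequence terms combine:
#'   \code{"product"} (default) or \code{"mean"}.
#' @param aggregateMode how qualifying cluster scores accumulate per
#'   residue: \code{"sum"} (default) or \code{"max"}.
#' @param dC single-linkage compatibility threshold in Angstrom (default 2.0).
#' @param minClusterSize minimum aligned-substructure size (default 3).
#' @param prefilter BLOSUM62 >= 0 pair prefilter (default FALSE).
#' @param zThresholds named per-metal z-score call thresholds
#'   (defaults CA 1.6, CU 1.8, MG 1.8, FE 1.0, MN 1.0, ZN 2.2).
#' @param cutoff metal-binding distance cutoff in Angstrom (default 3.5).
#' @param minLength minimum curated chain length (default 51).
#' @return a named list of class \code{"ScoringParams"}.
#' @export
scoringParams <- function(rmsdMax = 3.0, thetaSeq = 0.30,
                          combineMode = c("product", "mean"),
                          aggregateMode = c("sum", "max"),
                          dC = 2.0, minClusterSize = 3L, prefilter = FALSE,
                          zThresholds = c(CA = 1.6, CU = 1.8, MG = 1.8,
                                          FE = 1.0, MN = 1.0, ZN = 2.2),
                          cutoff = 3.5, minLength = 51L) {
  stopifnot(rmsdMax > 0)
  structure(list(rmsdMax = rmsdMax, thetaSeq = thetaSeq,
                 combineMode = match.arg(combineMode),
                 aggregateMode = match.arg(aggregateMode),
                 dC = dC, minClusterSize = as.integer(minClusterSize),
                 prefilter = prefilter, zThresholds = zThresholds,
                 cutoff = cutoff, minLength = as.integer(minLength)),
            class = "ScoringParams")
}

thetaFor <- function(params, metal) {
  th <- params$thetaSeq
  if (!is.null(names(th)) && metal %in% names(th)) unname(th[[metal]])
  else unname(th[[1L]])
}

zThresholdFor <- function(params, metal) {
  zt <- params$zThresholds
  if (!is.null(names(zt)) && metal %in% names(zt)) unname(zt[[metal]])
  else unname(zt[[1L]])
}

#' C-alpha RMSD of an aligned substructure
#'
#' A fresh least-squares superposition of the matched C-alpha sets (not the
#' triplet transform that seeded the cluster).
#'
#' @param cluster a cluster from [clusterPairs()].
#' @param queryTriplets,templateTriplets the triplet sets the cluster was
#'   built from.
#' @return RMSD in Angstrom.
#' @export
clusterRMSD <- function(cluster, queryTriplets, templateTriplets) {
  corr <- cluster$corr
  if (is.null(corr) || nrow(corr) < 3L)
    stop("cluster RMSD needs at least 3 correspondences")
  P <- t(queryTriplets$coords[, 2L, corr$qIdx])     # CA rows
  Q <- t(templateTriplets$coords[, 2L, corr$tIdx])
  kabsch(P, Q)$rmsd
}

#' Sequence-conservation score of an aligned substructure
#'
#' Sum of BLOSUM62 scores over the residue correspondence, normalized by the
#' template fragment's self-score (its maximum attainable alignment score).
#'
#' @param cluster a cluster from [clusterPairs()].
#' @return list with \code{seqRaw}, \code{seqMax} and \code{sSeq = seqRaw /
#'   seqMax}.
#' @export
seqScore <- function(cluster) {
  corr <- cluster$corr
  if (is.null(corr) || nrow(corr) == 0L) stop("empty cluster")
  qa <- aa3to1(corr$qRes); ta <- aa3to1(corr$tRes)
  seqRaw <- sum(blosum62Score(qa, ta))
  seqMax <- sum(blosum62Score(ta, ta))
  if (seqMax <= 0)
    stop("template fragment self-score is not positive (non-standard residues only)")
  list(seqRaw = seqRaw, seqMax = seqMax, sSeq = seqRaw / seqMax)
}

#' Structure-conservation score
#'
#' Linear map anchored at the RMSD bound: \code{1 - rmsd/rmsdMax}, clamped
#' at 0.  Alignments with \code{rmsd >= rmsdMax} must additionally be
#' rejected by the caller's filter.
#'
#' @param rmsdCa C-alpha RMSD in Angstrom (non-negative).
#' @param rmsdMax RMSD bound (default 3.0 Angstrom).
#' @return score in \[0, 1\].
#' @export
structureScore <- function(rmsdCa, rmsdMax = 3.0) {
  if (any(rmsdCa < 0)) stop("negative RMSD")
  pmax(0, 1 - rmsdCa / rmsdMax)
}

#' Score one cluster
#'
#' Combines the structure and sequence terms and applies the qualification
#' filters: C-alpha RMSD strictly below \code{rmsdMax} and sequence score
#' strictly above the per-metal theta.
#'
#' @param cluster a cluster from [clusterPairs()].
#' @param queryTriplets,templateTriplets its triplet sets.
#' @param params a [scoringParams()] list.
#' @param metal metal type used to pick theta (optional).
#' @return list: \code{rmsdCa, seqRaw, seqMax, sStr, sSeq, combined,
#'   passedFilters} plus the correspondence.
#' @export
scoreCluster <- function(cluster, queryTriplets, templateTriplets,
                         params = scoringParams(), metal = NULL) {
  rmsdCa <- clusterRMSD(cluster, queryTriplets, templateTriplets)
  sq <- seqScore(cluster)
  sStr <- structureScore(rmsdCa, params$rmsdMax)
  combined <- switch(params$combineMode,
                     product = sStr * sq$sSeq,
                     mean = (sStr + sq$sSeq) / 2)
  theta <- thetaFor(params, if (is.null(metal)) "" else metal)
  list(rmsdCa = rmsdCa, seqRaw = sq$seqRaw, seqMax = sq$seqMax,
       sStr = sStr, sSeq = sq$sSeq, combined = combined,
       passedFilters = (rmsdCa < params$rmsdMax) && (sq$sSeq > theta),
       corr = cluster$corr)
}

#' Accumulate qualifying cluster scores per residue
#'
#' @param chain the query [Chain-class].
#' @param clusterScores list of [scoreCluster()] results (across all
#'   templates); only those with \code{passedFilters} contribute.
#' @param aggregateMode \code{"sum"} (default) or \code{"max"}.
#' @return named numeric vector of raw scores, one per chain residue
#'   (0 for residues in no qualifying cluster).
#' @export
residueRawScores <- function(chain, clusterScores,
                             aggregateMode = c("sum", "max")) {
  aggregateMode <- match.arg(aggregateMode)
  rt <- residueTable(chain)
  raw <- stats::setNames(numeric(nrow(rt)), rt$ref)
  for (cs in clusterScores) {
    if (!isTRUE(cs$passedFilters)) next
    idx <- match(cs$corr$qRef, rt$ref)
    idx <- idx[!is.na(idx)]
    if (aggregateMode == "sum") raw[idx] <- raw[idx] + cs$combined
    else raw[idx] <- pmax(raw[idx], cs$combined)
  }
  raw
}

#' Z-normalize raw residue scores
#'
#' Centers and scales by the mean and population standard deviation over the
#' chain's residues; an all-constant vector yields all-zero z-scores.
#'
#' @param raw numeric vector of raw scores (length >= 2).
#' @return list with \code{raw, mean, sd, Z}.
#' @export
normalizeScores <- function(raw) {
  if (length(raw) < 2L) stop("need at least 2 residues to normalize")
  mu <- mean(raw)
  s <- sqrt(mean((raw - mu)^2))
  Z <- if (s > 0) (raw - mu) / s else raw * 0
  list(raw = raw, mean = mu, sd = s, Z = Z)
}
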