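#' Predict metal ion-binding residues of a query structure
#'
#' Scans every template of the requested metal (optionally excluding
#' templates derived from the query's own structure, the leave-one-out
#' rule), aligns the query to each by triplet transformation and
#' single-linkage clustering, scores qualifying aligned substructures, and
#' z-normalizes the accumulated per-residue scores chain by chain.  A
#' residue is called when its z-score reaches the threshold.
#'
#' @param query a [ProteinStructure-class], a [Chain-class], or a list of
#'   chains.
#' @param library a [TemplateLibrary-class].
#' @param metal metal type (CA, CU, FE, MG, MN or ZN).
#' @param params a [scoringParams()] list.
#' @param excludeSource leave-one-out flag: skip templates whose source
#'   structure id equals the query's (default FALSE).
#' @param threshold z-score call threshold; default is the per-metal value
#'   in \code{params$zThresholds}.
#' @return a [PredictionResult-class].
#' @export
predictBindingSites <- function(query, library, metal,
                                params = scoringParams(),
                                excludeSource = FALSE, threshold = NULL) {
  metal <- toupper(metal)
  stopifnot(metal %in% SUPPORTED_METALS)
  if (is(query, "ProteinStructure")) {
    queryId <- query@structureId
    chains <- extractPolypeptideChains(query, minLength = 1L)
  } else if (is(query, "Chain")) {
    queryId <- query@structureId
    chains <- list(query)
  } else {
    chains <- query
    queryId <- chains[[1L]]@structureId
  }
  if (is.null(threshold)) threshold <- zThresholdFor(params, metal)

  tpls <- Filter(function(t) t@metalType == metal, library@templates)
  nAll <- length(tpls)
  if (excludeSource)
    tpls <- Filter(function(t) t@sourceId != queryId, tpls)
  nExcl <- nAll - length(tpls)
  if (length(tpls) == 0L)
    warning("no templates of type ", metal, " to compare against (",
            nExcl, " excluded by leave-one-out)")

  rows <- list()
  for (ch in chains) {
    qt <- buildTriplets(ch)
    scores <- list()
    for (tpl in tpls) {
      tt <- tpl@triplets
      prs <- enumeratePairs(qt, tt, prefilter = params$prefilter)
      cls <- clusterPairs(prs, dC = params$dC,
                          minClusterSize = params$minClusterSize)
      for (cl in cls)
        scores[[length(scores) + 1L]] <-
          scoreCluster(cl, qt, tt, params, metal)
    }
    raw <- residueRawScores(ch, scores, params$aggregateMode)
    z <- normalizeScores(raw)
    rt <- residueTable(ch)
    rows[[length(rows) + 1L]] <- data.frame(
      chainId = rt$chainId, resNo = rt$resNo, insCode = rt$insCode,
      resName = rt$resName, ref = rt$ref, raw = unname(raw),
      Z = unname(z$Z), call = unname(z$Z >= threshold),
      stringsAsFactors = FALSE)
  }
  new("PredictionResult", queryId = queryId, metalType = metal,
      scores = do.call(rbind, rows), threshold = threshold,
      templatesCompared = length(tpls), templatesExcluded = as.integer(nExcl))
}

#' Write per-residue predictions as TSV
#'
#' @param result a [PredictionResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePrediction <- function(result, path) {
  utils::write.table(scoresTable(result), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Confusion counts of binary calls against truth
#'
#' @param calls,truth logical vectors of equal length.
#' @return list with \code{TP, TN, FP, FN}.
#' @export
confusionCounts <- function(calls, truth) {
  if (length(calls) != length(truth)) stop("length mismatch")
  calls <- as.logical(calls); truth <- as.logical(truth)
  list(TP = sum(calls & truth), TN = sum(!calls & !truth),
       FP = sum(calls & !truth), FN = sum(!calls & truth))
}

#' ACC / TPR / FPR from confusion counts
#'
#' TPR with zero positives (or FPR with zero negatives) is reported as NaN
#' with a warning, never silently as 0.
#'
#' @param cc a [confusionCounts()] list.
#' @return list with \code{ACC, TPR, FPR}.
#' @export
confusionMetrics <- function(cc) {
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  pos <- cc$TP + cc$FN; neg <- cc$TN + cc$FP
  if (pos == 0) warning("no positives: TPR undefined (NaN)")
  if (neg == 0) warning("no negatives: FPR undefined (NaN)")
  list(ACC = (cc$TP + cc$TN) / total,
       TPR = if (pos > 0) cc$TP / pos else NaN,
       FPR = if (neg > 0) cc$FP / neg else NaN)
}

#' ROC curve over z-score thresholds
#'
#' One point per distinct score (calls are \code{Z >= threshold}), framed by
#' (0,0) and (1,1); FPR and TPR are non-increasing as the threshold rises.
#'
#' @param Z numeric score vector.
#' @param truth logical truth vector (needs at least one positive and one
#'   negative).
#' @return data.frame with columns \code{threshold, FPR, TPR}, ordered by
#'   increasing FPR.
#' @export
rocCurve <- function(Z, truth) {
  truth <- as.logical(truth)
  if (length(Z) != length(truth)) stop("length mismatch")
  if (!any(truth) || all(truth))
    stop("degenerate truth: need at least one positive and one negative")
  pos <- sum(truth); neg <- sum(!truth)
  th <- sort(unique(Z), decreasing = TRUE)
  fpr <- tpr <- numeric(length(th))
  for (k in seq_along(th)) {
    calls <- Z >= th[k]
    tpr[k] <- sum(calls & truth) / pos
    fpr[k] <- sum(calls & !truth) / neg
  }
  pts <- data.frame(threshold = c(Inf, th, -Inf),
                    FPR = c(0, fpr, 1), TPR = c(0, tpr, 1))
  pts[!duplicated(pts[, c("FPR", "TPR")]), , drop = FALSE]
}

#' Area under a ROC curve
#'
#' Trapezoidal area of the [rocCurve()] step points.
#'
#' @param roc data.frame from [rocCurve()].
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(roc) {
  x <- roc$FPR; y <- roc$TPR
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Choose the calling threshold under an FPR budget
#'
#' The smallest threshold whose FPR does not exceed \code{maxFpr} (which,
#' FPR being monotone, maximizes TPR under the constraint).  Candidate
#' thresholds are the smallest score, the midpoints between consecutive
#' distinct scores, and one value above all scores.  When only the
#' call-nothing threshold qualifies, \code{+Inf} is returned with a warning.
#'
#' @param Z numeric score vector.
#' @param truth logical truth vector.
#' @param maxFpr FPR budget (default 0.05).
#' @return the threshold.
#' @export
chooseThreshold <- function(Z, truth, maxFpr = 0.05) {
  truth <- as.logical(truth)
  if (length(Z) != length(truth)) stop("length mismatch")
  if (!any(truth) || all(truth))
    stop("degenerate truth: need at least one positive and one negative")
  zs <- sort(unique(Z))
  cand <- c(zs[1L], if (length(zs) > 1L) (zs[-1L] + zs[-length(zs)]) / 2,
            zs[length(zs)] + 1)
  neg <- sum(!truth)
  for (t in cand) {
    calls <- Z >= t
    if (sum(calls & !truth) / neg <= maxFpr) {
      if (!any(calls)) {
        warning("FPR constraint only attainable by calling nothing; ",
                "returning +Inf")
        return(Inf)
      }
      return(t)
    }
  }
  warning("FPR constraint unattainable; returning +Inf")
  Inf
}

#' Leave-one-out evaluation of a template library
#'
#' For every metal type in the library, every input structure is predicted
#' with templates from its own structure excluded; truth labels are the
#' residues within the binding cutoff of any ion of that metal.  Z-scores
#' are pooled across structures per metal, the calling threshold is set so
#' that the pooled FPR does not exceed \code{targetFpr}, and confusion
#' metrics and the ROC/AUC are reported per metal plus micro-averaged
#' (pooled confusion counts) overall.
#'
#' @param structures list of [ProteinStructure-class] objects.
#' @param library a [TemplateLibrary-class] (default: built from
#'   \code{structures} with \code{params} settings).
#' @param params a [scoringParams()] list.
#' @param targetFpr FPR budget for threshold selection (default 0.05).
#' @param metals metals to evaluate (default: those present in the library).
#' @return an [EvalReport-class].
#' @export
evaluateLibrary <- function(structures, library = NULL,
                            params = scoringParams(), targetFpr = 0.05,
                            metals = NULL) {
  if (is.null(library))
    library <- buildLibrary(structures, cutoff = params$cutoff,
                            minLength = params$minLength)
  present <- unique(vapply(library@templates, function(t) t@metalType,
                           character(1)))
  if (is.null(metals)) metals <- present
  perMetal <- list(); rocs <- list()
  pooled <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  cnt <- templateCounts(library)
  for (m in metals) {
    Zs <- numeric(0); truths <- logical(0)
    for (s in structures) {
      chains <- extractPolypeptideChains(s, minLength = params$minLength)
      if (!length(chains)) next
      ions <- identifyMetalIons(s, m)
      pred <- predictBindingSites(chains, library, m, params,
                                  excludeSource = TRUE)
      tab <- scoresTable(pred)
      truth <- rep(FALSE, nrow(tab))
      if (nrow(ions)) {
        for (k in seq_len(nrow(ions))) {
          b <- findBindingResidues(chains, ions[k, , drop = FALSE],
                                   params$cutoff)
          truth <- truth | tab$ref %in% b$ref
        }
      }
      Zs <- c(Zs, tab$Z); truths <- c(truths, truth)
    }
    roc <- rocCurve(Zs, truths)
    thr <- chooseThreshold(Zs, truths, targetFpr)
    cc <- confusionCounts(Zs >= thr, truths)
    met <- confusionMetrics(cc)
    pooled <- Map(`+`, pooled, cc)
    perMetal[[m]] <- data.frame(
      metal = m, nTemplates = cnt[[m]], threshold = thr,
      TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
      ACC = met$ACC, TPR = met$TPR, FPR = met$FPR, AUC = rocAUC(roc),
      stringsAsFactors = FALSE)
    rocs[[m]] <- roc
  }
  new("EvalReport", perMetal = do.call(rbind, unname(perMetal)),
      overall = c(pooled, confusionMetrics(pooled)), roc = rocs)
}

#' Write an evaluation report as TSV (+ per-metal ROC TSVs)
#'
#' @param report an [EvalReport-class].
#' @param path output TSV for the per-metal table; ROC tables are written
#'   next to it as \code{<path>.roc.<METAL>.tsv}.
#' @return the path, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  utils::write.table(report@perMetal, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  for (m in names(report@roc))
    utils::write.table(report@roc[[m]], paste0(path, ".roc.", m, ".tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
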