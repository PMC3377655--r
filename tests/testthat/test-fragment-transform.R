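test_that("triplets follow chain order and require complete N/CA/C", {
  ch <- makeBackbone(10, "helix", seed = 2)
  tr <- buildTriplets(ch)
  expect_equal(MetalSiteFinder:::tripletCount(tr), 10L)
  expect_equal(tr$refs, paste0("A:", 1:10, ":"))

  a <- atomTable(ch)
  res4 <- a[a$resNo == 4, ]
  for (k in seq_len(nrow(res4)))
    if (res4$atomName[k] %in% c("N", "CA", "C")) {
      want <- as.numeric(res4[k, c("x", "y", "z")])
      row <- match(res4$atomName[k], c("N", "CA", "C"))
      expect_equal(unname(tr$coords[, row, 4]), want)
    }

  ch2 <- ch
  ch2@atoms <- a[!(a$resNo == 7 & a$atomName == "C"), ]
  expect_equal(MetalSiteFinder:::tripletCount(buildTriplets(ch2)), 9L)
})

test_that("triplet superposition recovers exact rigid relations", {
  tr <- buildTriplets(makeBackbone(3, "strand", seed = 4))
  M <- tr$coords[, , 1]

  selfFit <- superposeTriplet(M, M)
  expect_lt(selfFit$fitRmsd, 1e-8)
  expect_equal(selfFit$transform@rotation, diag(3), tolerance = 1e-8)
  expect_equal(selfFit$transform@translation, c(0, 0, 0), tolerance = 1e-8)

  shifted <- M + c(1, 2, 3)  # column-recycled: adds (1,2,3) to each point
  fit <- superposeTriplet(M, shifted)
  expect_lt(fit$fitRmsd, 1e-8)
  expect_equal(fit$transform@translation, c(1, 2, 3), tolerance = 1e-8)

  collinear <- matrix(c(0, 1, 2, 0, 1, 2, 0, 1, 2), 3, 3, byrow = TRUE)
  expect_error(superposeTriplet(collinear, M), "collinear")
})

test_that("Kabsch residuals match the quaternion closed form on random pairs", {
  set.seed(99)
  for (rep in 1:100) {
    P <- matrix(rnorm(9, sd = 2), 3, 3)
    Q <- matrix(rnorm(9, sd = 2), 3, 3)
    if (MetalSiteFinder:::tripletArea(t(P)) < 0.05 ||
        MetalSiteFinder:::tripletArea(t(Q)) < 0.05) next
    fit <- superposeTriplet(t(P), t(Q))
    expect_lt(abs(fit$fitRmsd - quatRmsd(P, Q)), 1e-6)
  }
})

test_that("Kabsch is optimal against random rigid alternatives", {
  set.seed(17)
  P <- matrix(rnorm(9, sd = 2), 3, 3)
  Q <- matrix(rnorm(9, sd = 2), 3, 3)
  best <- superposeTriplet(t(P), t(Q))$fitRmsd
  for (k in 1:500) {
    R <- randomRotationMatrix()
    tr <- rnorm(3, sd = 3)
    moved <- P %*% t(R) + rep(tr, each = 3)
    expect_gte(sqrt(mean(rowSums((moved - Q)^2))) + 1e-12, best)
  }
})

test_that("pair distance equals direct apply-then-RMSD arithmetic", {
  set.seed(21)
  qt <- randomTripletSet(4, seed = 21)
  tt <- randomTripletSet(3, seed = 22)
  prs <- enumeratePairs(qt, tt)
  for (p in seq_along(prs$i)) {
    M <- rigidTransform(prs$rot[, , p], prs$trans[p, ])
    # self distance equals the stored fit residual
    expect_equal(pairDistance(M, qt$coords[, , prs$i[p]],
                              tt$coords[, , prs$j[p]]),
                 prs$fitRmsd[p], tolerance = 1e-9)
    # cross distances equal explicit arithmetic
    sig <- qt$coords[, , (prs$i[p] %% 4) + 1]
    tau <- tt$coords[, , (prs$j[p] %% 3) + 1]
    moved <- M@rotation %*% sig + M@translation
    expect_equal(pairDistance(M, sig, tau),
                 sqrt(mean(colSums((moved - tau)^2))), tolerance = 1e-12)
  }
})

test_that("pair enumeration spans the full m x n matrix", {
  qt <- randomTripletSet(5, seed = 31)
  tt <- randomTripletSet(4, seed = 32)
  expect_equal(length(enumeratePairs(qt, tt)$i), 20L)
  empty <- randomTripletSet(0, seed = 33)
  expect_equal(length(enumeratePairs(empty, tt)$i), 0L)

  # prefilter keeps all same-residue pairs (self BLOSUM62 scores are >= 4)
  qt2 <- qt; qt2$resNames <- rep("CYS", 5); qt2$aa <- rep("C", 5)
  tt2 <- tt; tt2$resNames <- rep("CYS", 4); tt2$aa <- rep("C", 4)
  expect_equal(length(enumeratePairs(qt2, tt2, prefilter = TRUE)$i), 20L)
})

test_that("an exact rigid copy of a site clusters into the identity correspondence", {
  st <- smallSiteStructure(n = 30, indices = c(5L, 6L, 9L))
  lib <- buildLibrary(list(st), minLength = 30)
  tpl <- templates(lib)[[1]]
  moved <- rigidMove(st, randomRigidTransform(8))
  qt <- buildTriplets(firstChain(moved))
  cls <- clusterPairs(enumeratePairs(qt, tpl@triplets))
  # the site must come back as one cluster with the identity mapping
  hit <- Filter(function(cl) all(c("A:5:", "A:6:", "A:9:") %in% cl$corr$qRef),
                cls)
  expect_equal(length(hit), 1L)
  sub <- alignedSubstructure(hit[[1]])
  expect_equal(length(sub$query), length(sub$template))
  onSite <- sub$template %in% c("A:5:", "A:6:", "A:9:")
  expect_equal(sub$query[onSite], sub$template[onSite])
  expect_lt(max(hit[[1]]$corr$fitRmsd), 1e-6)
})

test_that("two sites related by different rigid motions give two clusters", {
  st <- smallSiteStructure(n = 30, indices = c(5L, 6L, 9L))
  lib <- buildLibrary(list(st), minLength = 30)
  tpl <- templates(lib)[[1]]
  site <- tpl@atoms
  # query = two copies of the site fragment under different motions
  m1 <- randomRigidTransform(41); m2 <- randomRigidTransform(42)
  c1 <- site; c1[, c("x","y","z")] <- applyTransform(m1, as.matrix(site[, c("x","y","z")]))
  c2 <- site; c2[, c("x","y","z")] <- applyTransform(m2, as.matrix(site[, c("x","y","z")]))
  c2$resNo <- c2$resNo + 100L
  qt <- buildTriplets(rbind(c1, c2))
  cls <- clusterPairs(enumeratePairs(qt, tpl@triplets))
  expect_equal(length(cls), 2L)
  expect_true(all(vapply(cls, function(cl) nrow(cl$corr), 0L) == 3L))
})

test_that("clustering equals connected components of the compatibility graph", {
  skip_if_not_installed("igraph")
  for (case in 1:10) {
    qt <- randomTripletSet(4, seed = 100 + case)
    tt <- randomTripletSet(5, seed = 200 + case)
    prs <- enumeratePairs(qt, tt)
    dC <- 6.0
    P <- length(prs$i)
    adj <- matrix(FALSE, P, P)
    for (p in 1:P) for (q in 1:P) {
      Mp <- rigidTransform(prs$rot[, , p], prs$trans[p, ])
      Mq <- rigidTransform(prs$rot[, , q], prs$trans[q, ])
      adj[p, q] <- pairDistance(Mp, qt$coords[, , prs$i[q]],
                                tt$coords[, , prs$j[q]]) <= dC &&
                   pairDistance(Mq, qt$coords[, , prs$i[p]],
                                tt$coords[, , prs$j[p]]) <= dC
    }
    want <- sort(vapply(igraphComponents(adj), paste, "", collapse = ","))
    got <- clusterPairs(prs, dC = dC, minClusterSize = 1L)
    gotComps <- sort(vapply(got, function(cl)
      paste(sort(cl$pairIdx), collapse = ","), ""))
    expect_equal(gotComps, want)
  }
})

test_that("shared query or template residues resolve by smallest residual", {
  qt <- randomTripletSet(3, seed = 61)
  tt <- randomTripletSet(3, seed = 62)
  # pairs (1,1) fit 0.5, (1,2) fit 0.2, (2,2) fit 0.3, (3,3) fit 0.1
  prs <- manualPairSet(i = c(1L, 1L, 2L, 3L), j = c(1L, 2L, 2L, 3L),
                       fit = c(0.5, 0.2, 0.3, 0.1), qt, tt)
  corr <- MetalSiteFinder:::oneToOne(prs, 1:4)
  # (1,2) beats (1,1) and blocks (2,2) on template 2
  expect_equal(corr$qIdx, c(1L, 3L))
  expect_equal(corr$tIdx, c(2L, 3L))
})

test_that("alignment geometry is invariant under rigid motion of the query", {
  st <- smallSiteStructure(n = 25, indices = c(5L, 6L, 9L))
  lib <- buildLibrary(list(st), minLength = 20)
  tpl <- templates(lib)[[1]]
  qt0 <- buildTriplets(firstChain(st))
  prs0 <- enumeratePairs(qt0, tpl@triplets)
  cls0 <- clusterPairs(prs0)
  part0 <- lapply(cls0, function(cl) cl$corr[, c("qRef", "tRef")])
  for (s in 1:5) {
    moved <- rigidMove(st, randomRigidTransform(700 + s))
    qt <- buildTriplets(firstChain(moved))
    prs <- enumeratePairs(qt, tpl@triplets)
    expect_lt(max(abs(prs$fitRmsd - prs0$fitRmsd)), 1e-6)
    cls <- clusterPairs(prs)
    part <- lapply(cls, function(cl) cl$corr[, c("qRef", "tRef")])
    expect_equal(part, part0, ignore_attr = TRUE)
  }
})

test_that("cluster partition does not depend on pair input order", {
  qt <- randomTripletSet(5, seed = 71)
  tt <- randomTripletSet(4, seed = 72)
  prs <- enumeratePairs(qt, tt)
  set.seed(3)
  perm <- sample(length(prs$i))
  prs2 <- list(i = prs$i[perm], j = prs$j[perm],
               fitRmsd = prs$fitRmsd[perm],
               rot = prs$rot[, , perm, drop = FALSE],
               trans = prs$trans[perm, , drop = FALSE],
               query = prs$query, template = prs$template)
  norm <- function(cls) {
    parts <- lapply(cls, function(cl)
      paste(sort(paste(cl$corr$qRef, cl$corr$tRef)), collapse = ";"))
    sort(unlist(parts))
  }
  expect_equal(norm(clusterPairs(prs2, dC = 6, minClusterSize = 1L)),
               norm(clusterPairs(prs, dC = 6, minClusterSize = 1L)))
})
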