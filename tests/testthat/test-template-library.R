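test_that("binding cutoff is a closed 3.5 A ball around the metal center", {
  ch <- makeBackbone(10, "strand", seed = 1)
  a <- atomTable(ch)
  # place the metal 3.4 A from residue 2's CA along +z, far from everything else
  ca2 <- as.numeric(a[a$resNo == 2 & a$atomName == "CA", c("x", "y", "z")])
  mkMetal <- function(dz) data.frame(metalType = "ZN", x = ca2[1], y = ca2[2],
                                     z = ca2[3] + dz, sourceId = "T:A:9:ZN")
  near <- findBindingResidues(ch, mkMetal(3.4))
  expect_true("A:2:" %in% near$ref)
  far <- findBindingResidues(ch, mkMetal(33))
  expect_false("A:2:" %in% far$ref)
  # exact boundary is included
  onEdge <- findBindingResidues(ch, mkMetal(3.5))
  expect_true("A:2:" %in% onEdge$ref)
})

test_that("a planted site yields exactly its residues (brute-force oracle)", {
  st <- smallSiteStructure(n = 30, indices = c(5L, 6L, 9L))
  ch <- firstChain(st)
  m <- metalIons(st)
  b <- findBindingResidues(ch, m[1, ])
  expect_setequal(b$resNo, c(5L, 6L, 9L))
  oracle <- bruteForceBinding(ch, c(m$x[1], m$y[1], m$z[1]))
  expect_setequal(b$ref, oracle)
  expect_true(all(b$minDist <= 3.5))
})

test_that("template rule: more than two binding residues, complete backbones", {
  st <- smallSiteStructure(n = 30, indices = c(5L, 6L, 9L))
  ch <- firstChain(st)
  m <- metalIons(st)[1, ]
  b <- findBindingResidues(ch, m)

  tpl <- buildTemplate(m, b, ch)
  expect_s4_class(tpl, "MetalSiteTemplate")
  expect_equal(nrow(bindingResidues(tpl)), 3L)

  rej <- buildTemplate(m, b[1:2, ], ch)
  expect_true(isRejected(rej))
  expect_match(rej$reason, "binding residue")

  # drop residue 5's carbonyl C: its triplet cannot be built
  ch2 <- ch
  ch2@atoms <- ch2@atoms[!(ch2@atoms$resNo == 5 & ch2@atoms$atomName == "C"), ]
  rej2 <- buildTemplate(m, b, ch2)
  expect_true(isRejected(rej2))
  expect_match(rej2$reason, "backbone")
})

test_that("each metal ion of a structure contributes its own template", {
  st <- smallSiteStructure(n = 60, indices = c(5L, 6L, 9L))
  st <- plantMetalSite(st, "FE", c(30L, 33L, 36L, 39L))
  lib <- buildLibrary(list(st), minLength = 51)
  expect_equal(length(templates(lib)), 2L)
  cnt <- templateCounts(lib)
  expect_equal(cnt[["ZN"]], 1L)
  expect_equal(cnt[["FE"]], 1L)
})

test_that("library building drops undersized sites and scales with input", {
  sts <- lapply(1:3, function(s)
    MetalSiteFinder:::renameStructure(
      smallSiteStructure(n = 60, seed = s), sprintf("S%03d", s)))
  lib <- buildLibrary(sts, minLength = 51)
  expect_equal(length(templates(lib)), 3L)
  ids <- vapply(templates(lib), function(t) t@templateId, "")
  expect_false(anyDuplicated(ids) > 0)

  # a 2-residue shell never becomes a template: pull one binder out of range
  st <- sts[[1]]
  drop <- st@atoms$resNo == 9
  st@atoms[drop, c("x", "y", "z")] <- st@atoms[drop, c("x", "y", "z")] + 50
  expect_equal(length(templates(buildLibrary(list(st), minLength = 51))), 0L)

  expect_warning(empty <- buildLibrary(list()), "no input")
  expect_equal(length(templates(empty)), 0L)
})

test_that("every stored template residue is within the cutoff of its metal", {
  bench <- makeBenchmark(nStructures = 3, nResidues = 60, seed = 11)
  lib <- buildLibrary(bench$structures, minLength = 51)
  for (tpl in templates(lib)) {
    ca <- MetalSiteFinder:::contactAtoms(tpl)
    expect_true(all(ca$minDist <= 3.5))
    expect_setequal(ca$ref, bindingResidues(tpl)$ref)
  }
})

test_that("identity clustering is single-linkage with first-entry representatives", {
  # identical sequences collapse to the first; unrelated ones stay apart
  s1 <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  s2 <- "WWGPPHHEEDDNNCCLLIIVVFFYYRRKKSSTT"
  reps <- clusterByIdentity(c(a = s1, b = s1, c = s2))
  expect_equal(reps, c("a", "c"), ignore_attr = TRUE)
  expect_true(list(c("a", "b")) %in% attr(reps, "clusters") ||
                any(vapply(attr(reps, "clusters"), function(cl)
                  setequal(cl, c("a", "b")), TRUE)))

  # transitive closure against an independently built identity graph
  set.seed(5)
  seqs <- c(a = s1,
            b = paste0(substr(s1, 1, 16),
                       paste(sample(c("G","P","W"), 17, TRUE), collapse = "")),
            c = s2,
            d = paste0(substr(s2, 1, 14),
                       paste(sample(c("A","Q","E"), 19, TRUE), collapse = "")))
  B <- MetalSiteFinder:::blosumMatrix()
  n <- length(seqs)
  adj <- diag(n) > 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
      substitutionMatrix = B, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    adj[i, j] <- adj[j, i] <- Biostrings::pid(pa, type = "PID1") / 100 >= 0.25
  }
  skip_if_not_installed("igraph")
  comps <- igraphComponents(adj)
  wantReps <- sort(vapply(comps, min, integer(1)))
  expect_equal(clusterByIdentity(seqs), names(seqs)[wantReps],
               ignore_attr = TRUE)
})

test_that("composition profiles are normalized frequencies with correct contacts", {
  st <- smallSiteStructure(n = 60, indices = c(5L, 6L, 9L))  # CYS,CYS,HIS
  lib <- buildLibrary(list(st), minLength = 51)
  prof <- compositionProfile(lib)
  r <- prof$residues
  expect_equal(r$freq[r$resName == "CYS"], 2 / 3)
  expect_equal(r$freq[r$resName == "HIS"], 1 / 3)
  expect_equal(sum(r$freq), 1, tolerance = 1e-12)
  a <- prof$atoms
  expect_equal(sum(a$freq), 1, tolerance = 1e-12)

  # contact atoms match a brute-force nearest-atom scan
  tpl <- templates(lib)[[1]]
  atoms <- atomTable(tpl)
  mc <- tpl@metalCoords
  got <- MetalSiteFinder:::contactAtoms(tpl)
  for (k in seq_len(nrow(got))) {
    sel <- atoms[MetalSiteFinder:::residueRef(atoms$chainId, atoms$resNo,
                                              atoms$insCode) == got$ref[k], ]
    d <- sqrt((sel$x - mc[1])^2 + (sel$y - mc[2])^2 + (sel$z - mc[3])^2)
    expect_equal(got$contactAtom[k], sel$atomName[which.min(d)])
  }
  emptyLib <- suppressWarnings(buildLibrary(list(), minLength = 51))
  expect_error(compositionProfile(emptyLib), "empty")
})

test_that("library JSON serialization round-trips", {
  bench <- makeBenchmark(nStructures = 2, nResidues = 60, seed = 13)
  lib <- buildLibrary(bench$structures, minLength = 51)
  path <- tempfile(fileext = ".json")
  writeTemplateLibrary(lib, path)
  lib2 <- readTemplateLibrary(path)
  expect_equal(length(templates(lib2)), length(templates(lib)))
  for (k in seq_along(templates(lib))) {
    t1 <- templates(lib)[[k]]; t2 <- templates(lib2)[[k]]
    expect_equal(t2@templateId, t1@templateId)
    expect_equal(t2@metalType, t1@metalType)
    expect_equal(t2@metalCoords, t1@metalCoords, tolerance = 1e-3)
    expect_equal(t2@residues$ref, t1@residues$ref)
    expect_equal(as.matrix(t2@atoms[, c("x","y","z")]),
                 as.matrix(t1@atoms[, c("x","y","z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(MetalSiteFinder:::tripletCount(t2@triplets),
                 MetalSiteFinder:::tripletCount(t1@triplets))
  }
})
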