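# Independent oracles used across the suite; none of these share code with
# the implementation paths they check.

# Horn's closed-form quaternion superposition: optimal RMSD from the largest
# eigenvalue of the 4x4 key matrix, no rotation ever constructed
quatRmsd <- function(P, Q) {
  n <- nrow(P)
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(P0, Q0)
  K <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[3,1] + S[1,3],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[3,1] + S[1,3], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(P0^2) + sum(Q0^2) - 2 * lmax) / n)
}

# connected components of a logical adjacency matrix via igraph
igraphComponents <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cm <- igraph::components(g)$membership
  unname(lapply(split(seq_along(cm), cm), sort))
}

# brute-force binding-residue scan: plain double loop over residues/atoms
bruteForceBinding <- function(chain, metalXYZ, cutoff = 3.5) {
  a <- atomTable(chain)
  key <- paste(a$chainId, a$resNo, a$insCode, sep = ":")
  hits <- character(0)
  for (r in unique(key)) {
    sel <- a[key == r, , drop = FALSE]
    dmin <- Inf
    for (i in seq_len(nrow(sel))) {
      d <- sqrt(sum((c(sel$x[i], sel$y[i], sel$z[i]) - metalXYZ)^2))
      dmin <- min(dmin, d)
    }
    if (dmin <= cutoff) hits <- c(hits, r)
  }
  hits
}

randomTripletSet <- function(n, seed, spread = 8) {
  set.seed(seed)
  coords <- array(NA_real_, dim = c(3, 3, n))
  for (k in seq_len(n)) {
    center <- runif(3, -spread, spread)
    repeat {
      M <- matrix(rnorm(9, sd = 1.2), 3, 3) + center
      v1 <- M[, 2] - M[, 1]; v2 <- M[, 3] - M[, 1]
      cr <- c(v1[2]*v2[3]-v1[3]*v2[2], v1[3]*v2[1]-v1[1]*v2[3],
              v1[1]*v2[2]-v1[2]*v2[1])
      if (0.5 * sqrt(sum(cr^2)) > 0.1) break
    }
    coords[, , k] <- M
  }
  res <- sample(c("ALA","CYS","HIS","GLY","ASP"), n, replace = TRUE)
  list(refs = paste0("A:", seq_len(n), ":"), resNames = res,
       aa = vapply(res, function(r) c(ALA="A",CYS="C",HIS="H",GLY="G",ASP="D")[[r]], ""),
       coords = coords)
}

randomRotationMatrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
           2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}
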