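# Independent oracles used to validate the clique enumerator and the Kabsch
# superposition, plus small fixture builders shared across test files.

# --- exhaustive maximal-clique oracle (bitmask subset enumeration, n <= 15) --

bruteMaximalCliques <- function(adj, minSize = 1L) {
  n <- nrow(adj)
  stopifnot(n <= 15)
  if (n == 0) return(list())
  nbrmask <- vapply(seq_len(n), function(v)
    sum(bitwShiftL(1L, which(adj[v, ]) - 1L)), integer(1))
  total <- bitwShiftL(1L, n)
  isclique <- logical(total)          # index s+1 <-> subset s
  isclique[1] <- TRUE                 # empty set
  lowbit <- function(s) bitwAnd(s, -s)
  cliques <- list()
  for (s in 1:(total - 1L)) {
    lb <- lowbit(s)
    v <- as.integer(log2(lb)) + 1L
    rest <- s - lb
    isclique[s + 1L] <- isclique[rest + 1L] &&
      bitwAnd(nbrmask[v], rest) == rest
    if (!isclique[s + 1L]) next
    # maximal iff no outside vertex is adjacent to all members
    maximal <- TRUE
    for (w in seq_len(n)) {
      wb <- bitwShiftL(1L, w - 1L)
      if (bitwAnd(s, wb) == 0L && bitwAnd(nbrmask[w], s) == s) {
        maximal <- FALSE
        break
      }
    }
    if (maximal) {
      members <- which(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
      if (length(members) >= minSize)
        cliques[[length(cliques) + 1L]] <- members
    }
  }
  cliques
}

# canonical string form of a clique set, for set equality checks
cliqueSetKey <- function(cliques) {
  sort(vapply(cliques, function(cl)
    paste(sort(cl), collapse = ","), character(1)))
}

# wrap an arbitrary adjacency matrix as an AssociationGraph whose vertex v is
# the pair (v, v): no two vertices share an index, so any adjacency is legal
graphFromAdjacency <- function(adj) {
  n <- nrow(adj)
  dimnames(adj) <- NULL
  new("AssociationGraph",
      vertices = cbind(t = seq_len(n), q = seq_len(n)),
      adjacency = adj, params = list(templateId = "synthetic"))
}

randomAdjacency <- function(n, p = 0.4) {
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    up <- which(upper.tri(adj))
    adj[up] <- stats::runif(length(up)) < p
    adj <- adj | t(adj)
  }
  adj
}

# cliques from findMaxCliques on a synthetic graph, as vertex index sets
enumeratedCliqueSets <- function(adj, minSize = 1L) {
  cls <- findMaxCliques(graphFromAdjacency(adj), minCliqueSize = minSize)
  lapply(cls, function(cl) sort(cl$pairs[, 1]))
}

# --- rotation-grid RMSD oracle ----------------------------------------------

.eulerRotation <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cc, sc, 0, -sc, cc), 3, 3)
  Rz %*% Ry %*% Rx
}

# brute-force minimum RMSD over rotations: coarse Euler grid followed by
# local grid refinement (translation is optimal at centroid alignment for
# any rotation, so only rotations are searched)
gridSearchRmsd <- function(fixed, moving, levels = 6L, steps = 13L) {
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(fixed, 2, colMeans(fixed))
  rmsdAt <- function(a, b, c) {
    R <- .eulerRotation(a, b, c)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  centre <- c(0, 0, 0)
  span <- c(pi, pi / 2, pi)
  best <- Inf
  for (lev in seq_len(levels)) {
    as <- seq(centre[1] - span[1], centre[1] + span[1], length.out = steps)
    bs <- seq(centre[2] - span[2], centre[2] + span[2], length.out = steps)
    cs <- seq(centre[3] - span[3], centre[3] + span[3], length.out = steps)
    for (a in as) for (b in bs) for (c in cs) {
      r <- rmsdAt(a, b, c)
      if (r < best) {
        best <- r
        centre <- c(a, b, c)
      }
    }
    span <- span / 4
  }
  best
}

randomRotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3))) -> Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# --- structure fixtures ------------------------------------------------------

# synthetic holo file: nNear residues ~3 A from a one-atom ligand at the
# origin, nFar residues ~12 A away; returns the path
makeHoloFixture <- function(path, ligCode = "XLG", nNear = 5L, nFar = 5L,
                            nearDist = 3.0, farDist = 12.0, seed = 1L,
                            extraLigandAt = NULL) {
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * (nNear + nFar)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ca <- dirs * c(rep(nearDist, nNear), rep(farDist, nFar))
  sc <- ca * 1.2
  res <- data.frame(chain = "A", resno = seq_len(nNear + nFar), ins = "",
                    aa = rep(c("ALA", "LEU", "SER", "PHE", "LYS"),
                             length.out = nNear + nFar),
                    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                    sc_x = sc[, 1], sc_y = sc[, 2], sc_z = sc[, 3],
                    stringsAsFactors = FALSE)
  het <- data.frame(code = ligCode, chain = "L", resno = 1L, elety = "P1",
                    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  if (!is.null(extraLigandAt))
    het <- rbind(het, data.frame(code = ligCode, chain = "L", resno = 2L,
                                 elety = "P1", x = extraLigandAt[1],
                                 y = extraLigandAt[2], z = extraLigandAt[3],
                                 stringsAsFactors = FALSE))
  writePdbFixture(res, path, het = het)
  path
}
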