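# Association-graph construction and maximal-clique matching.

test_that("a template self-matches as an identity clique", {
  fx <- generatePlantedStructure(6, noiseSigma = 0, nDecoyResidues = 0,
                                 seed = 21)
  g <- buildAssociationGraph(fx$template, fx$query)
  cls <- findMaxCliques(g, minCliqueSize = 3)
  expect_gte(length(cls), 1)
  expect_equal(cls[[1]]$size, 6L)
  # identity correspondence is among the vertices of the top clique
  expect_true(all(cls[[1]]$pairs[, 1] %in% 1:6))
})

test_that("no compatible residue types means zero vertices", {
  res <- data.frame(chain = "A", resno = 1:3, ins = "", aa = "TRP",
                    ca_x = c(0, 4, 0), ca_y = c(0, 0, 4), ca_z = 0,
                    sc_x = c(1, 5, 1), sc_y = c(0, 0, 4), sc_z = 1,
                    stringsAsFactors = FALSE)
  tmpl <- SiteTemplate("w3", res, ligandCode = "LIG")
  qres <- res; qres$aa <- "ALA"
  g <- buildAssociationGraph(tmpl, QueryStructure("q", qres))
  expect_equal(nrow(g@vertices), 0L)
  expect_length(findMaxCliques(g), 0)
})

test_that("edges agree with a brute-force pairwise checker", {
  set.seed(22)
  fx <- generatePlantedStructure(4, noiseSigma = 0.2, nDecoyResidues = 2,
                                 seed = 22)
  tol <- 1.5
  g <- buildAssociationGraph(fx$template, fx$query, distTol = tol)
  tres <- residues(fx$template); qres <- residues(fx$query)
  dmat <- function(df, cols) as.matrix(dist(as.matrix(df[, cols])))
  Dtca <- dmat(tres, 5:7); Dtsc <- dmat(tres, 8:10)
  Dqca <- dmat(qres, 5:7); Dqsc <- dmat(qres, 8:10)
  v <- g@vertices
  for (a in seq_len(nrow(v))) for (b in seq_len(nrow(v))) {
    i <- v[a, 1]; j <- v[a, 2]; k <- v[b, 1]; l <- v[b, 2]
    want <- i != k && j != l &&
      abs(Dtca[i, k] - Dqca[j, l]) <= tol &&
      abs(Dtsc[i, k] - Dqsc[j, l]) <= tol
    expect_identical(g@adjacency[a, b], want)
  }
})

test_that("edge test is symmetric and monotone in the tolerance", {
  fx <- generatePlantedStructure(5, noiseSigma = 0.4, nDecoyResidues = 5,
                                 seed = 23)
  g1 <- buildAssociationGraph(fx$template, fx$query, distTol = 0.8)
  g2 <- buildAssociationGraph(fx$template, fx$query, distTol = 2.0)
  expect_identical(g1@adjacency, t(g1@adjacency))
  # widening the tolerance can only add edges
  expect_true(all(g2@adjacency[g1@adjacency]))
})

test_that("hand-built graphs give the expected maximal cliques", {
  # complete graph on 5 vertices -> a single clique of size 5
  k5 <- matrix(TRUE, 5, 5); diag(k5) <- FALSE
  cls <- enumeratedCliqueSets(k5, minSize = 3)
  expect_equal(cls, list(1:5))
  # two disjoint triangles -> exactly two cliques of size 3
  tri2 <- matrix(FALSE, 6, 6)
  tri2[1:3, 1:3] <- TRUE; tri2[4:6, 4:6] <- TRUE; diag(tri2) <- FALSE
  cls <- enumeratedCliqueSets(tri2, minSize = 3)
  expect_equal(cliqueSetKey(cls), c("1,2,3", "4,5,6"))
})

test_that("clique enumeration equals the exhaustive oracle on random graphs", {
  set.seed(24)
  for (i in 1:50) {
    n <- sample(2:15, 1)
    adj <- randomAdjacency(n, 0.4)
    got <- cliqueSetKey(enumeratedCliqueSets(adj, minSize = 1))
    want <- cliqueSetKey(bruteMaximalCliques(adj, minSize = 1))
    expect_identical(got, want)
  }
})

test_that("clique enumeration agrees with igraph as a second, independent check", {
  skip_if_not_installed("igraph")
  set.seed(25)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    adj <- randomAdjacency(n, 0.5)
    got <- cliqueSetKey(enumeratedCliqueSets(adj, minSize = 1))
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    want <- cliqueSetKey(lapply(igraph::max_cliques(ig), as.integer))
    expect_identical(got, want)
  }
})

test_that("results are deterministically ordered and truncatable", {
  set.seed(26)
  adj <- randomAdjacency(12, 0.5)
  g <- graphFromAdjacency(adj)
  all_cls <- findMaxCliques(g, minCliqueSize = 1)
  sizes <- vapply(all_cls, `[[`, integer(1), "size")
  expect_true(all(diff(sizes) <= 0))
  expect_identical(findMaxCliques(g, minCliqueSize = 1, maxResults = 3),
                   all_cls[1:3])
  # re-running gives the identical list
  expect_identical(findMaxCliques(g, minCliqueSize = 1), all_cls)
})

test_that("the edge budget trips loudly and the template is reported skipped", {
  k <- matrix(TRUE, 10, 10); diag(k) <- FALSE
  g <- graphFromAdjacency(k)
  expect_error(findMaxCliques(g, edgeBudget = 10),
               class = "cliquesite_budget_exceeded")
  fx <- generatePlantedStructure(5, noiseSigma = 0, nDecoyResidues = 10,
                                 seed = 27)
  recs <- matchTemplate(fx$template, fx$query, edgeBudget = 1)
  expect_length(recs, 0)
  expect_true(attr(recs, "skipped"))
})

test_that("self-match identity holds for generated templates", {
  for (seed in 28:32) {
    n <- 4 + (seed %% 4)
    fx <- generatePlantedStructure(n, noiseSigma = 0, nDecoyResidues = 0,
                                   seed = seed)
    recs <- matchTemplate(fx$template, fx$query)
    expect_gte(length(recs), 1)
    expect_equal(recs[[1]]@cliqueSize, n)
    expect_lt(recs[[1]]@rmsd, 1e-6)
  }
})

test_that("a single-chain site is found identically with or without interface mode", {
  fx <- generatePlantedStructure(5, noiseSigma = 0.2, nDecoyResidues = 20,
                                 seed = 33)
  q <- fx$query
  off <- matchTemplate(fx$template, q, interfaceMode = FALSE)
  on <- matchTemplate(fx$template, q, interfaceMode = TRUE)
  expect_equal(length(off), length(on))
  expect_equal(off[[1]]@pairs, on[[1]]@pairs)
  expect_equal(off[[1]]@rmsd, on[[1]]@rmsd)
})

test_that("a site split across chains needs interface mode", {
  fx <- generatePlantedStructure(5, noiseSigma = 0.2, nDecoyResidues = 20,
                                 splitAcrossChains = c(3, 2), seed = 34)
  off <- matchTemplate(fx$template, fx$query, minCliqueSize = 5,
                       interfaceMode = FALSE)
  on <- matchTemplate(fx$template, fx$query, minCliqueSize = 5,
                      interfaceMode = TRUE)
  expect_length(off, 0)
  expect_gte(length(on), 1)
  expect_setequal(on[[1]]@spansChains, c("A", "B"))
})

test_that("unrelated decoy structures rarely match below 2 A", {
  hits <- 0L
  for (seed in 1:100) {
    fx <- generatePlantedStructure(5, noiseSigma = 0, nDecoyResidues = 0,
                                   seed = 1000 + seed)
    decoy <- generatePlantedStructure(5, noiseSigma = 0, nDecoyResidues = 0,
                                      seed = 2000 + seed)
    recs <- matchTemplate(fx$template, decoy$query, rmsdCutoff = 2.0)
    if (length(recs) > 0) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})
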