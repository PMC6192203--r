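# Fingerprints, Tanimoto similarity and Butina clustering.

test_that("fingerprints are deterministic and flag invalid input", {
  expect_identical(ligandFingerprint("CCO"), ligandFingerprint("CCO"))
  expect_true(attr(ligandFingerprint("CCO"), "valid"))
  expect_false(attr(ligandFingerprint(""), "valid"))
  expect_false(attr(ligandFingerprint(NA_character_), "valid"))
})

test_that("benzene and cyclohexane do not collide", {
  fb <- ligandFingerprint("c1ccccc1")
  fc <- ligandFingerprint("C1CCCCC1")
  expect_lt(tanimoto(fb, fc), 1)
})

test_that("the FP2 chemistry backend fingerprints and flags like the fallback", {
  skip_if_not_installed("ChemmineOB")
  fb <- ligandFingerprint("c1ccccc1", backend = "fp2")
  fc <- ligandFingerprint("C1CCCCC1", backend = "fp2")
  expect_true(attr(fb, "valid"))
  expect_lt(tanimoto(fb, fc), 1)
  bad <- ligandFingerprint("not((smiles", backend = "fp2")
  expect_false(attr(bad, "valid"))
})

test_that("tanimoto follows the hand-counted definition", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(tanimoto(a, b), 1 / 3)   # intersection 1, union 3
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(tanimoto(logical(4), logical(4)), 1)  # both empty by definition
  expect_error(tanimoto(a, b[1:3]), class = "cliquesite_contract_error")
})

test_that("tanimoto is symmetric and bounded on random vectors", {
  set.seed(41)
  for (i in 1:50) {
    a <- runif(64) < 0.3; b <- runif(64) < 0.3
    s <- tanimoto(a, b)
    expect_identical(s, tanimoto(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("identical and mutually dissimilar ligands cluster as expected", {
  same <- data.frame(ligand_code = c("AAA", "BBB", "CCC"), smiles = "CCO",
                     stringsAsFactors = FALSE)
  cl <- clusterLigands(same)
  expect_equal(unique(cl$cluster_id), 1L)
  expect_equal(cl$rel_size, rep(1, 3))

  diff <- data.frame(ligand_code = c("AAA", "BBB", "CCC"),
                     smiles = c("CCCCCCCCCC", "c1ccncc1",
                                "OC(=O)C(N)Cc1ccccc1"),
                     stringsAsFactors = FALSE)
  cl <- clusterLigands(diff)
  expect_equal(sort(cl$cluster_id), 1:3)      # three singletons
  expect_equal(cl$rel_size, rep(1, 3))        # largest cluster has size 1
})

blockFixture <- function() {
  baseA <- "NC(=O)c1ccc(OCC(O)CO)cc1SCCNC(C)=O"
  baseB <- "OC1CC(N2C=NC3=C2N=CN=C3N)OC1COP(=O)(O)O"
  tails <- c("", "F", "Cl", "Br", "I")
  data.frame(ligand_code = sprintf("L%02d", 1:10),
             smiles = c(paste0(baseA, tails), paste0(baseB, tails)),
             stringsAsFactors = FALSE)
}

test_that("a two-block fixture is recovered exactly, matching the components oracle", {
  lig <- blockFixture()
  fps <- lapply(lig$smiles, ligandFingerprint)
  sim <- outer(seq_along(fps), seq_along(fps),
               Vectorize(function(i, j) tanimoto(fps[[i]], fps[[j]])))
  # fixture sanity: similar within blocks, dissimilar across
  expect_true(all(sim[1:5, 1:5] >= 0.7) && all(sim[6:10, 6:10] >= 0.7))
  expect_true(all(sim[1:5, 6:10] < 0.7))

  cl <- clusterLigands(lig, simThreshold = 0.7)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  expect_equal(cl$cluster_size, rep(5L, 10))
  expect_equal(cl$rel_size, rep(1, 10))
  # oracle: connected components of the threshold graph
  adj <- sim >= 0.7; diag(adj) <- FALSE
  comp <- local({
    seen <- integer(10); id <- 0L
    for (s in 1:10) if (seen[s] == 0L) {
      id <- id + 1L; queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (seen[v]) next
        seen[v] <- id
        queue <- c(queue, which(adj[v, ] & seen == 0L))
      }
    }
    seen
  })
  expect_equal(tapply(cl$ligand_code, cl$cluster_id, sort),
               tapply(cl$ligand_code, comp, sort), ignore_attr = TRUE)
})

test_that("clustering is a deterministic partition with a proper weight scale", {
  set.seed(42)
  smis <- sample(c(CliqueSite:::BUILTIN_SMILES,
                   paste0(CliqueSite:::BUILTIN_SMILES, "C")), 25, replace = TRUE)
  lig <- data.frame(ligand_code = sprintf("Z%02d", 1:25), smiles = smis,
                    stringsAsFactors = FALSE)
  cl1 <- clusterLigands(lig)
  cl2 <- clusterLigands(lig[sample(25), ])   # order must not matter
  expect_identical(cl1, cl2)
  # partition: every ligand exactly once
  expect_setequal(cl1$ligand_code, lig$ligand_code)
  expect_false(anyDuplicated(cl1$ligand_code) > 0)
  expect_true(all(cl1$rel_size > 0 & cl1$rel_size <= 1))
  expect_equal(max(cl1$rel_size), 1)
})

test_that("invalid SMILES are excluded with the singleton fallback weight", {
  lig <- data.frame(ligand_code = c("OK1", "OK2", "OK3", "BAD"),
                    smiles = c("CCO", "CCO", "CCO", ""),
                    stringsAsFactors = FALSE)
  cl <- clusterLigands(lig)
  expect_true(is.na(cl$cluster_id[cl$ligand_code == "BAD"]))
  expect_equal(cl$rel_size[cl$ligand_code == "BAD"], 1 / 3)
  expect_equal(cl$cluster_size[cl$ligand_code == "OK1"], 3L)
})

test_that("cluster tables round-trip through CSV", {
  cl <- clusterLigands(blockFixture())
  path <- tempfile(fileext = ".csv")
  writeClusterTable(cl, path)
  back <- readClusterTable(path)
  expect_equal(back, as.data.frame(cl), ignore_attr = TRUE)
})
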