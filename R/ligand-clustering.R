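# Ligand fingerprinting and similarity clustering.
#
# Each library ligand is reduced to a fixed-length bit fingerprint computed
# from its SMILES string; ligands are grouped by Taylor-Butina leader
# clustering at a Tanimoto threshold, and each ligand's relative-cluster-size
# weight (cluster size / largest cluster size) feeds the composite hit score.

KGRAM_BITS <- 2048L
KGRAM_K <- 3L

#' Fingerprint a SMILES string
#'
#' Two backends are provided. `"kgram"` (default) is a self-contained hashed
#' character k-gram fingerprint: every length-3 substring of the SMILES
#' string is hashed (FNV-1a) onto a 2048-bit vector. It requires no
#' cheminformatics stack, is fully deterministic, and performs no chemical
#' canonicalization (two different SMILES spellings of one molecule may get
#' different fingerprints — a documented limitation). `"fp2"` uses Open
#' Babel's path-based FP2 fingerprint (1024 bits) through the ChemmineOB
#' package when it is installed, with chemical parsing and perception; an
#' unparseable SMILES is flagged invalid rather than raising an error.
#'
#' @param smiles character SMILES string.
#' @param backend `"kgram"` or `"fp2"`.
#' @return A logical bit vector with attributes `valid` (logical) and
#'   `backend`. Invalid input (empty string, or unparseable under `"fp2"`)
#'   yields an all-zero vector with `valid = FALSE`.
#' @examples
#' fp <- ligandFingerprint("CCO")
#' attr(fp, "valid")
#' @export
ligandFingerprint <- function(smiles, backend = c("kgram", "fp2")) {
  backend <- match.arg(backend)
  if (backend == "fp2") return(.fingerprintFP2(smiles))
  .fingerprintKgram(smiles)
}

.fingerprintKgram <- function(smiles) {
  bits <- rep(FALSE, KGRAM_BITS)
  s <- if (is.null(smiles) || is.na(smiles)) "" else trimws(smiles)
  if (!nzchar(s)) {
    return(structure(bits, valid = FALSE, backend = "kgram"))
  }
  n <- nchar(s)
  grams <- if (n <= KGRAM_K) s else
    vapply(seq_len(n - KGRAM_K + 1L),
           function(i) substr(s, i, i + KGRAM_K - 1L), character(1))
  for (g in unique(grams)) {
    idx <- (strtoi(fnv1aHash(g), 16L) %% KGRAM_BITS) + 1L
    bits[idx] <- TRUE
  }
  structure(bits, valid = TRUE, backend = "kgram")
}

.fingerprintFP2 <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    .stopClassed("cliquesite_backend_unavailable",
                 "fingerprint backend 'fp2' needs the ChemmineOB package")
  s <- if (is.null(smiles) || is.na(smiles)) "" else trimws(smiles)
  fp <- if (nzchar(s)) tryCatch({
    mol <- ChemmineOB::forEachMol("SMILES", s, identity)
    as.logical(ChemmineOB::fingerprint_OB(mol, "FP2"))
  }, error = function(e) NULL) else NULL
  if (is.null(fp))
    return(structure(rep(FALSE, 1024L), valid = FALSE, backend = "fp2"))
  structure(fp, valid = TRUE, backend = "fp2")
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`, defined as 1 when both vectors are all-zero.
#'
#' @param a,b logical bit vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    .stopClassed("cliquesite_contract_error",
                 "fingerprint lengths differ (%d vs %d)",
                 length(a), length(b))
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

#' Cluster ligands by fingerprint similarity
#'
#' Taylor-Butina leader clustering: for each ligand count its neighbours at
#' Tanimoto >= `simThreshold`; repeatedly take the unassigned ligand with the
#' most unassigned neighbours (ties: lexicographically smallest code) as a
#' cluster centroid together with its unassigned neighbours. Singletons are
#' allowed. The procedure is deterministic: identical input gives identical
#' output.
#'
#' Ligands with an invalid fingerprint are excluded from clustering and
#' reported with `cluster_id = NA`; their weight falls back to the singleton
#' value (1 / largest cluster size).
#'
#' @param ligands data.frame with columns `ligand_code`, `smiles` (duplicated
#'   codes are dropped, first kept).
#' @param simThreshold Tanimoto threshold (default 0.7).
#' @param backend fingerprint backend, see [ligandFingerprint()].
#' @return data.frame `ligand_code, cluster_id, cluster_size, rel_size`,
#'   ordered by ligand code, with attribute `backend`. `rel_size` is the
#'   cluster size divided by the largest cluster's size, so the largest
#'   cluster has weight 1 exactly.
#' @export
clusterLigands <- function(ligands, simThreshold = 0.7,
                           backend = c("kgram", "fp2")) {
  backend <- match.arg(backend)
  ligands <- ligands[!duplicated(ligands$ligand_code), , drop = FALSE]
  codes <- as.character(ligands$ligand_code)
  o <- order(codes)
  codes <- codes[o]
  smiles <- as.character(ligands$smiles)[o]
  n <- length(codes)
  empty <- data.frame(ligand_code = character(0), cluster_id = integer(0),
                      cluster_size = integer(0), rel_size = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(structure(empty, backend = backend))

  fps <- lapply(smiles, ligandFingerprint, backend = backend)
  valid <- vapply(fps, function(f) isTRUE(attr(f, "valid")), logical(1))
  vi <- which(valid)
  cluster_id <- rep(NA_integer_, n)
  if (length(vi) > 0) {
    m <- length(vi)
    fpm <- do.call(rbind, fps[vi])               # m x bits
    sim <- matrix(1, m, m)
    if (m > 1) {
      inter <- tcrossprod(fpm * 1)               # |a AND b|
      ones <- rowSums(fpm)
      un <- outer(ones, ones, "+") - inter       # |a OR b|
      sim <- ifelse(un == 0, 1, inter / un)
    }
    nb <- sim >= simThreshold
    assigned <- rep(FALSE, m)
    cid <- 0L
    while (!all(assigned)) {
      counts <- colSums(nb & !assigned)          # unassigned neighbours (incl self)
      counts[assigned] <- -1L
      lead <- which(counts == max(counts))
      lead <- lead[order(codes[vi][lead])][1]    # tie: smallest ligand code
      members <- which(nb[lead, ] & !assigned)
      cid <- cid + 1L
      cluster_id[vi[members]] <- cid
      assigned[members] <- TRUE
    }
  }
  sizes <- table(cluster_id[!is.na(cluster_id)])
  max_size <- if (length(sizes) > 0) max(sizes) else 1L
  cluster_size <- ifelse(is.na(cluster_id), 1L,
                         as.integer(sizes[as.character(cluster_id)]))
  out <- data.frame(ligand_code = codes,
                    cluster_id = cluster_id,
                    cluster_size = cluster_size,
                    rel_size = cluster_size / max_size,
                    stringsAsFactors = FALSE)
  structure(out, backend = backend)
}

#' @rdname clusterLigands
#' @param clusters a cluster table as returned by `clusterLigands`.
#' @param path output CSV path.
#' @export
writeClusterTable <- function(clusters, path) {
  utils::write.csv(clusters, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname clusterLigands
#' @export
readClusterTable <- function(path) {
  if (!file.exists(path))
    .stopClassed("cliquesite_parse_error", "cluster table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand_code", "cluster_id", "cluster_size", "rel_size")
  if (!all(need %in% names(df)))
    .stopClassed("cliquesite_parse_error",
                 "%s: expected columns %s", path, paste(need, collapse = ","))
  df[, need]
}
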