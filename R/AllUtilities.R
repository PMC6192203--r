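# Shared constants and small helpers.

# The 20 standard amino acids (3-letter codes).
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Non-standard residue mapping kept deliberately minimal: selenomethionine is
# chemically a methionine; everything else is dropped at parse time.
NONSTANDARD_AA_MAP <- c(MSE = "MET")

# Physicochemical groups for relaxed amino-acid compatibility.
AA_GROUPS <- list(
  acidic     = c("ASP", "GLU"),
  basic      = c("LYS", "ARG", "HIS"),
  hydroxyl   = c("SER", "THR"),
  aliphatic  = c("ILE", "LEU", "VAL", "MET"),
  aromatic   = c("PHE", "TYR", "TRP"),
  amide      = c("ASN", "GLN"),
  small      = c("ALA", "GLY"),
  cysteine   = "CYS",
  proline    = "PRO"
)

.aaGroupOf <- local({
  map <- character(0)
  for (g in names(AA_GROUPS)) map[AA_GROUPS[[g]]] <- g
  function(aa) unname(map[aa])
})

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopClassed <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "cliquesite_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used to stamp a configuration hash into report metadata; arithmetic is done
# on split 16-bit halves to stay exact in doubles.
fnv1aHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- .xor32(h, b)
    # h * 16777619 mod 2^32
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

.xor32 <- function(a, b) {
  # bitwXor on doubles representing uint32
  ai <- a %% 4294967296; bi <- b %% 4294967296
  r <- 0; p <- 1
  for (i in 1:32) {
    abit <- ai %% 2; bbit <- bi %% 2
    if (abit != bbit) r <- r + p
    ai <- (ai - abit) / 2; bi <- (bi - bbit) / 2
    p <- p * 2
    if (ai == 0 && bi == 0) break
  }
  r
}

# Full pairwise Euclidean distance matrix for an n x 3 coordinate matrix.
pairwiseDistances <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

# Deterministic residue label "chain:resno" or "chain:resno^ins".
residueLabel <- function(res) {
  ins <- ifelse(is.na(res$ins) | res$ins == "", "", paste0("^", res$ins))
  paste0(res$chain, ":", res$resno, ins)
}

# Order residues by (chain, resno, ins); returns the permutation.
residueOrder <- function(res) {
  order(res$chain, res$resno, ifelse(is.na(res$ins), "", res$ins))
}
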