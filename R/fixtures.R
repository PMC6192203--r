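# Synthetic-data generation: planted-site structures, decoy template
# libraries and minimal PDB fixtures, so the whole pipeline is testable with
# no external downloads.
#
# The generator emulates the apo/holo asymmetry of a binding-site benchmark:
# the template keeps the exact ("holo") site coordinates while the query gets
# a noise-perturbed copy ("apo") buried among decoy residues. Geometry is
# deliberately unphysical — residues are random points with a minimum
# separation — because matching operates on pairwise distances only.

# Small built-in catalogue of valid SMILES for generated ligand tables:
# common metabolites, cofactor fragments and drug-like scaffolds.
BUILTIN_SMILES <- c(
  "CCO", "CC(=O)O", "CC(C)O", "OCC(O)CO", "C1CCCCC1", "c1ccccc1",
  "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1",
  "CC(=O)Nc1ccc(O)cc1", "OC(=O)c1ccccc1", "NC(=O)c1ccccc1",
  "OC(=O)CCC(=O)O", "NCCc1ccccc1", "OCC1OC(O)C(O)C(O)C1O",
  "Nc1ncnc2[nH]cnc12", "OC(=O)C(N)Cc1ccccc1", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C"
)

AA_NO_GLY <- setdiff(STANDARD_AA, "GLY")

.randomUnitVectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# Rejection-sample n points uniformly in a sphere with pairwise separation
# >= minDist. Radius grows with n so packing stays feasible.
.packPoints <- function(n, minDist = 3.2, maxTries = 20000L,
                        existing = NULL) {
  radius <- max(8, 3.0 * (n + nrow(existing %||% matrix(0, 0, 3)))^(1 / 3) * 1.6)
  pts <- existing %||% matrix(numeric(0), 0, 3)
  placed <- 0L
  tries <- 0L
  out <- matrix(NA_real_, n, 3)
  while (placed < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      .stopClassed("cliquesite_generation_error",
                   "could not place %d points at separation %.1f A after %d tries",
                   n, minDist, maxTries)
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) > radius^2) next
    all_pts <- rbind(pts, if (placed > 0) out[seq_len(placed), , drop = FALSE])
    if (nrow(all_pts) > 0) {
      d2 <- (all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2 +
            (all_pts[, 3] - p[3])^2
      if (min(d2) < minDist^2) next
    }
    placed <- placed + 1L
    out[placed, ] <- p
  }
  out
}

# Build a residue table from C-alpha positions: random amino-acid types and
# a side-chain centroid synthesized at a fixed 1.5 A offset in a random
# direction (glycine, when allowed, collapses to its C-alpha).
.residuesFromPoints <- function(ca, chain, resnoStart = 1L,
                                aaPool = AA_NO_GLY) {
  n <- nrow(ca)
  aa <- sample(aaPool, n, replace = TRUE)
  sc <- ca + 1.5 * .randomUnitVectors(n)
  gly <- aa == "GLY"
  sc[gly, ] <- ca[gly, ]
  data.frame(chain = chain, resno = seq.int(resnoStart, length.out = n),
             ins = "", aa = aa,
             ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
             sc_x = sc[, 1], sc_y = sc[, 2], sc_z = sc[, 3],
             stringsAsFactors = FALSE)
}

#' Write a minimal PDB fixture
#'
#' Emits a valid minimal PDB file from a residue descriptor table: one CA
#' ATOM record per residue plus a CB record at the side-chain centroid for
#' non-glycine residues, optionally followed by HETATM records. Coordinates
#' are written at the PDB precision (0.001 A); the output is byte-stable for
#' identical input.
#'
#' @param res residue table (see [residueTable()]).
#' @param path output path.
#' @param het optional data.frame of HETATM atoms with columns
#'   `code, chain, resno, elety, x, y, z`.
#' @return `path`, invisibly.
#' @export
writePdbFixture <- function(res, path, het = NULL) {
  res <- residueTable(res)
  lines <- character(0)
  serial <- 0L
  atomLine <- function(record, name, resid, chain, resno, x, y, z, element) {
    serial <<- serial + 1L
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, paste0(" ", name), " ", resid, chain, resno, " ",
            x, y, z, 1.0, 0.0, element)
  }
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    lines <- c(lines, atomLine("ATOM", "CA ", r$aa, r$chain, r$resno,
                               r$ca_x, r$ca_y, r$ca_z, "C"))
    if (r$aa != "GLY")
      lines <- c(lines, atomLine("ATOM", "CB ", r$aa, r$chain, r$resno,
                                 r$sc_x, r$sc_y, r$sc_z, "C"))
  }
  if (!is.null(het)) {
    for (i in seq_len(nrow(het))) {
      h <- het[i, ]
      lines <- c(lines, atomLine("HETATM", sprintf("%-3s", h$elety), h$code,
                                 h$chain, h$resno, h$x, h$y, h$z,
                                 substr(trimws(h$elety), 1, 1)))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Generate a planted-site benchmark structure
#'
#' Plants a synthetic binding site: `nSiteResidues` residues at random
#' non-clashing positions (pairwise separation >= 3.2 A) form the
#' ground-truth template; the query structure contains a copy of the site
#' perturbed by Gaussian coordinate noise (`noiseSigma`, applied
#' independently to each pseudo-atom coordinate) surrounded by
#' `nDecoyResidues` decoy residues, and is written as a minimal PDB file.
#' Optionally the site is split across several chains so that only
#' interface-mode matching can recover it whole.
#'
#' The generator is reproducible: the same arguments and seed give a
#' byte-identical PDB file on any platform (Mersenne-Twister RNG).
#'
#' @param nSiteResidues number of site residues, >= 3.
#' @param noiseSigma coordinate noise s.d. in Angstrom (default 0.3).
#' @param nDecoyResidues decoy residues surrounding the site (default 50).
#' @param splitAcrossChains `NULL` for a single-chain site, or an integer
#'   partition such as `c(3, 2)` assigning site residues to successive
#'   chains A, B, ...
#' @param seed integer RNG seed.
#' @param path output PDB path (default: a tempfile).
#' @param ligandCode,ligandSmiles identity given to the planted template's
#'   ligand (defaults `"LIG"` and ethanol).
#' @return A list with `path` (the PDB file), `template` (the ground-truth
#'   [SiteTemplate-class], unperturbed coordinates) and `query` (the
#'   [QueryStructure-class] actually written).
#' @export
generatePlantedStructure <- function(nSiteResidues, noiseSigma = 0.3,
                                     nDecoyResidues = 50L,
                                     splitAcrossChains = NULL, seed = 1L,
                                     path = tempfile(fileext = ".pdb"),
                                     ligandCode = "LIG",
                                     ligandSmiles = BUILTIN_SMILES[1]) {
  stopifnot(nSiteResidues >= 3)
  if (!is.null(splitAcrossChains)) {
    splitAcrossChains <- as.integer(splitAcrossChains)
    if (sum(splitAcrossChains) != nSiteResidues || any(splitAcrossChains < 1))
      .stopClassed("cliquesite_generation_error",
                   "splitAcrossChains must be a positive partition of nSiteResidues")
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  site_ca <- .packPoints(nSiteResidues)
  site <- .residuesFromPoints(site_ca, chain = "A")
  template <- SiteTemplate(
    templateId = sprintf("planted_s%d", as.integer(seed)),
    residues = site, ligandCode = ligandCode,
    sourceStructure = sprintf("synthetic_seed%d", as.integer(seed)),
    ligandSmiles = ligandSmiles)

  # query: noisy copy of the site, optionally split over chains
  qsite <- site
  noise <- function(m) m + matrix(stats::rnorm(length(m), 0, noiseSigma),
                                  nrow(m), ncol(m))
  if (noiseSigma > 0) {
    qsite[, c("ca_x", "ca_y", "ca_z")] <-
      noise(as.matrix(qsite[, c("ca_x", "ca_y", "ca_z")]))
    sc <- as.matrix(qsite[, c("sc_x", "sc_y", "sc_z")])
    gly <- qsite$aa == "GLY"
    sc[!gly, ] <- noise(sc[!gly, , drop = FALSE])
    sc[gly, ] <- as.matrix(qsite[gly, c("ca_x", "ca_y", "ca_z")])
    qsite[, c("sc_x", "sc_y", "sc_z")] <- sc
  }
  chains <- "A"
  if (!is.null(splitAcrossChains)) {
    chains <- LETTERS[seq_along(splitAcrossChains)]
    qsite$chain <- rep(chains, splitAcrossChains)
  }
  decoys <- NULL
  if (nDecoyResidues > 0) {
    decoy_ca <- .packPoints(nDecoyResidues, existing = site_ca)
    decoy_chain <- rep(chains, length.out = nDecoyResidues)
    decoys <- .residuesFromPoints(decoy_ca, chain = decoy_chain[1])
    decoys$chain <- sort(decoy_chain)
  }
  qres <- rbind(qsite, decoys)
  # renumber per chain so (chain, resno) is unique
  for (ch in unique(qres$chain)) {
    sel <- qres$chain == ch
    qres$resno[sel] <- seq_len(sum(sel))
  }
  query <- QueryStructure(
    sprintf("planted_query_s%d", as.integer(seed)), qres)
  writePdbFixture(residues(query), path)
  list(path = path, template = template, query = query)
}

#' Generate a decoy template library
#'
#' Random geometric templates (non-clashing random residues, sizes drawn
#' from `sizes`) with generated ligand codes and SMILES strings taken from a
#' built-in catalogue of valid SMILES. Deterministic under `seed`; saving
#' the same library twice gives byte-identical files.
#'
#' @param nTemplates number of decoy templates.
#' @param sizes integer vector of allowed template sizes (default `5:8`).
#' @param seed integer RNG seed.
#' @param extraTemplates optional list of [SiteTemplate-class] (e.g. a
#'   planted ground-truth template) merged into the library and ligand
#'   table.
#' @return A [TemplateLibrary-class].
#' @export
generateDecoyLibrary <- function(nTemplates, sizes = 5:8, seed = 1L,
                                 extraTemplates = list()) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  entries <- list()
  lig_codes <- character(0)
  lig_smiles <- character(0)
  for (i in seq_len(nTemplates)) {
    n <- if (length(sizes) == 1) sizes else sample(sizes, 1)
    ca <- .packPoints(n)
    res <- .residuesFromPoints(ca, chain = "A")
    code <- sprintf("D%02d", ((i - 1) %% 99) + 1)
    smi <- BUILTIN_SMILES[((i - 1) %% length(BUILTIN_SMILES)) + 1]
    entries[[i]] <- SiteTemplate(
      templateId = sprintf("decoy_%03d", i),
      residues = res, ligandCode = code,
      sourceStructure = sprintf("synthetic_decoy_%03d", i),
      ligandSmiles = smi)
    lig_codes <- c(lig_codes, code)
    lig_smiles <- c(lig_smiles, smi)
  }
  for (tmpl in extraTemplates) {
    entries[[length(entries) + 1L]] <- tmpl
    if (nzchar(tmpl@ligandCode)) {
      lig_codes <- c(lig_codes, tmpl@ligandCode)
      lig_smiles <- c(lig_smiles, tmpl@ligandSmiles)
    }
  }
  keep <- !duplicated(lig_codes)
  TemplateLibrary(entries,
                  data.frame(ligand_code = lig_codes[keep],
                             smiles = lig_smiles[keep],
                             stringsAsFactors = FALSE),
                  metadata = list(generator = "generateDecoyLibrary",
                                  seed = as.integer(seed)))
}
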