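# Structure parsing: PDB/mmCIF -> residue-level descriptors.
#
# Each standard residue is reduced to two pseudo-atoms: its C-alpha and its
# side-chain heavy-atom centroid. Matching downstream operates exclusively on
# these representative points.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.readStructureAtoms <- function(path, modelIndex = 1L) {
  if (!file.exists(path))
    .stopClassed("cliquesite_parse_error", "structure file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  reader <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif else bio3d::read.pdb
  multi <- modelIndex > 1L
  pdb <- tryCatch(
    suppressWarnings(reader(path, multi = multi, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) .stopClassed("cliquesite_parse_error",
                                     "cannot parse structure file %s: %s",
                                     path, conditionMessage(e)))
  atoms <- pdb$atom
  if (multi) {
    if (modelIndex > nrow(pdb$xyz))
      .stopClassed("cliquesite_parse_error",
                   "model %d requested but %s has %d model(s)",
                   modelIndex, path, nrow(pdb$xyz))
    xyz <- matrix(pdb$xyz[modelIndex, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  atoms$chain[is.na(atoms$chain)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms
}

.isHydrogen <- function(atoms) {
  elesy <- toupper(trimws(atoms$elesy))
  h <- !is.na(elesy) & elesy %in% c("H", "D")
  # fall back on the atom name when the element column is blank
  blank <- is.na(elesy) | elesy == ""
  h[blank] <- grepl("^[0-9]*[HD]", trimws(atoms$elety[blank]))
  h
}

# Resolve alternate locations: within each (chain, resno, ins, atom name)
# group keep the highest-occupancy record, ties broken by file order.
.resolveAltloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    idx[which.max(atoms$o[idx])]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

.residuesFromAtoms <- function(atoms, structureId) {
  # protein residues: ATOM records plus HETATM selenomethionine
  aa <- atoms$resid
  mapped <- NONSTANDARD_AA_MAP[aa]
  aa[!is.na(mapped)] <- mapped[!is.na(mapped)]
  is_standard <- aa %in% STANDARD_AA
  is_protein <- atoms$type == "ATOM" | atoms$resid %in% names(NONSTANDARD_AA_MAP)
  dropped <- unique(atoms$resid[is_protein & !is_standard & atoms$type == "ATOM"])
  if (length(dropped) > 0)
    warning("dropping non-standard residue type(s): ",
            paste(sort(dropped), collapse = ", "), call. = FALSE)
  atoms <- atoms[is_protein & is_standard & !.isHydrogen(atoms), , drop = FALSE]
  if (nrow(atoms) == 0) return(NULL)
  atoms$aa3 <- {
    a <- atoms$resid; m <- NONSTANDARD_AA_MAP[a]
    a[!is.na(m)] <- m[!is.na(m)]; a
  }
  atoms <- .resolveAltloc(atoms)

  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  groups <- split(seq_len(nrow(atoms)), key)
  rows <- lapply(groups, function(idx) {
    sub <- atoms[idx, , drop = FALSE]
    ca <- which(trimws(sub$elety) == "CA")
    if (length(ca) == 0) return(NULL)
    ca <- ca[1]
    sc <- sub[!trimws(sub$elety) %in% BACKBONE_ATOMS, , drop = FALSE]
    if (sub$aa3[1] == "GLY" || nrow(sc) == 0) {
      scx <- sub$x[ca]; scy <- sub$y[ca]; scz <- sub$z[ca]
    } else {
      scx <- mean(sc$x); scy <- mean(sc$y); scz <- mean(sc$z)
    }
    data.frame(chain = sub$chain[1], resno = sub$resno[1],
               ins = sub$insert[1], aa = sub$aa3[1],
               ca_x = sub$x[ca], ca_y = sub$y[ca], ca_z = sub$z[ca],
               sc_x = scx, sc_y = scy, sc_z = scz,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Parse a protein structure into residue descriptors
#'
#' Reads a PDB or mmCIF file (dispatched on the file extension) and returns a
#' [QueryStructure-class] holding one descriptor per standard amino-acid
#' residue that has a C-alpha atom. HETATM ligands, waters and nucleic acids
#' are excluded; selenomethionine (MSE) is mapped to MET; other non-standard
#' residues are dropped with a warning. Alternate locations are resolved to
#' the highest-occupancy conformer (ties: first in file order). Only one
#' model of a multi-model file is used.
#'
#' @param path path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param modelIndex 1-based model number for multi-model files (default 1).
#' @param chains optional character vector restricting the parse to these
#'   chain identifiers.
#' @param structureId identifier stored in the result; defaults to the file
#'   name without extension.
#' @return A [QueryStructure-class] object.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' fx <- generatePlantedStructure(nSiteResidues = 5, noiseSigma = 0,
#'                                nDecoyResidues = 5, seed = 7, path = pdb)
#' parseStructure(pdb)
#' @export
parseStructure <- function(path, modelIndex = 1L, chains = NULL,
                           structureId = NULL) {
  structureId <- structureId %||% tools::file_path_sans_ext(basename(path))
  atoms <- .readStructureAtoms(path, as.integer(modelIndex))
  if (!is.null(chains))
    atoms <- atoms[atoms$chain %in% chains, , drop = FALSE]
  res <- .residuesFromAtoms(atoms, structureId)
  if (is.null(res) || nrow(res) == 0)
    .stopClassed("cliquesite_empty_structure",
                 "no standard amino-acid residues selected from %s%s", path,
                 if (is.null(chains)) "" else
                   sprintf(" (chain filter: %s)", paste(chains, collapse = ",")))
  QueryStructure(structureId, res)
}

#' Extract the residues in contact with a bound ligand
#'
#' Finds the residues of a holo structure having at least one heavy atom
#' within `contactCutoff` of any heavy atom of the named HETATM ligand. When
#' the structure carries several instances of the same ligand code, the first
#' instance in file order is used unless `instance` selects one explicitly.
#'
#' @param holoPath path to the holo structure file.
#' @param ligandCode 3-letter HET code of the ligand.
#' @param contactCutoff heavy-atom distance cutoff in Angstrom (default 4.5,
#'   a standard contact definition for binding-pocket residues).
#' @param instance optional instance selector `"chain:resno"`.
#' @return A list with `residues` (descriptor data.frame ordered by chain and
#'   residue number) and `instance` (the `"chain:resno"` label of the ligand
#'   instance used).
#' @seealso [buildTemplate()]
#' @export
extractLigandContacts <- function(holoPath, ligandCode, contactCutoff = 4.5,
                                  instance = NULL) {
  atoms <- .readStructureAtoms(holoPath)
  het <- atoms[atoms$type == "HETATM" & !.isHydrogen(atoms), , drop = FALSE]
  lig <- het[het$resid == ligandCode, , drop = FALSE]
  if (nrow(lig) == 0) {
    present <- sort(unique(het$resid))
    .stopClassed("cliquesite_ligand_not_found",
                 "ligand %s not found in %s; HET codes present: %s",
                 ligandCode, holoPath,
                 if (length(present)) paste(present, collapse = ", ") else "<none>")
  }
  inst_key <- paste(lig$chain, lig$resno, sep = ":")
  if (is.null(instance)) {
    instance <- inst_key[1]  # first instance in file order
  } else if (!instance %in% inst_key) {
    .stopClassed("cliquesite_ligand_not_found",
                 "ligand instance %s of %s not present (instances: %s)",
                 instance, ligandCode, paste(unique(inst_key), collapse = ", "))
  }
  lig <- lig[inst_key == instance, , drop = FALSE]

  res <- .residuesFromAtoms(atoms, "holo")
  if (is.null(res))
    .stopClassed("cliquesite_empty_structure",
                 "no standard amino-acid residues in %s", holoPath)

  # protein heavy atoms, tagged with their residue key
  prot <- atoms[atoms$type == "ATOM" & !.isHydrogen(atoms), , drop = FALSE]
  prot_key <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  if (contactCutoff <= 0) {
    contact_keys <- character(0)
  } else {
    lx <- as.matrix(lig[, c("x", "y", "z")])
    px <- as.matrix(prot[, c("x", "y", "z")])
    # squared-distance test against every ligand heavy atom
    near <- rep(FALSE, nrow(px))
    for (k in seq_len(nrow(lx))) {
      d2 <- (px[, 1] - lx[k, 1])^2 + (px[, 2] - lx[k, 2])^2 +
            (px[, 3] - lx[k, 3])^2
      near <- near | d2 <= contactCutoff^2
    }
    contact_keys <- unique(prot_key[near])
  }
  res_key <- paste(res$chain, res$resno, res$ins, sep = "\r")
  out <- res[res_key %in% contact_keys, , drop = FALSE]
  out <- out[residueOrder(out), , drop = FALSE]
  rownames(out) <- NULL
  list(residues = out, instance = instance)
}
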