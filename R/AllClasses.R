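#' @import methods
NULL

# Residue tables -------------------------------------------------------------
#
# Residues are carried as plain data.frames with one row per residue and
# columns:
#   chain  character  chain identifier
#   resno  integer    author residue number (as deposited, no renumbering)
#   ins    character  insertion code ("" if none)
#   aa     character  3-letter standard amino-acid code
#   ca_x, ca_y, ca_z  numeric  C-alpha coordinates (Angstrom)
#   sc_x, sc_y, sc_z  numeric  side-chain heavy-atom centroid (equals the
#                              C-alpha position for glycine)

RESIDUE_COLUMNS <- c("chain", "resno", "ins", "aa",
                     "ca_x", "ca_y", "ca_z", "sc_x", "sc_y", "sc_z")

#' Assemble a residue descriptor table
#'
#' Low-level constructor for the residue tables stored inside
#' [QueryStructure-class] and [SiteTemplate-class] objects. Checks column
#' names, amino-acid alphabet, coordinate finiteness and
#' (chain, resno, ins) uniqueness.
#'
#' @param df data.frame with the residue descriptor columns.
#' @return The validated data.frame (row names stripped, columns ordered).
#' @export
residueTable <- function(df) {
  missing <- setdiff(RESIDUE_COLUMNS, names(df))
  if (length(missing) > 0)
    stop("residue table lacks columns: ", paste(missing, collapse = ", "))
  df <- df[, RESIDUE_COLUMNS, drop = FALSE]
  df$chain <- as.character(df$chain)
  df$resno <- as.integer(df$resno)
  df$ins <- ifelse(is.na(df$ins), "", as.character(df$ins))
  df$aa <- as.character(df$aa)
  for (col in RESIDUE_COLUMNS[5:10]) df[[col]] <- as.numeric(df[[col]])
  rownames(df) <- NULL
  df
}

.validateResidueTable <- function(df) {
  msgs <- character(0)
  if (!all(RESIDUE_COLUMNS %in% names(df)))
    return("residue table lacks required columns")
  bad_aa <- setdiff(unique(df$aa), STANDARD_AA)
  if (length(bad_aa) > 0)
    msgs <- c(msgs, paste0("non-standard amino acids present: ",
                           paste(bad_aa, collapse = ", ")))
  coords <- as.matrix(df[, RESIDUE_COLUMNS[5:10]])
  if (nrow(df) > 0 && !all(is.finite(coords)))
    msgs <- c(msgs, "non-finite coordinates in residue table")
  key <- paste(df$chain, df$resno, df$ins, sep = "\r")
  if (anyDuplicated(key))
    msgs <- c(msgs, "(chain, resno, ins) not unique across residues")
  msgs
}

# QueryStructure -------------------------------------------------------------

#' Parsed query structure
#'
#' Residue-level representation of a protein structure used for matching.
#' Each residue contributes two pseudo-atoms: the C-alpha position and the
#' side-chain heavy-atom centroid (glycine degenerates to C-alpha only).
#'
#' @slot structureId character, identifier (file stem by default).
#' @slot residues data.frame, one row per standard residue (see
#'   [residueTable()]).
#' @slot chainIds character, chains present.
#' @seealso [parseStructure()]
#' @exportClass QueryStructure
setClass("QueryStructure",
  representation(structureId = "character",
                 residues = "data.frame",
                 chainIds = "character"),
  validity = function(object) {
    msgs <- .validateResidueTable(object@residues)
    if (nrow(object@residues) == 0)
      msgs <- c(msgs, "query structure has no residues")
    if (!setequal(object@chainIds, unique(object@residues$chain)))
      msgs <- c(msgs, "chainIds inconsistent with residue table")
    if (length(msgs) > 0) msgs else TRUE
  })

#' @rdname QueryStructure-class
#' @param structureId identifier for the structure.
#' @param residues residue descriptor data.frame.
#' @export
QueryStructure <- function(structureId, residues) {
  residues <- residueTable(residues)
  residues <- residues[residueOrder(residues), , drop = FALSE]
  rownames(residues) <- NULL
  new("QueryStructure", structureId = as.character(structureId),
      residues = residues,
      chainIds = sort(unique(residues$chain)))
}

# SiteTemplate ----------------------------------------------------------------

#' Binding- or catalytic-site template
#'
#' A known site described by its contact residues (with coordinates) plus the
#' bound ligand, used as a search pattern against query structures. Ligand
#' binding templates carry a 3-letter HET code (and optionally a SMILES
#' string); catalytic-site templates have an empty ligand code.
#'
#' @slot templateId character, unique identifier within a library.
#' @slot sourceStructure character, provenance (e.g. a PDB code).
#' @slot siteKind character, `"ligand_binding"` or `"catalytic"`.
#' @slot residues data.frame, at least 3 residues (see [residueTable()]).
#' @slot ligandCode character, 3-letter HET code ("" for catalytic sites).
#' @slot ligandSmiles character, SMILES of the ligand ("" if unknown).
#' @seealso [buildTemplate()], [TemplateLibrary-class]
#' @exportClass SiteTemplate
setClass("SiteTemplate",
  representation(templateId = "character",
                 sourceStructure = "character",
                 siteKind = "character",
                 residues = "data.frame",
                 ligandCode = "character",
                 ligandSmiles = "character"),
  validity = function(object) {
    msgs <- .validateResidueTable(object@residues)
    if (nrow(object@residues) < 3)
      msgs <- c(msgs, "site template needs at least 3 residues")
    if (!object@siteKind %in% c("ligand_binding", "catalytic"))
      msgs <- c(msgs, "siteKind must be 'ligand_binding' or 'catalytic'")
    if (object@siteKind == "ligand_binding" && !nzchar(object@ligandCode))
      msgs <- c(msgs, "ligand_binding template requires a ligand code")
    if (length(msgs) > 0) msgs else TRUE
  })

#' @rdname SiteTemplate-class
#' @param templateId,sourceStructure,siteKind,residues,ligandCode,ligandSmiles
#'   see the slot documentation.
#' @export
SiteTemplate <- function(templateId, residues, ligandCode = "",
                         siteKind = if (nzchar(ligandCode)) "ligand_binding" else "catalytic",
                         sourceStructure = "", ligandSmiles = "") {
  residues <- residueTable(residues)
  residues <- residues[residueOrder(residues), , drop = FALSE]
  rownames(residues) <- NULL
  new("SiteTemplate", templateId = as.character(templateId),
      sourceStructure = as.character(sourceStructure),
      siteKind = siteKind, residues = residues,
      ligandCode = as.character(ligandCode),
      ligandSmiles = as.character(ligandSmiles))
}

# TemplateLibrary -------------------------------------------------------------

#' Library of site templates
#'
#' An on-disk collection of [SiteTemplate-class] entries together with a
#' ligand table mapping HET codes to SMILES strings and build metadata.
#' Serialized as versioned JSON-lines by [saveLibrary()].
#'
#' @slot entries list of `SiteTemplate`.
#' @slot ligandTable data.frame with columns `ligand_code`, `smiles`.
#' @slot metadata list of build parameters and flags (e.g. `missing_smiles`).
#' @seealso [saveLibrary()], [loadLibrary()]
#' @exportClass TemplateLibrary
setClass("TemplateLibrary",
  representation(entries = "list",
                 ligandTable = "data.frame",
                 metadata = "list"),
  validity = function(object) {
    msgs <- character(0)
    if (!all(vapply(object@entries, is, logical(1), "SiteTemplate")))
      msgs <- c(msgs, "entries must all be SiteTemplate objects")
    ids <- vapply(object@entries, function(e) e@templateId, character(1))
    if (anyDuplicated(ids))
      msgs <- c(msgs, "template ids are not unique")
    if (!all(c("ligand_code", "smiles") %in% names(object@ligandTable)))
      msgs <- c(msgs, "ligandTable needs columns ligand_code, smiles")
    if (length(msgs) > 0) msgs else TRUE
  })

#' @rdname TemplateLibrary-class
#' @param entries list of `SiteTemplate`.
#' @param ligandTable data.frame `ligand_code`, `smiles` (may be empty).
#' @param metadata named list.
#' @export
TemplateLibrary <- function(entries, ligandTable = NULL, metadata = list()) {
  if (is.null(ligandTable))
    ligandTable <- data.frame(ligand_code = character(0),
                              smiles = character(0),
                              stringsAsFactors = FALSE)
  ligandTable$ligand_code <- as.character(ligandTable$ligand_code)
  ligandTable$smiles <- as.character(ligandTable$smiles)
  # flag ligand codes referenced by entries but absent from the table
  codes <- unique(vapply(entries, function(e) e@ligandCode, character(1)))
  codes <- codes[nzchar(codes)]
  missing <- sort(setdiff(codes, ligandTable$ligand_code))
  metadata$missing_smiles <- missing
  new("TemplateLibrary", entries = entries,
      ligandTable = ligandTable[, c("ligand_code", "smiles"), drop = FALSE],
      metadata = metadata)
}

# AssociationGraph ------------------------------------------------------------

#' Association (product) graph between a template and a query
#'
#' Vertices are amino-acid-compatible (template residue, query residue) pairs;
#' an edge joins two vertices when the template-side and query-side pairwise
#' distances agree within the tolerance for both the C-alpha and side-chain
#' centroid pseudo-atoms, and the vertices share neither a template nor a
#' query residue. Cliques in this graph are rigid sub-structure matches.
#'
#' @slot vertices integer matrix, columns `t` (template residue index) and
#'   `q` (query residue index).
#' @slot adjacency logical symmetric matrix over vertices.
#' @slot params list, tolerances used in construction.
#' @seealso [buildAssociationGraph()], [findMaxCliques()]
#' @exportClass AssociationGraph
setClass("AssociationGraph",
  representation(vertices = "matrix",
                 adjacency = "matrix",
                 params = "list"),
  validity = function(object) {
    msgs <- character(0)
    nv <- nrow(object@vertices)
    if (nv > 0 && ncol(object@vertices) != 2)
      msgs <- c(msgs, "vertices must have two columns")
    if (nv != nrow(object@adjacency) || nv != ncol(object@adjacency))
      msgs <- c(msgs, "adjacency dimensions do not match vertex count")
    if (nv > 0 && !identical(object@adjacency, t(object@adjacency)))
      msgs <- c(msgs, "adjacency must be symmetric")
    if (length(msgs) > 0) msgs else TRUE
  })

# MatchRecord -----------------------------------------------------------------

#' One template-to-query correspondence
#'
#' Produced by [matchTemplate()]: a maximal clique of residue pairs together
#' with the optimal rigid transform and the RMSD it realizes over the matched
#' pseudo-atoms.
#'
#' @slot templateId,sourceStructure,siteKind,ligandCode template provenance.
#' @slot pairs integer matrix (`t`, `q`): matched residue indices.
#' @slot rotation 3x3 proper rotation matrix mapping template coordinates
#'   onto the query frame.
#' @slot translation length-3 numeric translation (Angstrom).
#' @slot rmsd numeric, RMSD over matched pseudo-atoms (Angstrom).
#' @slot cliqueSize,templateSize integer.
#' @slot spansChains character, query chains involved.
#' @slot matchedResidues character, query residue labels "chain:resno".
#' @exportClass MatchRecord
setClass("MatchRecord",
  representation(templateId = "character",
                 sourceStructure = "character",
                 siteKind = "character",
                 ligandCode = "character",
                 pairs = "matrix",
                 rotation = "matrix",
                 translation = "numeric",
                 rmsd = "numeric",
                 cliqueSize = "integer",
                 templateSize = "integer",
                 spansChains = "character",
                 matchedResidues = "character"),
  validity = function(object) {
    msgs <- character(0)
    if (object@cliqueSize < 3 || object@cliqueSize > object@templateSize)
      msgs <- c(msgs, "clique size must lie in [3, template size]")
    if (object@rmsd < 0) msgs <- c(msgs, "rmsd must be non-negative")
    R <- object@rotation
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
      msgs <- c(msgs, "rotation must be proper orthonormal")
    if (length(msgs) > 0) msgs else TRUE
  })
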