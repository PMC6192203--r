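# Template library: per-structure template building plus the versioned
# JSON-lines on-disk format.
#
# File layout (UTF-8, one JSON object per line):
#   line 1   header: {"format":"cliquesite-lib","version":1,"metadata":{...}}
#   line 2+  one template per line with all SiteTemplate fields; residues as
#            parallel arrays
#   final    {"ligand_table":{"<code>":"<smiles>",...}} (optional)

LIB_FORMAT <- "cliquesite-lib"
LIB_VERSION <- 1L

# Ligands never worth a binding-site template: waters, common buffer ions and
# cryoprotectants. Configurable at build time.
DEFAULT_EXCLUDED_LIGANDS <- c(
  "HOH", "DOD", "WAT", "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU",
  "NI", "CO", "CD", "HG", "IOD", "BR", "SO4", "PO4", "NO3", "ACT", "GOL",
  "EDO", "PEG", "PG4", "MPD", "DMS", "BME", "TRS", "EPE", "MES", "FMT"
)

#' Build a site template from a holo structure
#'
#' Extracts the residues in contact with a bound ligand (see
#' [extractLigandContacts()]) and wraps them into a [SiteTemplate-class].
#' Sites with fewer than 3 contact residues are rejected: a correspondence of
#' fewer than 3 points cannot constrain a rigid transform's RMSD, so such
#' degenerate templates never enter a library.
#'
#' @inheritParams extractLigandContacts
#' @param templateId identifier; defaults to
#'   `"<file stem>_<ligand>_<instance>"`.
#' @param ligandSmiles optional SMILES string for the ligand.
#' @param sourceStructure provenance label; defaults to the file stem.
#' @return A [SiteTemplate-class] of kind `"ligand_binding"`.
#' @export
buildTemplate <- function(holoPath, ligandCode, contactCutoff = 4.5,
                          instance = NULL, templateId = NULL,
                          ligandSmiles = "", sourceStructure = NULL) {
  contacts <- extractLigandContacts(holoPath, ligandCode, contactCutoff,
                                    instance)
  if (nrow(contacts$residues) < 3)
    .stopClassed("cliquesite_too_small_site",
                 "only %d residue(s) contact %s (%s) in %s; at least 3 are required",
                 nrow(contacts$residues), ligandCode, contacts$instance,
                 holoPath)
  stem <- tools::file_path_sans_ext(basename(holoPath))
  SiteTemplate(
    templateId = templateId %||%
      paste(stem, ligandCode, gsub(":", "", contacts$instance), sep = "_"),
    residues = contacts$residues,
    ligandCode = ligandCode,
    sourceStructure = sourceStructure %||% stem,
    ligandSmiles = ligandSmiles)
}

.templateToJSON <- function(tmpl) {
  res <- residues(tmpl)
  jsonlite::toJSON(list(
    template_id = jsonlite::unbox(tmpl@templateId),
    source_structure = jsonlite::unbox(tmpl@sourceStructure),
    site_kind = jsonlite::unbox(tmpl@siteKind),
    ligand_code = jsonlite::unbox(tmpl@ligandCode),
    ligand_smiles = jsonlite::unbox(tmpl@ligandSmiles),
    residues = list(
      chain = res$chain, resno = res$resno, ins = res$ins, aa = res$aa,
      ca = lapply(seq_len(nrow(res)), function(i)
        c(res$ca_x[i], res$ca_y[i], res$ca_z[i])),
      sc = lapply(seq_len(nrow(res)), function(i)
        c(res$sc_x[i], res$sc_y[i], res$sc_z[i]))
    )), digits = NA)
}

.templateFromJSON <- function(obj) {
  r <- obj$residues
  ca <- matrix(unlist(r$ca), ncol = 3, byrow = TRUE)
  sc <- matrix(unlist(r$sc), ncol = 3, byrow = TRUE)
  SiteTemplate(
    templateId = obj$template_id,
    residues = data.frame(chain = unlist(r$chain), resno = unlist(r$resno),
                          ins = unlist(r$ins), aa = unlist(r$aa),
                          ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                          sc_x = sc[, 1], sc_y = sc[, 2], sc_z = sc[, 3],
                          stringsAsFactors = FALSE),
    ligandCode = obj$ligand_code,
    siteKind = obj$site_kind,
    sourceStructure = obj$source_structure,
    ligandSmiles = obj$ligand_smiles)
}

#' Write a template library to disk
#'
#' Serializes a [TemplateLibrary-class] as versioned JSON-lines (see the
#' format notes in this file's source). The output is deterministic: saving
#' the same library twice yields byte-identical files.
#'
#' @param lib a [TemplateLibrary-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveLibrary <- function(lib, path) {
  stopifnot(is(lib, "TemplateLibrary"))
  meta <- lib@metadata
  meta$missing_smiles <- NULL   # recomputed at load time
  header <- jsonlite::toJSON(list(
    format = jsonlite::unbox(LIB_FORMAT),
    version = jsonlite::unbox(LIB_VERSION),
    n_templates = jsonlite::unbox(length(lib@entries)),
    metadata = meta), digits = NA)
  lines <- c(header,
             vapply(lib@entries, .templateToJSON, character(1)))
  lt <- lib@ligandTable
  if (nrow(lt) > 0) {
    o <- order(lt$ligand_code)
    tab <- as.list(lt$smiles[o]); names(tab) <- lt$ligand_code[o]
    lines <- c(lines, jsonlite::toJSON(list(ligand_table = tab),
                                       auto_unbox = TRUE, digits = NA))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a template library from disk
#'
#' Inverse of [saveLibrary()]; the round trip is lossless. Entries whose
#' ligand code is absent from the ligand table are flagged in
#' `metadata$missing_smiles` rather than rejected.
#'
#' @param path library file path.
#' @return A [TemplateLibrary-class].
#' @export
loadLibrary <- function(path) {
  if (!file.exists(path))
    .stopClassed("cliquesite_parse_error", "library file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    .stopClassed("cliquesite_parse_error", "empty library file: %s", path)
  header <- tryCatch(jsonlite::fromJSON(lines[1], simplifyVector = FALSE),
                     error = function(e)
                       .stopClassed("cliquesite_parse_error",
                                    "%s line 1: malformed header (%s)",
                                    path, conditionMessage(e)))
  if (!identical(header$format, LIB_FORMAT))
    .stopClassed("cliquesite_parse_error",
                 "%s is not a %s file", path, LIB_FORMAT)
  if (!identical(as.integer(header$version), LIB_VERSION))
    .stopClassed("cliquesite_unsupported_version",
                 "%s: unsupported library format version %s (supported: %d)",
                 path, header$version, LIB_VERSION)
  entries <- list()
  ligtab <- data.frame(ligand_code = character(0), smiles = character(0),
                       stringsAsFactors = FALSE)
  for (i in seq_along(lines)[-1]) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      .stopClassed("cliquesite_parse_error",
                                   "%s line %d: malformed record (%s)",
                                   path, i, conditionMessage(e)))
    if (!is.null(obj$ligand_table)) {
      lt <- obj$ligand_table
      ligtab <- data.frame(ligand_code = names(lt),
                           smiles = unlist(lt, use.names = FALSE),
                           stringsAsFactors = FALSE)
    } else if (!is.null(obj$template_id)) {
      entries[[length(entries) + 1L]] <- tryCatch(
        .templateFromJSON(obj),
        error = function(e)
          .stopClassed("cliquesite_parse_error",
                       "%s line %d: invalid template (%s)",
                       path, i, conditionMessage(e)))
    } else {
      .stopClassed("cliquesite_parse_error",
                   "%s line %d: unrecognized record", path, i)
    }
  }
  meta <- lapply(header$metadata %||% list(), function(x)
    if (is.list(x)) unlist(x) else x)
  TemplateLibrary(entries, ligtab, metadata = meta)
}

#' Read / write a ligand table CSV
#'
#' The ligand table maps 3-letter HET codes to SMILES strings, one ligand
#' per row, columns `ligand_code,smiles`.
#'
#' @param path CSV file path.
#' @return `readLigandTable` returns the data.frame; `writeLigandTable`
#'   returns `path` invisibly.
#' @export
readLigandTable <- function(path) {
  if (!file.exists(path))
    .stopClassed("cliquesite_parse_error", "ligand table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("ligand_code", "smiles") %in% names(df)))
    .stopClassed("cliquesite_parse_error",
                 "%s: expected columns ligand_code,smiles", path)
  df[, c("ligand_code", "smiles")]
}

#' @rdname readLigandTable
#' @param table data.frame with columns `ligand_code`, `smiles`.
#' @export
writeLigandTable <- function(table, path) {
  utils::write.csv(table[, c("ligand_code", "smiles")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}
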