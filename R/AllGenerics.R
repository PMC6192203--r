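#' Accessors for CliqueSite objects
#'
#' Standard accessors: `residues()` returns the residue descriptor table,
#' `nResidues()` its row count, `chainIds()` the chains present,
#' `templateId()`, `ligandCode()`, `siteKind()` the template identity fields,
#' `templateEntries()` and `ligandTable()` the library contents.
#'
#' @param x a `QueryStructure`, `SiteTemplate`, `TemplateLibrary` or
#'   `MatchRecord` object, as applicable.
#' @return See the individual generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("templateId", function(x) standardGeneric("templateId"))
#' @rdname accessors
#' @export
setGeneric("ligandCode", function(x) standardGeneric("ligandCode"))
#' @rdname accessors
#' @export
setGeneric("siteKind", function(x) standardGeneric("siteKind"))
#' @rdname accessors
#' @export
setGeneric("templateEntries", function(x) standardGeneric("templateEntries"))
#' @rdname accessors
#' @export
setGeneric("ligandTable", function(x) standardGeneric("ligandTable"))

#' @rdname accessors
#' @export
setMethod("residues", "QueryStructure", function(x) x@residues)
#' @rdname accessors
#' @export
setMethod("residues", "SiteTemplate", function(x) x@residues)
#' @rdname accessors
#' @export
setMethod("nResidues", "QueryStructure", function(x) nrow(x@residues))
#' @rdname accessors
#' @export
setMethod("nResidues", "SiteTemplate", function(x) nrow(x@residues))
#' @rdname accessors
#' @export
setMethod("chainIds", "QueryStructure", function(x) x@chainIds)
#' @rdname accessors
#' @export
setMethod("templateId", "SiteTemplate", function(x) x@templateId)
#' @rdname accessors
#' @export
setMethod("ligandCode", "SiteTemplate", function(x) x@ligandCode)
#' @rdname accessors
#' @export
setMethod("siteKind", "SiteTemplate", function(x) x@siteKind)
#' @rdname accessors
#' @export
setMethod("templateEntries", "TemplateLibrary", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("ligandTable", "TemplateLibrary", function(x) x@ligandTable)

#' @describeIn QueryStructure-class compact display
#' @param object object to display
#' @export
setMethod("show", "QueryStructure", function(object) {
  cat("QueryStructure", sQuote(object@structureId), "\n")
  cat(" ", nrow(object@residues), "residues in",
      length(object@chainIds), "chain(s):",
      paste(object@chainIds, collapse = ", "), "\n")
})

#' @describeIn SiteTemplate-class compact display
#' @param object object to display
#' @export
setMethod("show", "SiteTemplate", function(object) {
  cat("SiteTemplate", sQuote(object@templateId),
      sprintf("[%s]", object@siteKind), "\n")
  cat(" ", nrow(object@residues), "residues; source:",
      ifelse(nzchar(object@sourceStructure), object@sourceStructure, "<none>"),
      "; ligand:",
      ifelse(nzchar(object@ligandCode), object@ligandCode, "<none>"), "\n")
})

#' @describeIn TemplateLibrary-class compact display
#' @param object object to display
#' @export
setMethod("show", "TemplateLibrary", function(object) {
  kinds <- table(vapply(object@entries, function(e) e@siteKind, character(1)))
  cat("TemplateLibrary with", length(object@entries), "template(s)\n")
  for (k in names(kinds)) cat("  ", k, ":", kinds[[k]], "\n")
  cat("  ligand table:", nrow(object@ligandTable), "entries")
  ms <- object@metadata$missing_smiles
  if (length(ms) > 0) cat(" (missing SMILES:", paste(ms, collapse = ", "), ")")
  cat("\n")
})

#' @describeIn AssociationGraph-class compact display
#' @param object object to display
#' @export
setMethod("show", "AssociationGraph", function(object) {
  nv <- nrow(object@vertices)
  ne <- if (nv > 0) sum(object@adjacency) / 2 else 0
  cat("AssociationGraph:", nv, "vertices,", ne, "edges\n")
})

#' @describeIn MatchRecord-class compact display
#' @param object object to display
#' @export
setMethod("show", "MatchRecord", function(object) {
  cat(sprintf("MatchRecord %s: clique %d/%d, rmsd %.3f A, chains {%s}\n",
              object@templateId, object@cliqueSize, object@templateSize,
              object@rmsd, paste(object@spansChains, collapse = ",")))
})
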