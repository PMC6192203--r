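# Composite hit scoring and ranked reports.
#
# The score combines the three signals of match quality: the fraction of
# template residues matched (coverage), the superposition RMSD, and the
# relative size of the SMILES-similarity cluster containing the template's
# ligand. The default functional form
#
#   S = w_c * (clique_size / template_size) + w_r * exp(-rmsd / rho)
#       + w_l * rel_size
#
# is this package's own reconstruction of a composite clique/RMSD/cluster
# score: it is bounded in [0, w_c + w_r + w_l], strictly increasing in clique
# size and cluster weight, strictly decreasing in RMSD, and every weight is
# configurable so an alternative form can be dropped in. Catalytic-site
# templates carry no ligand, so their ligand term is 0 and their score lies
# in [0, w_c + w_r].

DEFAULT_WEIGHTS <- list(w_c = 1.0, w_r = 1.0, w_l = 0.5, rho = 1.5)

REPORT_COLUMNS <- c("rank", "template_id", "source_structure", "ligand_code",
                    "clique_size", "template_size", "rmsd",
                    "cluster_rel_size", "coverage", "score", "chains",
                    "matched_residues")

REPORT_SCHEMA_VERSION <- 1L

#' Composite match score
#'
#' @param cliqueSize,templateSize integers, `3 <= cliqueSize <= templateSize`.
#' @param rmsd site RMSD in Angstrom, `>= 0`.
#' @param clusterRelSize relative ligand-cluster size in `(0, 1]`, or `NA`
#'   for a catalytic-site match (ligand term omitted).
#' @param weights list with `w_c`, `w_r`, `w_l` and the RMSD decay scale
#'   `rho` (Angstrom); defaults `1, 1, 0.5, 1.5`.
#' @return Non-negative score; at the defaults the maximum attainable value
#'   is 2.5 for ligand sites (full coverage, zero RMSD, largest cluster) and
#'   2.0 for catalytic sites.
#' @examples
#' compositeScore(6, 6, 0, 1)          # 2.5, the maximum
#' compositeScore(3, 6, 2.0, 0.25)
#' @export
compositeScore <- function(cliqueSize, templateSize, rmsd, clusterRelSize,
                           weights = DEFAULT_WEIGHTS) {
  w <- utils::modifyList(DEFAULT_WEIGHTS, as.list(weights))
  if (any(cliqueSize < 3 | cliqueSize > templateSize))
    .stopClassed("cliquesite_contract_error",
                 "cliqueSize must lie in [3, templateSize]")
  if (any(rmsd < 0) || any(!is.finite(rmsd) & !is.infinite(rmsd)))
    .stopClassed("cliquesite_contract_error", "rmsd must be >= 0")
  bad <- !is.na(clusterRelSize) & (clusterRelSize <= 0 | clusterRelSize > 1)
  if (any(bad))
    .stopClassed("cliquesite_contract_error",
                 "clusterRelSize must be in (0, 1] or NA")
  lig <- ifelse(is.na(clusterRelSize), 0, w$w_l * clusterRelSize)
  w$w_c * (cliqueSize / templateSize) + w$w_r * exp(-rmsd / w$rho) + lig
}

#' Score and rank match records
#'
#' Attaches the ligand-cluster weight to each [MatchRecord-class], computes
#' the composite score and returns the ranked hit table. Ligand codes absent
#' from the cluster table fall back to the singleton weight (1 / largest
#' cluster size) with a message. Sorting is by score descending with a
#' deterministic tie-break (RMSD ascending, clique size descending,
#' template id ascending); ranks are dense and 1-based.
#'
#' @param matches list of [MatchRecord-class].
#' @param clusters cluster table from [clusterLigands()] (may be `NULL` when
#'   scoring catalytic hits only).
#' @param weights see [compositeScore()].
#' @return data.frame with columns
#'   `rank, template_id, source_structure, ligand_code, clique_size,
#'   template_size, rmsd, cluster_rel_size, coverage, score, chains,
#'   matched_residues`.
#' @export
rankHits <- function(matches, clusters = NULL, weights = DEFAULT_WEIGHTS) {
  if (length(matches) == 0) {
    out <- data.frame(rank = integer(0), template_id = character(0),
                      source_structure = character(0),
                      ligand_code = character(0), clique_size = integer(0),
                      template_size = integer(0), rmsd = numeric(0),
                      cluster_rel_size = numeric(0), coverage = numeric(0),
                      score = numeric(0), chains = character(0),
                      matched_residues = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  max_cluster <- if (!is.null(clusters) && nrow(clusters) > 0)
    max(clusters$cluster_size, na.rm = TRUE) else 1L
  relOf <- function(code, kind) {
    if (kind == "catalytic" || !nzchar(code)) return(NA_real_)
    if (!is.null(clusters) && code %in% clusters$ligand_code)
      return(clusters$rel_size[match(code, clusters$ligand_code)])
    message("ligand ", code,
            " missing from cluster table; using singleton weight")
    1 / max_cluster
  }
  rows <- lapply(matches, function(m) {
    rel <- relOf(m@ligandCode, m@siteKind)
    data.frame(
      template_id = m@templateId,
      source_structure = m@sourceStructure,
      ligand_code = m@ligandCode,
      clique_size = m@cliqueSize,
      template_size = m@templateSize,
      rmsd = m@rmsd,
      cluster_rel_size = rel,
      coverage = m@cliqueSize / m@templateSize,
      score = compositeScore(m@cliqueSize, m@templateSize, m@rmsd, rel,
                             weights),
      chains = paste(m@spansChains, collapse = ","),
      matched_residues = paste(m@matchedResidues, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  o <- order(-out$score, out$rmsd, -out$clique_size, out$template_id)
  out <- out[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out[, REPORT_COLUMNS]
}

#' Combined ligand-site / catalytic-site report
#'
#' Merges ranked hits from a ligand binding-site scan and a catalytic-site
#' scan into one report, so the location of the binding site, the identity
#' of the likely ligand(s) and any catalytic-activity match are presented
#' together. Empty sections are stated explicitly.
#'
#' @param ligandHits,catalyticHits ranked tables from [rankHits()] (either
#'   may be `NULL` or empty).
#' @param topK hits retained per section (default 10).
#' @param metadata named list merged into the report `metadata` block
#'   (e.g. query id, config hash, skipped templates).
#' @return A list of class `cliquesite_report` with elements `metadata`,
#'   `ligand_sites`, `catalytic_sites`, `skipped_templates`.
#' @seealso [writeReport()]
#' @export
combinedFunctionReport <- function(ligandHits = NULL, catalyticHits = NULL,
                                   topK = 10L, metadata = list()) {
  clip <- function(h) {
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h[seq_len(min(topK, nrow(h))), , drop = FALSE]
  }
  base_meta <- list(
    tool = "CliqueSite",
    tool_version = as.character(utils::packageVersion("CliqueSite")),
    report_schema_version = REPORT_SCHEMA_VERSION,
    library_format_version = LIB_VERSION,
    score_formula = "w_c*coverage + w_r*exp(-rmsd/rho) + w_l*rel_size (reconstruction)",
    top_k = topK)
  structure(list(
    metadata = utils::modifyList(base_meta, metadata),
    ligand_sites = clip(ligandHits),
    catalytic_sites = clip(catalyticHits),
    skipped_templates = metadata$skipped_templates %||% character(0)
  ), class = "cliquesite_report")
}

#' Write a report as TSV and/or JSON
#'
#' The TSV carries the metadata block as `# key: value` comment lines, then
#' one section per site kind; the JSON mirrors the report structure. Output
#' is deterministic: identical inputs and configuration give byte-identical
#' files.
#'
#' @param report a `cliquesite_report` from [combinedFunctionReport()].
#' @param tsvPath,jsonPath output paths (`NULL` to skip one of the formats).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, tsvPath = NULL, jsonPath = NULL) {
  stopifnot(inherits(report, "cliquesite_report"))
  written <- character(0)
  fmtNum <- function(x) formatC(x, digits = 6, format = "g")
  if (!is.null(tsvPath)) {
    con <- file(tsvPath, "wb")
    wl <- function(...) writeLines(c(...), con, useBytes = TRUE)
    meta <- report$metadata
    for (k in sort(names(meta)))
      wl(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")))
    for (section in c("ligand_sites", "catalytic_sites")) {
      wl(sprintf("## section: %s", section))
      h <- report[[section]]
      if (is.null(h) || nrow(h) == 0) {
        wl("# no hits")
        next
      }
      h$rmsd <- fmtNum(h$rmsd); h$score <- fmtNum(h$score)
      h$coverage <- fmtNum(h$coverage)
      h$cluster_rel_size <- ifelse(is.na(h$cluster_rel_size), "NA",
                                   fmtNum(h$cluster_rel_size))
      wl(paste(names(h), collapse = "\t"))
      for (i in seq_len(nrow(h)))
        wl(paste(vapply(h[i, ], as.character, character(1)), collapse = "\t"))
    }
    if (length(report$skipped_templates) > 0)
      wl("## skipped templates (budget exceeded)",
         paste0("# ", report$skipped_templates))
    close(con)
    written <- c(written, tsvPath)
  }
  if (!is.null(jsonPath)) {
    json <- jsonlite::toJSON(list(
      metadata = report$metadata,
      ligand_sites = report$ligand_sites,
      catalytic_sites = report$catalytic_sites,
      skipped_templates = report$skipped_templates
    ), dataframe = "rows", auto_unbox = TRUE, digits = 10, pretty = TRUE,
      null = "null")
    writeLines(json, jsonPath, useBytes = TRUE)
    written <- c(written, jsonPath)
  }
  invisible(written)
}
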