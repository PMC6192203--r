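# Run configuration and the end-to-end pipeline operations behind the
# command-line interface.

#' Default run configuration
#'
#' All tunables in one named list. Defaults:
#' \describe{
#'   \item{distTol}{1.5 A distance-difference tolerance for association-graph
#'     edges.}
#'   \item{minCliqueSize}{3, smallest reported correspondence.}
#'   \item{rmsdCutoff}{3.0 A, matches above this are discarded.}
#'   \item{interfaceMode}{FALSE; per-chain matching unless enabled.}
#'   \item{aaMode}{"strict" residue compatibility.}
#'   \item{simThreshold}{0.7 Tanimoto for ligand clustering.}
#'   \item{w_c, w_r, w_l, rho}{composite-score weights 1, 1, 0.5 and the RMSD
#'     decay scale 1.5 A.}
#'   \item{contactCutoff}{4.5 A heavy-atom cutoff for template extraction.}
#'   \item{edgeBudget}{200000 association-graph edges before a template is
#'     skipped.}
#'   \item{maxResults}{50 cliques kept per association graph.}
#'   \item{topK}{10 hits per report section.}
#'   \item{fingerprintBackend}{"kgram" (see [ligandFingerprint()]).}
#'   \item{excludedLigands}{waters/ions/buffers skipped by the library
#'     builder.}
#'   \item{seed}{1, for the fixture generator.}
#' }
#'
#' @return Named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    distTol = 1.5,
    minCliqueSize = 3L,
    rmsdCutoff = 3.0,
    interfaceMode = FALSE,
    aaMode = "strict",
    simThreshold = 0.7,
    w_c = 1.0, w_r = 1.0, w_l = 0.5, rho = 1.5,
    contactCutoff = 4.5,
    edgeBudget = 200000L,
    maxResults = 50L,
    topK = 10L,
    fingerprintBackend = "kgram",
    excludedLigands = DEFAULT_EXCLUDED_LIGANDS,
    seed = 1L
  )
}

#' Read a JSON configuration file
#'
#' Values from the file override [defaultConfig()]; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (used for CLI
#'   flags).
#' @return Complete configuration list.
#' @export
readConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultConfig()
  fromFile <- if (is.null(path)) list() else {
    if (!file.exists(path))
      .stopClassed("cliquesite_config_error", "config file not found: %s", path)
    tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
             error = function(e)
               .stopClassed("cliquesite_config_error",
                            "cannot parse config %s: %s", path,
                            conditionMessage(e)))
  }
  for (src in list(fromFile, overrides)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown) > 0)
      .stopClassed("cliquesite_config_error",
                   "unknown configuration key(s): %s",
                   paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, src)
  }
  cfg$minCliqueSize <- as.integer(cfg$minCliqueSize)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Hash of the effective configuration
#'
#' FNV-1a hash of the canonical JSON serialization, echoed into every output
#' so two reports are comparable at a glance.
#'
#' @param config configuration list.
#' @return 8-hex-digit string.
#' @export
configHash <- function(config) {
  config <- config[sort(names(config))]
  fnv1aHash(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                          digits = NA)))
}

#' Build a template library from holo structures
#'
#' Iterates [buildTemplate()] over every structure file and every
#' non-excluded HETATM ligand instance it contains (one template per ligand
#' instance: a ligand bound twice gives two templates, since the two sites
#' may differ). Per-file and per-ligand failures are logged and skipped; the
#' build fails only if no template at all could be built.
#'
#' @param paths character vector of structure files.
#' @param ligandTable optional data.frame `ligand_code,smiles` attached to
#'   the library (and used to fill template SMILES).
#' @param contactCutoff heavy-atom contact cutoff, Angstrom.
#' @param excludedLigands HET codes never turned into templates.
#' @return A [TemplateLibrary-class]; attribute `buildLog` records skips.
#' @export
buildLibraryFromStructures <- function(paths, ligandTable = NULL,
                                       contactCutoff = 4.5,
                                       excludedLigands = DEFAULT_EXCLUDED_LIGANDS) {
  entries <- list()
  log <- character(0)
  for (path in paths) {
    atoms <- tryCatch(.readStructureAtoms(path), error = function(e) {
      log <<- c(log, sprintf("skipped %s: %s", path, conditionMessage(e)))
      NULL
    })
    if (is.null(atoms)) next
    het <- atoms[atoms$type == "HETATM" & !.isHydrogen(atoms), , drop = FALSE]
    het <- het[!het$resid %in% c(excludedLigands, names(NONSTANDARD_AA_MAP)), ,
               drop = FALSE]
    if (nrow(het) == 0) {
      log <- c(log, sprintf("no eligible ligand in %s", path))
      next
    }
    insts <- unique(data.frame(code = het$resid,
                               instance = paste(het$chain, het$resno, sep = ":"),
                               stringsAsFactors = FALSE))
    for (i in seq_len(nrow(insts))) {
      smi <- ""
      if (!is.null(ligandTable)) {
        hit <- match(insts$code[i], ligandTable$ligand_code)
        if (!is.na(hit)) smi <- ligandTable$smiles[hit]
      }
      tmpl <- tryCatch(
        buildTemplate(path, insts$code[i], contactCutoff,
                      instance = insts$instance[i], ligandSmiles = smi),
        cliquesite_error = function(e) {
          log <<- c(log, sprintf("skipped %s %s in %s: %s", insts$code[i],
                                 insts$instance[i], path, conditionMessage(e)))
          NULL
        })
      if (!is.null(tmpl)) entries[[length(entries) + 1L]] <- tmpl
    }
  }
  if (length(entries) == 0)
    .stopClassed("cliquesite_empty_build",
                 "no templates built from %d file(s); log:\n%s",
                 length(paths), paste(log, collapse = "\n"))
  codes <- unique(vapply(entries, function(e) e@ligandCode, character(1)))
  if (is.null(ligandTable)) {
    smiles <- vapply(codes, function(code) {
      for (e in entries)
        if (e@ligandCode == code && nzchar(e@ligandSmiles))
          return(e@ligandSmiles)
      ""
    }, character(1))
    ligandTable <- data.frame(ligand_code = codes, smiles = smiles,
                              stringsAsFactors = FALSE)
    ligandTable <- ligandTable[nzchar(ligandTable$smiles), , drop = FALSE]
  }
  lib <- TemplateLibrary(entries, ligandTable,
                         metadata = list(contact_cutoff = contactCutoff))
  attr(lib, "buildLog") <- log
  lib
}

#' Scan a query structure against template libraries
#'
#' The per-job pipeline: match every template of the ligand binding-site
#' library (and optionally a catalytic-site library) against the query with
#' [matchTemplate()], weight ligand hits by their SMILES-cluster relative
#' size, rank with [rankHits()] and assemble the combined report. Templates
#' whose association graph exceeds the edge budget are listed in the report
#' footer, never silently dropped.
#'
#' @param query a [QueryStructure-class].
#' @param library a [TemplateLibrary-class] of binding-site templates (may
#'   also contain catalytic entries).
#' @param catalyticLibrary optional second [TemplateLibrary-class] of
#'   catalytic-site templates.
#' @param config configuration list (see [defaultConfig()]).
#' @param clusters optional precomputed cluster table; by default
#'   [clusterLigands()] is run on the library's ligand table.
#' @return A `cliquesite_report` (see [combinedFunctionReport()]).
#' @export
scanStructure <- function(query, library, catalyticLibrary = NULL,
                          config = defaultConfig(), clusters = NULL) {
  stopifnot(is(query, "QueryStructure"), is(library, "TemplateLibrary"))
  entries <- templateEntries(library)
  if (!is.null(catalyticLibrary))
    entries <- c(entries, templateEntries(catalyticLibrary))
  if (length(entries) == 0)
    .stopClassed("cliquesite_config_error", "template library is empty")

  if (is.null(clusters)) {
    lt <- ligandTable(library)
    clusters <- if (nrow(lt) > 0)
      clusterLigands(lt, simThreshold = config$simThreshold,
                     backend = config$fingerprintBackend)
    else NULL
  }

  matches <- list()
  skipped <- character(0)
  for (tmpl in entries) {
    recs <- matchTemplate(tmpl, query,
                          distTol = config$distTol,
                          minCliqueSize = config$minCliqueSize,
                          rmsdCutoff = config$rmsdCutoff,
                          interfaceMode = config$interfaceMode,
                          aaMode = config$aaMode,
                          maxResults = config$maxResults,
                          edgeBudget = config$edgeBudget)
    if (isTRUE(attr(recs, "skipped")))
      skipped <- c(skipped, tmpl@templateId)
    matches <- c(matches, recs)
  }
  kinds <- vapply(matches, function(m) m@siteKind, character(1))
  weights <- config[c("w_c", "w_r", "w_l", "rho")]
  lig_hits <- rankHits(matches[kinds == "ligand_binding"], clusters, weights)
  cat_hits <- rankHits(matches[kinds == "catalytic"], NULL, weights)
  combinedFunctionReport(
    lig_hits, cat_hits, topK = config$topK,
    metadata = list(
      query = query@structureId,
      config_hash = configHash(config),
      fingerprint_backend = if (!is.null(clusters))
        attr(clusters, "backend") %||% "precomputed" else "none",
      interface_mode = config$interfaceMode,
      n_templates = length(entries),
      skipped_templates = skipped))
}
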