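# Synthetic recovery benchmarks: the planted-site stand-in for apo/holo
# binding-site recovery, and the split-site benchmark for interface mode.

#' Planted-site recovery benchmark
#'
#' For each seed: generate a planted-site structure (site size cycling
#' through `siteSizes`, Gaussian coordinate noise, decoy residues), build a
#' decoy template library with the planted ground-truth template added,
#' re-parse the written PDB and run the full scan. Reports where the planted
#' template ranked.
#'
#' @param seeds integer vector, one trial per seed.
#' @param siteSizes site residue counts cycled across trials (default 5:8).
#' @param noiseSigma coordinate noise, Angstrom (default 0.3).
#' @param nDecoyResidues decoy residues per structure (default 50).
#' @param nDecoyTemplates decoy templates per library (default 50).
#' @param config scan configuration (default [defaultConfig()]).
#' @return data.frame with one row per trial: `seed`, `site_size`, `rank`
#'   (NA if the planted template was not found at all), `rmsd` of its best
#'   hit, `top_template` (the rank-1 template id).
#' @export
plantedSiteBenchmark <- function(seeds, siteSizes = 5:8, noiseSigma = 0.3,
                                 nDecoyResidues = 50L, nDecoyTemplates = 50L,
                                 config = defaultConfig()) {
  rows <- lapply(seq_along(seeds), function(i) {
    seed <- seeds[i]
    n <- siteSizes[(i - 1L) %% length(siteSizes) + 1L]
    fx <- generatePlantedStructure(n, noiseSigma, nDecoyResidues, seed = seed)
    lib <- generateDecoyLibrary(nDecoyTemplates, seed = seed + 500000L,
                                extraTemplates = list(fx$template))
    query <- parseStructure(fx$path)
    unlink(fx$path)
    rep <- scanStructure(query, lib, config = config)
    hits <- rep$ligand_sites
    planted <- fx$template@templateId
    idx <- which(hits$template_id == planted)
    data.frame(seed = seed, site_size = n,
               rank = if (length(idx)) hits$rank[idx[1]] else NA_integer_,
               rmsd = if (length(idx)) hits$rmsd[idx[1]] else NA_real_,
               top_template = if (nrow(hits)) hits$template_id[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Interface-mode benchmark
#'
#' For each seed: plant a site split across two chains (partition
#' `c(3, 2)` by default) and try to recover it with interface mode on and
#' off, using a minimum clique size larger than any single-chain fragment so
#' that only a cross-chain correspondence can succeed.
#'
#' @param seeds integer vector, one trial per seed.
#' @param nSiteResidues total site residues (default 5).
#' @param partition split of the site across chains (default `c(3, 2)`).
#' @param nDecoyResidues decoy residues (default 50).
#' @param minCliqueSize minimum correspondence size; defaults to
#'   `max(partition) + 1`, one above the largest per-chain fragment.
#' @param noiseSigma coordinate noise, Angstrom (default 0.3).
#' @return data.frame with `seed`, `detected_on`, `detected_off`.
#' @export
interfaceBenchmark <- function(seeds, nSiteResidues = 5L,
                               partition = c(3L, 2L), nDecoyResidues = 50L,
                               minCliqueSize = max(partition) + 1L,
                               noiseSigma = 0.3) {
  rows <- lapply(seeds, function(seed) {
    fx <- generatePlantedStructure(nSiteResidues, noiseSigma, nDecoyResidues,
                                   splitAcrossChains = partition, seed = seed)
    query <- parseStructure(fx$path)
    unlink(fx$path)
    on <- matchTemplate(fx$template, query, minCliqueSize = minCliqueSize,
                        interfaceMode = TRUE)
    off <- matchTemplate(fx$template, query, minCliqueSize = minCliqueSize,
                         interfaceMode = FALSE)
    data.frame(seed = seed, detected_on = length(on) > 0,
               detected_off = length(off) > 0)
  })
  do.call(rbind, rows)
}
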