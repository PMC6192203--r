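# The matching core: association-graph construction between a site template
# and a query structure, maximal-clique enumeration (Bron-Kerbosch with
# pivoting and degeneracy ordering), and template matching with an optional
# interface mode that lets a match span several query chains.

#' Amino-acid compatibility test
#'
#' `strict` requires identical 3-letter types; `relaxed` accepts members of
#' the same physicochemical group ({D,E}, {K,R,H}, {S,T}, {I,L,V,M},
#' {F,Y,W}, {N,Q}, {A,G}, {C}, {P}).
#'
#' @param aaT,aaQ character vectors of 3-letter codes (recycled).
#' @param mode `"strict"` or `"relaxed"`.
#' @return logical vector.
#' @export
aaCompatible <- function(aaT, aaQ, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  if (mode == "strict") aaT == aaQ else .aaGroupOf(aaT) == .aaGroupOf(aaQ)
}

#' Build the association graph between a template and a query
#'
#' A vertex is a pair (template residue i, query residue j) whose amino-acid
#' types are compatible under `aaMode`. An edge joins vertices (i,j) and
#' (k,l) iff i != k, j != l, and the template-side and query-side pairwise
#' distances agree within `distTol` for both pseudo-atoms:
#' `|d_ca(t_i,t_k) - d_ca(q_j,q_l)| <= distTol` and
#' `|d_sc(t_i,t_k) - d_sc(q_j,q_l)| <= distTol`.
#' Cliques of this graph are geometrically consistent residue
#' correspondences. An empty graph is a valid result.
#'
#' @param template a [SiteTemplate-class] (>= 3 residues).
#' @param query a [QueryStructure-class].
#' @param distTol distance-difference tolerance in Angstrom (default 1.5).
#' @param aaMode residue compatibility rule, see [aaCompatible()].
#' @param queryIndices optional integer subset of query residue indices to
#'   consider (used by per-chain matching); vertex indices in the result
#'   always refer to the full query residue table.
#' @return An [AssociationGraph-class].
#' @export
buildAssociationGraph <- function(template, query, distTol = 1.5,
                                  aaMode = c("strict", "relaxed"),
                                  queryIndices = NULL) {
  aaMode <- match.arg(aaMode)
  tres <- residues(template)
  qres <- residues(query)
  qidx <- if (is.null(queryIndices)) seq_len(nrow(qres)) else
    sort(as.integer(queryIndices))
  params <- list(distTol = distTol, aaMode = aaMode,
                 templateId = template@templateId,
                 structureId = query@structureId)

  # vertices: all compatible (i, j) pairs, ordered lexicographically
  comp <- outer(tres$aa, qres$aa[qidx],
                function(a, b) aaCompatible(a, b, aaMode))
  hit <- which(comp, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(new("AssociationGraph",
               vertices = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("t", "q"))),
               adjacency = matrix(logical(0), 0, 0), params = params))
  }
  verts <- cbind(t = as.integer(hit[, 1]), q = qidx[hit[, 2]])
  verts <- verts[order(verts[, 1], verts[, 2]), , drop = FALSE]

  Dtca <- pairwiseDistances(as.matrix(tres[, c("ca_x", "ca_y", "ca_z")]))
  Dtsc <- pairwiseDistances(as.matrix(tres[, c("sc_x", "sc_y", "sc_z")]))
  Dqca <- pairwiseDistances(as.matrix(qres[, c("ca_x", "ca_y", "ca_z")]))
  Dqsc <- pairwiseDistances(as.matrix(qres[, c("sc_x", "sc_y", "sc_z")]))

  ti <- verts[, 1]; qi <- verts[, 2]
  adj <- abs(Dtca[ti, ti, drop = FALSE] - Dqca[qi, qi, drop = FALSE]) <= distTol &
         abs(Dtsc[ti, ti, drop = FALSE] - Dqsc[qi, qi, drop = FALSE]) <= distTol &
         outer(ti, ti, "!=") & outer(qi, qi, "!=")
  dimnames(adj) <- NULL
  new("AssociationGraph", vertices = verts, adjacency = adj, params = params)
}

# Degeneracy ordering: repeatedly remove a minimum-degree vertex (ties:
# smallest index). Returns the removal order.
.degeneracyOrder <- function(nbrs) {
  n <- length(nbrs)
  deg <- vapply(nbrs, length, integer(1))
  alive <- rep(TRUE, n)
  ord <- integer(n)
  for (k in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    ord[k] <- v
    alive[v] <- FALSE
    for (w in nbrs[[v]]) if (alive[w]) deg[w] <- deg[w] - 1L
  }
  ord
}

# Bron-Kerbosch with pivoting over integer-vector sets (sorted).
.bkPivot <- function(R, P, X, nbrs, acc) {
  if (length(P) == 0 && length(X) == 0) {
    acc[[length(acc) + 1L]] <- R
    return(acc)
  }
  # pivot u in P union X maximizing |P cap N(u)| (ties: smallest vertex id)
  PX <- c(P, X)
  cnt <- vapply(PX, function(u) sum(P %in% nbrs[[u]]), integer(1))
  u <- PX[order(-cnt, PX)][1]
  for (v in setdiff(P, nbrs[[u]])) {
    Nv <- nbrs[[v]]
    acc <- .bkPivot(c(R, v), intersect(P, Nv), intersect(X, Nv), nbrs, acc)
    P <- setdiff(P, v)
    X <- sort(c(X, v))
  }
  acc
}

#' Enumerate maximal cliques of an association graph
#'
#' Bron-Kerbosch with pivoting, with the outer loop over a degeneracy
#' ordering of the vertices. Returns every maximal clique of at least
#' `minCliqueSize` vertices as a residue correspondence, in a deterministic
#' order: size descending, then lexicographic on the sorted vertex pairs.
#'
#' @param graph an [AssociationGraph-class].
#' @param minCliqueSize smallest correspondence reported (default 3; below 3
#'   a rigid transform's RMSD is not meaningfully constrained).
#' @param maxResults truncate the ordered result list (default `Inf`).
#' @param edgeBudget refuse graphs with more edges than this (default
#'   200000): clique enumeration is exponential in the worst case, so
#'   oversized graphs raise a classed `cliquesite_budget_exceeded` error and
#'   the caller skips the template explicitly rather than truncating
#'   silently.
#' @return A list of correspondences; each has `pairs` (integer matrix,
#'   columns `t`, `q`, ordered by `t`) and `size`.
#' @export
findMaxCliques <- function(graph, minCliqueSize = 3L, maxResults = Inf,
                           edgeBudget = 200000L) {
  nv <- nrow(graph@vertices)
  if (nv == 0) return(list())
  adj <- graph@adjacency
  ne <- sum(adj) / 2
  if (ne > edgeBudget)
    .stopClassed("cliquesite_budget_exceeded",
                 "association graph for template %s has %d edges (budget %d)",
                 graph@params$templateId %||% "<unknown>", ne, edgeBudget)
  nbrs <- lapply(seq_len(nv), function(v) which(adj[v, ]))
  ord <- .degeneracyOrder(nbrs)
  pos <- integer(nv); pos[ord] <- seq_len(nv)
  cliques <- list()
  for (v in ord) {
    later <- nbrs[[v]][pos[nbrs[[v]]] > pos[v]]
    earlier <- nbrs[[v]][pos[nbrs[[v]]] < pos[v]]
    cliques <- .bkPivot(v, sort(later), sort(earlier), nbrs, cliques)
  }
  cliques <- lapply(cliques, sort)
  cliques <- cliques[vapply(cliques, length, integer(1)) >= minCliqueSize]
  if (length(cliques) == 0) return(list())
  sizes <- vapply(cliques, length, integer(1))
  keys <- vapply(cliques, function(cl)
    paste(sprintf("%08d", cl), collapse = ","), character(1))
  o <- order(-sizes, keys)
  cliques <- cliques[o]
  if (is.finite(maxResults) && length(cliques) > maxResults)
    cliques <- cliques[seq_len(maxResults)]
  lapply(cliques, function(cl) {
    pairs <- graph@vertices[cl, , drop = FALSE]
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    list(pairs = pairs, size = nrow(pairs))
  })
}

#' Match a site template against a query structure
#'
#' Composes [buildAssociationGraph()], [findMaxCliques()] and
#' [correspondenceRmsd()]. In the default per-chain mode the graph is built
#' once per query chain, so a correspondence never crosses chains; with
#' `interfaceMode = TRUE` the graph is built over all chains jointly and a
#' match may span subunit interfaces. Correspondences whose superposition
#' RMSD exceeds `rmsdCutoff` are discarded.
#'
#' @param template a [SiteTemplate-class].
#' @param query a [QueryStructure-class].
#' @param distTol,aaMode,minCliqueSize,edgeBudget see
#'   [buildAssociationGraph()] and [findMaxCliques()].
#' @param rmsdCutoff maximum site RMSD retained, Angstrom (default 3.0).
#' @param interfaceMode logical; allow matches spanning several chains.
#' @param maxResults per-graph cap on enumerated cliques (default 50).
#' @return A list of [MatchRecord-class] objects, best (largest, then lowest
#'   RMSD) first. If the edge budget was exceeded the list carries attribute
#'   `skipped = TRUE` and `skipReason`; the template must then be reported as
#'   skipped, never silently dropped.
#' @export
matchTemplate <- function(template, query, distTol = 1.5,
                          minCliqueSize = 3L, rmsdCutoff = 3.0,
                          interfaceMode = FALSE,
                          aaMode = c("strict", "relaxed"),
                          maxResults = 50L, edgeBudget = 200000L) {
  aaMode <- match.arg(aaMode)
  qres <- residues(query)
  index_sets <- if (interfaceMode) list(seq_len(nrow(qres))) else
    lapply(chainIds(query), function(ch) which(qres$chain == ch))

  records <- list()
  skipped <- FALSE
  reasons <- character(0)
  for (idx in index_sets) {
    g <- buildAssociationGraph(template, query, distTol, aaMode,
                               queryIndices = idx)
    cls <- tryCatch(
      findMaxCliques(g, minCliqueSize, maxResults, edgeBudget),
      cliquesite_budget_exceeded = function(e) {
        skipped <<- TRUE
        reasons <<- c(reasons, conditionMessage(e))
        NULL
      })
    if (is.null(cls)) next
    for (cl in cls) {
      fit <- correspondenceRmsd(cl$pairs, template, query)
      if (fit$rmsd > rmsdCutoff) next
      qmatched <- qres[cl$pairs[, 2], , drop = FALSE]
      records[[length(records) + 1L]] <- new("MatchRecord",
        templateId = template@templateId,
        sourceStructure = template@sourceStructure,
        siteKind = template@siteKind,
        ligandCode = template@ligandCode,
        pairs = cl$pairs,
        rotation = fit$rotation,
        translation = fit$translation,
        rmsd = fit$rmsd,
        cliqueSize = cl$size,
        templateSize = nrow(residues(template)),
        spansChains = sort(unique(qmatched$chain)),
        matchedResidues = residueLabel(qmatched))
    }
  }
  if (length(records) > 1) {
    o <- order(-vapply(records, function(r) r@cliqueSize, integer(1)),
               vapply(records, function(r) r@rmsd, numeric(1)))
    records <- records[o]
  }
  structure(records, skipped = skipped,
            skipReason = if (skipped) paste(reasons, collapse = "; ") else NULL)
}
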