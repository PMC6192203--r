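# Optimal rigid-body superposition (Kabsch algorithm via SVD) and RMSD.

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `moving` onto `fixed` using the
#' Kabsch algorithm: the covariance matrix of the centred point sets is
#' decomposed by SVD and the determinant sign is corrected so the result is
#' always a proper rotation (never a reflection).
#'
#' @param fixed,moving numeric n x 3 matrices of corresponding points, n >= 3.
#' @return A list with `rotation` (3x3 proper rotation), `translation`
#'   (length 3) and `rmsd`. The transform maps a moving point `p` to
#'   `rotation %*% p + translation`.
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' kabsch(x, x)$rmsd  # 0
#' @export
kabsch <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (ncol(fixed) != 3 || ncol(moving) != 3)
    .stopClassed("cliquesite_contract_error", "point sets must be n x 3")
  if (nrow(fixed) != nrow(moving))
    .stopClassed("cliquesite_contract_error",
                 "point sets differ in length (%d vs %d)",
                 nrow(fixed), nrow(moving))
  if (nrow(fixed) < 3)
    .stopClassed("cliquesite_contract_error",
                 "at least 3 point pairs are required, got %d", nrow(fixed))
  if (!all(is.finite(fixed)) || !all(is.finite(moving)))
    .stopClassed("cliquesite_contract_error", "non-finite coordinates")
  cf <- colMeans(fixed); cm <- colMeans(moving)
  P <- sweep(moving, 2, cm)   # centred moving
  Q <- sweep(fixed, 2, cf)    # centred fixed
  if (max(abs(P)) == 0 && max(abs(Q)) == 0)
    .stopClassed("cliquesite_contract_error", "all points coincident")
  C <- crossprod(P, Q)        # 3x3 covariance
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rmsd <- sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  list(rotation = R, translation = as.numeric(cf - R %*% cm), rmsd = rmsd)
}

# Stack the pseudo-atoms of a residue subset: C-alpha for every residue plus
# the side-chain centroid where `scMask` is TRUE (glycine contributes its
# C-alpha only, not a duplicated point; under relaxed compatibility the
# side-chain point is used only when both partners have one).
.stackPseudoAtoms <- function(res, idx, scMask) {
  sub <- res[idx, , drop = FALSE]
  ca <- as.matrix(sub[, c("ca_x", "ca_y", "ca_z")])
  sc <- as.matrix(sub[scMask, c("sc_x", "sc_y", "sc_z"), drop = FALSE])
  unname(rbind(ca, sc))
}

#' RMSD of a clique correspondence
#'
#' Superposes the template residues of a correspondence onto the matched
#' query residues over their pseudo-atoms (C-alpha plus side-chain centroid;
#' glycine contributes C-alpha only) and returns the transform and the
#' site RMSD.
#'
#' @param pairs integer matrix with columns `t` (template residue index) and
#'   `q` (query residue index).
#' @param template a [SiteTemplate-class].
#' @param query a [QueryStructure-class].
#' @return As [kabsch()]: list with `rotation`, `translation`, `rmsd`.
#' @export
correspondenceRmsd <- function(pairs, template, query) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("t", "q")))
  tres <- residues(template); qres <- residues(query)
  scMask <- tres$aa[pairs[, 1]] != "GLY" & qres$aa[pairs[, 2]] != "GLY"
  moving <- .stackPseudoAtoms(tres, pairs[, 1], scMask)
  fixed <- .stackPseudoAtoms(qres, pairs[, 2], scMask)
  kabsch(fixed, moving)
}
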