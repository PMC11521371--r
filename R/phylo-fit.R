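#' Fit the reversible model and branch lengths by maximum likelihood
#'
#' Coordinate ascent: golden-section line searches over pi1 and every branch
#' length in turn, sweeping until the relative log-likelihood improvement
#' falls below `relTol`. Deterministic given the starting point (all branch
#' lengths 0.1, pi1 at the observed presence fraction).
#'
#' @param tree an [ape::phylo] topology (branch lengths, if present, are
#'   ignored; optimisation starts from 0.1 everywhere).
#' @param counts pattern counts from [patternCounts()] (observable patterns
#'   only).
#' @param relTol relative log-likelihood convergence tolerance.
#' @param maxSweeps sweep cap; non-convergence yields a warning and the best
#'   parameters so far.
#' @param maxBl upper bound for branch lengths (expected changes/character).
#' @return list: `model` ([BinaryModel-class]), `tree` (with fitted branch
#'   lengths), `loglik`, `converged`, `sweeps`.
#' @export
fitBinaryModel <- function(tree, counts, relTol = 1e-8, maxSweeps = 200L,
                           maxBl = 20) {
  if (length(tree$tip.label) < 3L) stop("need at least 3 taxa")
  tree2 <- tree
  tree2$edge.length <- rep(0.1, nrow(tree$edge))
  ta <- .treeArrays(tree2)
  .checkObservable(counts)
  counts <- .alignCounts(counts, ta$tips)
  presFrac <- sum(counts$patterns * counts$counts) /
    (ncol(counts$patterns) * sum(counts$counts))
  fit <- .fitBinaryModel(ta$edge, ta$blen, ta$nTip, counts$patterns,
                         as.numeric(counts$counts), presFrac,
                         relTol, as.integer(maxSweeps), maxBl)
  if (!fit$converged)
    warning("fit did not converge in ", maxSweeps, " sweeps; returning best so far")
  out <- tree2
  # .treeArrays reordered edges postorder; write lengths back in that order
  po <- ape::reorder.phylo(tree2, "postorder")
  po$edge.length <- fit$blen
  list(model = binaryModel(fit$pi1), tree = po,
       loglik = fit$loglik, converged = fit$converged, sweeps = fit$sweeps)
}
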