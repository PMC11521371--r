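#' Simulate gene family gain and loss on a tree
#'
#' Each family is present at the root with probability `rootPresenceProb`.
#' Along every edge a present family is lost with that edge's loss
#' probability; by default there is no regain (a Dollo-like process that
#' mirrors loss-dominated genome evolution and keeps ground truth
#' unambiguous). Setting `gainProb > 0` allows absent families to reappear,
#' for robustness experiments. Loss probabilities are per *branch*, not per
#' unit branch length: gene content and sequence divergence are decoupled.
#'
#' @param tree an [ape::phylo] species tree.
#' @param nFamilies number of gene families to simulate.
#' @param rootPresenceProb probability a family is present at the root.
#' @param lossProb baseline per-branch loss probability.
#' @param lossOverrides optional named numeric vector; names are tip labels
#'   whose *terminal* branch uses the given loss probability instead of the
#'   baseline (the fast-losing-lineage knob).
#' @param gainProb per-branch probability that an absent family is gained.
#' @param familyIds optional family ids; default `fam0001`, ...
#' @return list with `pam` (a [PresenceAbsenceMatrix-class] of leaf states,
#'   unfiltered: all-zero columns are retained) and `truth` (list with
#'   `tree` and `nodeStates`, an (nodes x families) 0/1 matrix over all tree
#'   nodes in ape node numbering).
#' @examples
#' set.seed(1)
#' tr <- simulateTree(4, "balanced")
#' sim <- evolveGeneContent(tr, 100, lossProb = 0.2)
#' dim(sim$pam)
#' @export
evolveGeneContent <- function(tree, nFamilies, rootPresenceProb = 1,
                              lossProb = 0.15, lossOverrides = NULL,
                              gainProb = 0, familyIds = NULL) {
  stopifnot(inherits(tree, "phylo"))
  .checkProb(rootPresenceProb, "rootPresenceProb")
  .checkProb(lossProb, "lossProb")
  .checkProb(gainProb, "gainProb")
  if (!is.null(lossOverrides)) {
    if (is.null(names(lossOverrides)) ||
        !all(names(lossOverrides) %in% tree$tip.label))
      stop("lossOverrides must be named by tip labels")
    for (v in lossOverrides) .checkProb(v, "lossOverrides")
  }
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  if (is.null(familyIds)) familyIds <- sprintf("fam%04d", seq_len(nFamilies))
  states <- matrix(0L, nNode, nFamilies)
  root <- nTip + 1L
  states[root, ] <- stats::rbinom(nFamilies, 1L, rootPresenceProb)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge  # parent before child
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]; ch <- edges[i, 2L]
    pl <- lossProb
    if (ch <= nTip && !is.null(lossOverrides)) {
      lab <- tree$tip.label[ch]
      if (lab %in% names(lossOverrides)) pl <- lossOverrides[[lab]]
    }
    s <- states[p, ]
    lost <- s == 1L & stats::runif(nFamilies) < pl
    gained <- if (gainProb > 0) s == 0L & stats::runif(nFamilies) < gainProb
              else FALSE
    s[lost] <- 0L
    s[gained] <- 1L
    states[ch, ] <- s
  }
  leafStates <- states[seq_len(nTip), , drop = FALSE]
  dimnames(leafStates) <- list(tree$tip.label, familyIds)
  colnames(states) <- familyIds
  list(pam = presenceAbsenceMatrix(leafStates),
       truth = list(tree = tree, nodeStates = states))
}

.checkProb <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(what, " must be a probability in [0, 1]")
  invisible(p)
}
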